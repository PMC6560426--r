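# rumenamp

Analysis of rumen bacterial communities from 16S rRNA V1–V3 amplicon
sequencing, built for two-group feeding trials (e.g. essential-oil
supplemented vs control calves). The package implements the complete
computational chain from raw assembled reads to publication-style tables —
read quality screening, OTU clustering at a non-standard 5% cutoff (V1
is the most variable region of the gene, so the usual 3% full-length
cutoff is too tight for V1–V3), reference-based artifact screening,
taxonomy, diversity, ordination, and two-group statistics — together with
a ground-truthed synthetic-data generator so the entire pipeline is
testable offline, with no sequence downloads.

Intended users: microbiome researchers reanalysing rumen amplicon data
with these specific screening rules, and method developers who need a
small, fully specified, fully tested reference pipeline.

## What it computes

**Read screening** (in order, first failing rule attributed): intact 27F
(`AGAGTTTGATCMTGGCTCAG`) and 519R (`GWATTACCGCGGCKGCTG`) primers matched
IUPAC-aware and exactly; length 400–580 nt inclusive, primers included;
at most 1% of bases with Phred quality < 15 (inclusive). Primers are
trimmed from retained reads.

**OTU inference**: greedy abundance-sorted centroid clustering. The
distance between sequences *a*, *b* is

    d(a,b) = (mismatches + internal gap columns) / aligned columns

of their global alignment (match +1, mismatch −1, gap −2; terminal gap
columns excluded from the counts), and a read joins the first centroid
with d ≤ 0.05, else founds a new OTU.

**Artifact screens** (OTU level, in order): a split-alignment chimera
test (flag iff some breakpoint splits the centroid into two segments each
≥ 98% identical to two *different* references while no single reference
explains ≥ 92% of the whole length); a 5′/3′ end-integrity test (fail iff
more than 5 nt of the centroid are unaligned at either end against the
best equal-or-longer reference); a single-read OTU test (the best-hit
alignment must span the whole sequence with ≤ 1% dissimilar positions).

**Taxonomy**: a naive-Bayes 8-mer classifier with bootstrap confidence
(word probability (n<sub>w</sub> + 0.5)/(N + 1), 100 bootstraps of ⌈W/8⌉
words, ranks below 0.8 confidence reported as "unclassified *parent*"),
plus a separate best-alignment hit giving the closest relative and its
identity percent.

**Diversity**: single rarefaction to 1800 reads; observed OTUs,
bias-corrected Chao1 = S<sub>obs</sub> + F₁(F₁−1)/(2(F₂+1)), Shannon
H = −Σ pᵢ ln pᵢ, Simpson dominance D = Σ nᵢ(nᵢ−1)/(N(N−1)), Good's
coverage 1 − F₁/N; Bray–Curtis distances with principal coordinates
analysis; canonical correspondence analysis against SCFA concentrations
and growth covariates (chi-square standardized matrix, weighted
regression, SVD).

**Statistics**: "main OTUs" are those with mean relative abundance ≥ 1%
in at least one group; group comparisons use the unpaired pooled-variance
Student t-test, computable from raw values or directly from printed
mean ± SEM summaries (t = (m₁−m₂)/√(SEM₁²+SEM₂²) for equal n); Pearson
correlations with p from t = r√(n−2)/√(1−r²); fold changes as plain
ratios. P-values are unadjusted.

## Worked example

```r
library(rumenamp)

refs   <- simulate_reference_db(n_taxa = 12, seed = 7)
design <- simulation_design(n_per_group = 3, n_taxa = 12,
                            reads_per_sample = 250, seed = 11)
sim <- simulate_study(design, refs, "study-dir", rarefy_depth = 150)

cfg <- pipeline_config(rarefy_depth = 150, seed = 5)
res <- run_pipeline(sim$fastq, refs, sim$metadata, cfg)

head(res$qc, 3)
#>   sample_id input_reads fail_primer fail_length fail_quality retained
#> 1     EO_01         250           0           2           16      232
#> 2     EO_02         250           0           3           21      226
#> 3     EO_03         250           0           3           33      214

res$table
#> <otu_table> 12 OTU(s) x 6 sample(s), 1335 reads

table(res$verdicts$verdict)
#>       fail_chimera fail_end_integrity               pass
#>                 12                  1                 12

res$report
#> rumenamp study report (group A = Control, group B = EO)
#>
#> Phylum-level relative abundance (%):
#>   Firmicutes            61.10 +/-  7.73  vs  43.52 +/-  3.55   p = 0.1077
#>   Bacteroidetes         13.14 +/-  0.60  vs  48.83 +/-  3.73   p = 0.0007
#>   Proteobacteria        25.76 +/-  7.14  vs   7.66 +/-  0.39   p = 0.0646
#>
#> 12 main OTU(s); totals per phylum:
#>   Bacteroidetes        A  13.14  B  48.83  (3 OTUs)
#>   Firmicutes           A  61.09  B  43.50  (6 OTUs)
#>   Proteobacteria       A  25.77  B   7.66  (3 OTUs)
```

Reading this output: the 6 per-sample FASTQ files each lose ~1% of reads
to the length rule (planted off-target short amplicons) and ~10% to the
quality rule, as designed. All 12 planted bimeras are caught by the
chimera screen, the 12 surviving OTUs match the 12 simulated taxa, and
the two taxa planted as enriched in the EO group drive the higher
Bacteroidetes (and lower Firmicutes) relative abundance in EO samples,
with the Bacteroidetes difference significant at p = 0.0007.

Published two-group summaries can be re-analysed directly:

```r
cmp <- ttest_from_summary(43.68, 6.92, 10, 73.22, 6.79, 10)
sprintf("t = %.3f, df = %d, p = %.4f", cmp$t_stat, cmp$df, cmp$p_value)
#> "t = -3.047, df = 18, p = 0.0069"
```

A command-line interface mirrors the R API
(`inst/cli/rumenamp <simulate|qc|cluster|screen|classify|diversity|ordinate|report|ttest-summary>`).

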