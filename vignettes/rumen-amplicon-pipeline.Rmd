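---
title: "Methods: the rumenamp amplicon pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the rumenamp amplicon pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`rumenamp` reimplements, as a reusable and fully tested pipeline, the
computational analysis of a two-group rumen microbiome feeding trial based
on 16S rRNA V1–V3 amplicons: read retention screens, operational taxonomic
unit (OTU) inference at a 5% dissimilarity cutoff, reference-based artifact
screens, two-tool taxonomy (rank classifier plus closest-relative search),
rarefied alpha diversity, Bray–Curtis PCoA, canonical correspondence
analysis (CCA) against short-chain fatty acid (SCFA) and growth covariates,
and the pooled t-test / Pearson-correlation statistics behind the abundance
tables such studies print.

The statistical model underlying the group comparisons is deliberately
simple, matching field practice for these tables: per feature (taxon, OTU,
or diversity index), two independent samples of size $n_A$ and $n_B$ are
compared with the pooled-variance Student t-test on relative abundances,
and p-values are reported unadjusted. The compositional nature of relative
abundances is a known caveat (a change in one abundant taxon moves all
others); transformations and compositional methods are out of scope by
design, and the report labels all p-values as unadjusted.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cluster_cutoff` | 0.05 | dissimilarity fraction | V1 is the most variable 16S region; the usual 3% full-length cutoff over-splits V1–V3 amplicons |
| `len_min`, `len_max` | 400, 580 | nt, primers included | the expected V1–V3 amplicon size window; inclusive bounds |
| `lowq_phred`, `max_lowq_frac` | 15, 0.01 | Phred, fraction | at most 1% of bases below Q15, inclusive at exactly 1% |
| `rarefy_depth` | 1800 | reads | common depth before diversity comparison |
| `main_otu_threshold` | 0.01 | fraction | an OTU is "main" iff its mean relative abundance reaches 1% in ≥ 1 group |
| `end_missing_max` | 5 | nt | "more than five" missing end nucleotides fails the end-integrity screen |
| `singleread_max_dissim` | 0.01 | fraction | single-read OTUs must match a reference near-perfectly over their full length |
| `chimera_seg_identity` | 0.98 | fraction | per-segment identity for a chimera call |
| `chimera_whole_identity_max` | 0.92 | fraction | whole-length identity above which one reference "explains" the centroid |
| `chimera_step` | 40 | nt | breakpoint search grid |
| classifier `k`, bootstraps, subsample, confidence | 8, 100, 1/8, 0.8 | — | the rank classifier's standard published parameterisation; the study named only the tool, so these defaults are an assumption and all are configurable |

# Interpretation decisions the source left open

* **"Intact" primers** are matched IUPAC-aware with zero mismatches —
  the strictest consistent reading. A `primer_mismatches` option relaxes
  this.
* **The length window** is applied to the read as received (primers
  included), with inclusive bounds; primers are trimmed afterwards so
  clustering and taxonomy see biological sequence only. The source lists
  the screens before any trimming, which this ordering preserves.
* **Failure attribution** is to the first failing rule in the order
  primer → length → quality; the retain/reject outcome itself is
  order-independent, and a property test asserts this.
* **Group order** in reports defaults to order of appearance in the
  metadata and can be fixed with the `groups` argument.

# Alignment: one scorer, two modes

All sequence comparison uses one scoring scheme (match +1, mismatch −1,
gap −2, linear) implemented in C++, with fully specified tie-breaks
(endpoint: maximal score, then larger row, then larger column; traceback:
diagonal, then up, then left) so results are reproducible bit-for-bit and
an independent pure-R dynamic-programming oracle in the test suite can
check both modes exactly.

* **Global mode** (used for pairwise distances): end gaps are penalized
  during optimization, forcing the alignment to span both sequences;
  terminal gap columns are then excluded from the distance counts so
  trimming-induced length differences are not counted as divergence. A
  free-end-gap distance would be degenerate: the score-optimal alignment
  of two *unrelated* amplicons collapses to a short chance suffix–prefix
  overlap, frequently perfect, giving distance ≈ 0 and destroying cutoff
  clustering. Arguments are ordered canonically before aligning so
  co-optimal traceback choices cannot break symmetry.
* **Semi-global mode** (used for best-hit searches): end gaps free, which
  is correct when a partial centroid is searched against longer
  references. Hits are ranked by alignment *score*, not raw identity —
  identity ranking is won by trivially short perfect overlaps — and the
  winner's identity over its aligned columns is what gets reported.
  A shared-12-mer prefilter skips references that cannot be the best hit;
  it falls back to the full set if it would empty the candidate list, and
  a test asserts it never changes the winner.

**End-overhang semantics.** A pairwise aligner cannot leave overhangs on
both sequences at the same end: damaged centroid ends facing a longer
reference are absorbed as mismatch columns rather than end gaps. The
end-integrity screen therefore trims the best-hit alignment to its
maximum-scoring contiguous column segment (Kadane's algorithm) and counts
centroid bases outside that segment as unaligned overhang — recovering the
local-alignment semantics that a BLAST-style screen has natively.

**Chimera breakpoints.** Breakpoints are scanned on the 40-nt grid. The
grid alone misses bimeras of deeply divergent parents, because a ±20 nt
offset pollutes one segment past the 98% rule. When the two terminal
40-nt windows are each near-perfectly explained by two different
references but no grid point passes, the breakpoint is refined from the
Kadane-trimmed alignment against the 5′-anchor parent and re-tested under
the unchanged rule. A second caveat is inherent to the thresholds
themselves: a bimera whose parents are only ~10% divergent has
whole-length identity ≥ 0.95 to its major parent whenever the breakpoint
is off-centre, which is above the 0.92 "explained" ceiling — such bimeras
are undetectable by this test regardless of the search strategy. The
screen is therefore only claimed (and only tested) to reach its ≥ 0.9
sensitivity target on bimeras of deeply divergent parents.

# Clustering

Reads are dereplicated; unique sequences are processed by multiplicity
(descending), then length (descending), then lexicographic order, join the
*first* existing centroid within the cutoff, or found a new OTU. This
greedy abundance-sorted scheme is the de-facto standard for cutoff OTUs,
but the original study used unpublished custom scripts, so no equivalence
with its exact OTU inventory is claimed; an exhaustive single-linkage
oracle is kept in the tests to expose the (expected) method-dependence of
OTU counts, and on well-separated synthetic data both methods recover the
planted partition exactly. An internal gap run of length $g$ counts as $g$
difference columns (no gap-run compression). A conservative shared-8-mer
lower bound on the distance skips provably-too-distant centroid
comparisons; tests assert prefilter on/off equivalence.

# Diversity and ordination conventions

* **Simpson** is reported as the dominance form
  $D = \sum n_i(n_i-1)/(N(N-1))$ (low = diverse), consistent with the
  low printed values (~0.15) in this literature; $1-D$ is a trivial
  transform left to the user.
* **Chao1** uses the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$
  so zero doubletons are defined.
* **Rarefaction** is a single draw without replacement (as in the source),
  seeded; an `iters` argument averages draws but defaults to 1.
* **PCoA**: Gower double-centering of $-\tfrac12 D^2$; coordinates only
  from positive eigenvalues; negative eigenvalues reported, not used; axis
  signs fixed so the largest-magnitude loading is positive.
* **CCA** follows the textbook weighted-regression formulation: total
  inertia equals the table's chi-square statistic over its grand total
  (hand-checked in the tests), eigenvalues are squared singular values of
  the fitted chi-square-standardized matrix, species scores are scaled by
  the singular values (scaling 2), and biplot arrows are weighted
  correlations of covariates with site axes scaled by relative singular
  values. Results are checked against an independent implementation
  (vegan) in the test suite. Any covariate subset may be supplied; the
  ordination records which was used.

# The synthetic world

The generator's defaults *are* the study conditions the pipeline targets:
2 treatment groups ("EO", "Control") × 10 samples, 2000 reads per sample,
log-normal community abundances (σ = 1) over 40 taxa, two planted
EO-enriched taxa at 7.2× and 20.2×, per-base substitution errors at 0.5%,
and 1% each of three artifact classes. Values the source did not state
were fixed once at field-realistic levels and not revisited:

* `sample_sigma = 0.5`: per-sample log-normal jitter on taxon abundances
  (biological replicate noise);
* `poor_quality_frac = 0.1`: fraction of reads drawn with a 2% low-quality
  base rate (most fail the 1% rule), while the remaining reads use 0.2%
  rejection-sampled to always pass — so realized low-quality fractions
  bracket the QC threshold and clean-design retention is exactly 100%;
* SCFA and growth covariates: normal draws with group means anchored to
  the printed study values (e.g. propionate 40.25 vs 31.06 mM) and
  plausible spreads.

The reference database plants its divergence structure explicitly:
420–540 nt cores (so primer-flanked amplicons stay inside the 400–580 nt
read window) flanked by one concrete instantiation of the 27F/519R primer
sites; 6–9% dissimilarity within a genus (disjoint mutation sets from a
shared genus root); independent random roots between genera (~70%
divergence, far above the ≥ 10% requirement). Every generated database is
re-verified with the package's own aligner and generation fails loudly if
a band is violated.

Artifact classes: bimeras are two-parent single-breakpoint joins with the
breakpoint uniform in the middle 50% of the amplicon (so both parents stay
detectable); "truncated" reads have 8–14 terminal core bases *replaced* by
random sequence — a read genuinely missing its terminal bases would also
be missing its primer and die at QC, never reaching the OTU-level end
screen this class exists to exercise; off-target reads are short random
amplicons (< 400 nt with primers). All reads, artifact or not, receive
errors and quality strings; every read carries a ground-truth label.

What the generator does *not* emulate — and what a green test therefore
does not establish: realistic MiSeq error profiles (quality decay along
the read, indel hotspots), correlated errors, paired-end structure,
phylogenetically realistic divergence (lineages are assigned from a fixed
pool; between-phylum distances are not larger than between-genus
distances), 16S copy-number variation, or abundance–sequence-quality
correlations.

# Numerical and degenerate-input conventions

* Summary-form and raw-form t-tests agree to 1e-12 on the same data; with
  both SEMs zero the comparison is degenerate (p = 1 if means equal, else
  p = 0 with a `degenerate` flag).
* `fold_change(a, 0)` returns `Inf` as the undefined-ratio marker.
* Percent tables print to 2 decimals; per-phylum Total rows are column
  sums of the *printed-precision* values, so printed tables are internally
  consistent. (The source study's own Firmicutes totals are not — its
  printed entries sum to 32.30/50.54 against printed totals of
  32.94/50.63 — which is why one acceptance test in this package is
  deliberately red.)
* Rarefaction errors on samples below depth, naming them; all-zero count
  vectors error; constant or collinear CCA covariates error, naming the
  offending columns.
* Every stochastic step (simulation, rarefaction, classifier bootstrap)
  takes a seed and restores the caller's RNG state.

# Known limitations

The pipeline is desk-scale by design: exhaustive pairwise alignment
against a curated local reference FASTA stands in for BLAST against NCBI
nt, the split-alignment chimera test stands in for UCHIME/ChimeraSlayer,
and nomenclature validation against LPSN is out of scope (the reference
taxonomy is assumed curated). The source study's sequence-level results
(4154 OTUs from 347,254 reads) require its archived raw data and are not
reproduction targets; what is reproduced exactly are its printed
statistical summaries and the behavior of every stated screening rule.
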