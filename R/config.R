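#' Pipeline configuration
#'
#' Collects every threshold used across the pipeline in one validated object.
#' The defaults are the study conditions the package is built around: OTU
#' clustering at 5% dissimilarity of the V1-V3 amplicon, a 400-580 nt read
#' length window (primers included), at most 1% of bases below Phred 15,
#' rarefaction to 1800 reads, a 1% mean relative abundance rule for "main"
#' OTUs, a 5 nt tolerance for missing alignment ends, a 1% dissimilarity
#' tolerance for single-read OTUs, and a 0.05 significance level.
#'
#' @param cluster_cutoff OTU clustering cutoff as a dissimilarity fraction.
#' @param len_min,len_max inclusive read length window in nt, measured on the
#'   read as received (primers included).
#' @param max_lowq_frac maximum tolerated fraction of low-quality bases.
#' @param lowq_phred Phred score below which a base counts as low quality.
#' @param rarefy_depth reads drawn per sample before diversity analysis.
#' @param main_otu_threshold mean relative abundance (fraction) an OTU must
#'   reach in at least one group to be a "main" OTU.
#' @param end_missing_max maximum nt allowed missing from either alignment end
#'   before an OTU fails the end-integrity screen (fail when strictly more).
#' @param singleread_max_dissim maximum dissimilar fraction tolerated for a
#'   single-read OTU against its best full-length hit.
#' @param alpha significance level for two-group comparisons.
#' @param seed integer seed controlling every stochastic step.
#' @param fwd_primer,rev_primer IUPAC primer sequences (27F / 519R defaults).
#' @param otu_prefix prefix used when naming OTUs.
#' @param primer_mismatches mismatches tolerated inside a primer ("intact"
#'   means exact, so the default is 0).
#' @param chimera_seg_identity minimum per-segment identity for the
#'   split-alignment chimera call.
#' @param chimera_whole_identity_max whole-length identity above which a
#'   centroid is considered explained by a single reference.
#' @param chimera_step breakpoint search step in nt.
#'
#' @return an object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$cluster_cutoff
#' @export
pipeline_config <- function(cluster_cutoff = 0.05,
                            len_min = 400L,
                            len_max = 580L,
                            max_lowq_frac = 0.01,
                            lowq_phred = 15L,
                            rarefy_depth = 1800L,
                            main_otu_threshold = 0.01,
                            end_missing_max = 5L,
                            singleread_max_dissim = 0.01,
                            alpha = 0.05,
                            seed = 1L,
                            fwd_primer = "AGAGTTTGATCMTGGCTCAG",
                            rev_primer = "GWATTACCGCGGCKGCTG",
                            otu_prefix = "OTU-",
                            primer_mismatches = 0L,
                            chimera_seg_identity = 0.98,
                            chimera_whole_identity_max = 0.92,
                            chimera_step = 40L) {
  cfg <- list(
    cluster_cutoff = cluster_cutoff,
    len_min = as.integer(len_min), len_max = as.integer(len_max),
    max_lowq_frac = max_lowq_frac, lowq_phred = as.integer(lowq_phred),
    rarefy_depth = as.integer(rarefy_depth),
    main_otu_threshold = main_otu_threshold,
    end_missing_max = as.integer(end_missing_max),
    singleread_max_dissim = singleread_max_dissim,
    alpha = alpha, seed = as.integer(seed),
    fwd_primer = toupper(fwd_primer), rev_primer = toupper(rev_primer),
    otu_prefix = otu_prefix,
    primer_mismatches = as.integer(primer_mismatches),
    chimera_seg_identity = chimera_seg_identity,
    chimera_whole_identity_max = chimera_whole_identity_max,
    chimera_step = as.integer(chimera_step)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$cluster_cutoff > 0, cfg$cluster_cutoff < 1,
    cfg$len_min <= cfg$len_max, cfg$len_min > 0,
    cfg$max_lowq_frac >= 0, cfg$max_lowq_frac <= 1,
    cfg$lowq_phred >= 0,
    cfg$rarefy_depth > 0,
    cfg$main_otu_threshold >= 0, cfg$main_otu_threshold <= 1,
    cfg$end_missing_max >= 0,
    cfg$singleread_max_dissim >= 0, cfg$singleread_max_dissim <= 1,
    cfg$alpha > 0, cfg$alpha < 1
  )
  for (p in c(cfg$fwd_primer, cfg$rev_primer)) {
    chars <- strsplit(p, "", fixed = TRUE)[[1L]]
    bad <- setdiff(chars, strsplit(IUPAC_CHARS, "")[[1L]])
    if (nchar(p) == 0L || length(bad) > 0L)
      stop("primer contains non-IUPAC characters: ", paste(bad, collapse = ""))
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("rumenamp pipeline configuration\n")
  cat(sprintf("  OTU cutoff         : %.3g dissimilarity\n", x$cluster_cutoff))
  cat(sprintf("  length window      : %d-%d nt (primers included)\n", x$len_min, x$len_max))
  cat(sprintf("  quality rule       : <= %.3g%% of bases below Q%d\n",
              100 * x$max_lowq_frac, x$lowq_phred))
  cat(sprintf("  rarefaction depth  : %d reads\n", x$rarefy_depth))
  cat(sprintf("  main OTU rule      : mean >= %.3g%% in one group\n",
              100 * x$main_otu_threshold))
  cat(sprintf("  primers            : %s / %s\n", x$fwd_primer, x$rev_primer))
  invisible(x)
}
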