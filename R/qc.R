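# Read retention screens applied to assembled V1-V3 amplicon reads, in fixed
# order: (1) intact primers at both termini, (2) 400-580 nt length window
# measured with primers still attached, (3) no more than 1% of bases below
# Phred 15. A read failing several rules is attributed to the first failing
# rule only, so the per-sample report rows sum to the input read count.
# Primers are trimmed from retained reads before they are emitted, so
# clustering and taxonomy operate on biological sequence only.

iupac_regex <- function(primer) {
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1L]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad))
    stop("non-IUPAC character in primer: ", paste(chars[bad], collapse = ""))
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Test a read for intact primers at both ends
#'
#' The forward primer must match at position 1 and the reverse complement of
#' the reverse primer at the 3' terminus. Matching is IUPAC-aware (an `M` in
#' the primer matches `A` or `C` in the read) and exact: "intact" means zero
#' mismatches unless `max_mismatch` is raised.
#'
#' @param seq read sequence (character scalar).
#' @param fwd,rev IUPAC primer strings (e.g. 27F and 519R).
#' @param max_mismatch mismatches tolerated inside each primer (default 0).
#' @return `TRUE` or `FALSE`.
#' @export
has_intact_primers <- function(seq, fwd, rev, max_mismatch = 0L) {
  stopifnot(nchar(fwd) > 0L, nchar(rev) > 0L)
  seq <- toupper(seq)
  nf <- nchar(fwd)
  nr <- nchar(rev)
  if (nchar(seq) < nf + nr) return(FALSE)
  rcrev <- revcomp(toupper(rev))
  if (max_mismatch == 0L) {
    ok_f <- grepl(paste0("^", iupac_regex(fwd)), seq)
    ok_r <- grepl(paste0(iupac_regex(rcrev), "$"), seq)
    return(ok_f && ok_r)
  }
  mm <- function(primer, target) {
    pc <- strsplit(toupper(primer), "")[[1L]]
    tc <- strsplit(target, "")[[1L]]
    bad <- !pc %in% names(IUPAC_SETS)
    if (any(bad))
      stop("non-IUPAC character in primer: ", paste(pc[bad], collapse = ""))
    sum(!mapply(function(p, t) t %in% IUPAC_SETS[[p]], pc, tc))
  }
  mm(fwd, substr(seq, 1L, nf)) <= max_mismatch &&
    mm(rcrev, substr(seq, nchar(seq) - nr + 1L, nchar(seq))) <= max_mismatch
}

#' Test a read against the base-quality rule
#'
#' Passes iff the fraction of bases with Phred score strictly below
#' `lowq_phred` is at most `max_lowq_frac` (inclusive at the boundary:
#' exactly 1% low-quality bases passes under the defaults).
#'
#' @param quals integer vector of Phred scores for one read.
#' @param lowq_phred low-quality threshold (default 15).
#' @param max_lowq_frac maximum tolerated low-quality fraction (default 0.01).
#' @return `TRUE` or `FALSE`.
#' @export
passes_quality <- function(quals, lowq_phred = 15L, max_lowq_frac = 0.01) {
  stopifnot(length(quals) > 0L)
  sum(quals < lowq_phred) / length(quals) <= max_lowq_frac
}

#' Screen reads for retention and trim primers
#'
#' Applies the three retention rules in order primer -> length -> quality,
#' attributing each rejected read to its first failing rule. Retained reads
#' are emitted with both primers trimmed (sequence and qualities).
#'
#' @param reads a [quality_reads] object for one sample.
#' @param cfg a [pipeline_config] supplying primers and thresholds.
#' @return a list with `reads` (trimmed retained [quality_reads]), `report`
#'   (one-row data frame: `input_reads`, `fail_primer`, `fail_length`,
#'   `fail_quality`, `retained`) and `retained_ids`.
#' @export
screen_reads <- function(reads, cfg = pipeline_config()) {
  stopifnot(inherits(reads, "quality_reads"))
  n <- length(reads)
  nf <- nchar(cfg$fwd_primer)
  nr <- nchar(cfg$rev_primer)

  ok_primer <- vapply(reads$seq, has_intact_primers, logical(1),
                      fwd = cfg$fwd_primer, rev = cfg$rev_primer,
                      max_mismatch = cfg$primer_mismatches,
                      USE.NAMES = FALSE)
  len <- nchar(reads$seq)
  ok_length <- len >= cfg$len_min & len <= cfg$len_max
  ok_quality <- vapply(reads$quals, passes_quality, logical(1),
                       lowq_phred = cfg$lowq_phred,
                       max_lowq_frac = cfg$max_lowq_frac)

  fail_primer <- !ok_primer
  fail_length <- ok_primer & !ok_length
  fail_quality <- ok_primer & ok_length & !ok_quality
  keep <- ok_primer & ok_length & ok_quality

  trimmed <- quality_reads(
    reads$read_id[keep],
    substr(reads$seq[keep], nf + 1L, len[keep] - nr),
    lapply(reads$quals[keep], function(q) q[(nf + 1L):(length(q) - nr)])
  )
  report <- data.frame(
    input_reads = n,
    fail_primer = sum(fail_primer),
    fail_length = sum(fail_length),
    fail_quality = sum(fail_quality),
    retained = sum(keep)
  )
  list(reads = trimmed, report = report, retained_ids = reads$read_id[keep])
}

#' Screen a set of per-sample FASTQ files
#'
#' @param fastq_paths named character vector of FASTQ paths (names are sample
#'   ids; unnamed paths use the file name stem).
#' @param cfg a [pipeline_config].
#' @return a list with `reads` (data frame `sample_id`, `read_id`, `seq` of
#'   retained, trimmed reads) and `report` (per-sample QC rows).
#' @export
screen_study <- function(fastq_paths, cfg = pipeline_config()) {
  ids <- names(fastq_paths)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- tools::file_path_sans_ext(basename(fastq_paths))
  out <- lapply(seq_along(fastq_paths), function(i) {
    scr <- screen_reads(read_fastq(fastq_paths[[i]]), cfg)
    list(df = if (length(scr$reads)) data.frame(sample_id = ids[i],
                                                read_id = scr$reads$read_id,
                                                seq = scr$reads$seq,
                                                stringsAsFactors = FALSE)
         else NULL,
         report = cbind(sample_id = ids[i], scr$report))
  })
  list(
    reads = do.call(rbind, Filter(Negate(is.null), lapply(out, `[[`, "df"))),
    report = do.call(rbind, lapply(out, `[[`, "report"))
  )
}
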