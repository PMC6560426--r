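# Post-clustering OTU validity screens, applied in fixed order:
# chimera -> end integrity -> single-read. All three rest on the same
# best-hit alignment search against the local curated reference set; the
# chimera test is a split-alignment test (a fully specified stand-in for
# heuristic chimera detectors): a centroid is flagged when some breakpoint
# splits it into two segments that are each near-perfectly explained by two
# different references while no single reference explains the whole length.

#' Split-alignment chimera screen for one centroid
#'
#' Flags the centroid as chimeric iff there is a breakpoint `b` (searched on
#' a grid of `step` nt) and a parent pair (P, Q), P != Q, with
#' `identity(centroid[1..b], P) >= seg_identity` and
#' `identity(centroid[(b+1)..L], Q) >= seg_identity`, while the best
#' whole-length identity to any single reference is `<= whole_identity_max`.
#' Breakpoints are scanned on the coarse grid first; when both terminal
#' windows are near-perfectly explained by two different references but no
#' grid point satisfies the per-segment rule, the breakpoint is refined
#' from the alignment against the 5'-anchor parent and re-tested (see the
#' implementation note in the source). Centroids shorter than two windows
#' are not evaluable and pass with a warning flag in the evidence.
#'
#' @param centroid centroid DNA string.
#' @param refs a `reference_db` (at least 2 references).
#' @param seg_identity per-segment identity threshold (default 0.98).
#' @param whole_identity_max whole-length identity at or below which a single
#'   reference is considered insufficient to explain the centroid (0.92).
#' @param step breakpoint grid step in nt (default 40).
#' @param prefilter passed to the best-hit search.
#' @return a list: `chimeric` (logical), `best_whole_id`, `best_whole_identity`,
#'   and when flagged `parent_a`, `parent_b`, `breakpoint`; `evaluable` is
#'   FALSE when the centroid was too short to test.
#' @export
chimera_screen <- function(centroid, refs, seg_identity = 0.98,
                           whole_identity_max = 0.92, step = 40L,
                           prefilter = TRUE) {
  stopifnot(nrow(refs) >= 2L)
  L <- nchar(centroid)
  if (L < 2L * step) {
    return(list(chimeric = FALSE, evaluable = FALSE,
                best_whole_id = NA_character_,
                best_whole_identity = NA_real_))
  }
  profiles <- lapply(refs$seq, kmer_profile, k = 12L)
  whole <- best_hit(centroid, refs, prefilter = prefilter,
                    ref_profiles = profiles)
  out <- list(chimeric = FALSE, evaluable = TRUE,
              best_whole_id = whole$ref_id,
              best_whole_identity = whole$identity)
  if (whole$identity > whole_identity_max) return(out)

  eval_breakpoint <- function(b) {
    pre <- best_hit(substr(centroid, 1L, b), refs, prefilter = prefilter,
                    ref_profiles = profiles)
    if (pre$identity < seg_identity) return(NULL)
    suf <- best_hit(substr(centroid, b + 1L, L), refs, prefilter = prefilter,
                    ref_profiles = profiles)
    if (suf$identity < seg_identity) return(NULL)
    if (pre$ref_id == suf$ref_id) return(NULL)
    list(parent_a = pre$ref_id, parent_b = suf$ref_id, breakpoint = b,
         strength = min(pre$identity, suf$identity))
  }

  best_call <- NULL
  for (b in seq.int(step, L - step, by = step)) {
    call <- eval_breakpoint(b)
    if (!is.null(call) &&
        (is.null(best_call) || call$strength > best_call$strength))
      best_call <- call
  }

  # The coarse grid can straddle the true breakpoint by up to step/2 nt,
  # which pollutes one segment enough to miss the per-segment identity rule
  # when the parents are deeply divergent. If the two terminal windows are
  # each near-perfectly explained by two different references, refine: the
  # maximum-scoring aligned segment of the centroid against the 5'-anchor
  # parent ends at the true breakpoint, and that position is re-tested with
  # the full per-segment rule.
  if (is.null(best_call)) {
    anchor5 <- best_hit(substr(centroid, 1L, step), refs,
                        prefilter = prefilter, ref_profiles = profiles)
    anchor3 <- best_hit(substr(centroid, L - step + 1L, L), refs,
                        prefilter = prefilter, ref_profiles = profiles)
    if (anchor5$identity >= seg_identity && anchor3$identity >= seg_identity &&
        anchor5$ref_id != anchor3$ref_id) {
      ov <- local_overhangs(centroid,
                            refs$seq[refs$ref_id == anchor5$ref_id][1L])
      b_star <- L - ov$overhang_3p
      if (b_star >= step && b_star <= L - step)
        best_call <- eval_breakpoint(b_star)
    }
  }

  if (!is.null(best_call)) {
    out$chimeric <- TRUE
    out$parent_a <- best_call$parent_a
    out$parent_b <- best_call$parent_b
    out$breakpoint <- best_call$breakpoint
  }
  out
}

# Unaligned end overhangs of `a` in the best local trimming of the
# semi-global alignment. The pairwise aligner cannot leave overhangs on
# both sequences at the same end (one of them always absorbs the other as
# mismatch columns), so damaged centroid ends facing a longer reference
# show up as terminal runs of negative-scoring columns instead of end
# gaps. Trimming the alignment to its maximum-scoring contiguous column
# segment (Kadane) recovers the unaligned-end semantics of a local
# aligner; centroid bases outside the kept segment count as overhang.
local_overhangs <- function(a, b) {
  al <- align_pair(a, b, return_alignment = TRUE)
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1L]]
  colscore <- ifelse(ca == "-" | cb == "-", -2, ifelse(ca == cb, 1, -1))
  n <- length(colscore)
  best <- -Inf; best_i <- 1L; best_j <- 0L
  cur <- 0; cur_start <- 1L
  for (i in seq_len(n)) {
    if (cur <= 0) { cur <- 0; cur_start <- i }
    cur <- cur + colscore[i]
    if (cur > best) { best <- cur; best_i <- cur_start; best_j <- i }
  }
  lead_a <- if (best_i > 1L) sum(ca[seq_len(best_i - 1L)] != "-") else 0L
  trail_a <- if (best_j < n) sum(ca[(best_j + 1L):n] != "-") else 0L
  list(overhang_5p = al$end_gap_a_5p + lead_a,
       overhang_3p = al$end_gap_a_3p + trail_a)
}

#' 5'/3' end-integrity screen for one centroid
#'
#' The best hit is the best-scoring reference of equal or longer length
#' (see [best_hit_identity()] for the ranking). The centroid fails iff its
#' unaligned overhang
#' (centroid bases outside the best locally trimmed alignment, see the
#' implementation note above) exceeds `end_missing_max` nt at either end
#' ("more than five" under the default). With no reference of sufficient
#' length the OTU is not evaluable and passes with a warning flag.
#'
#' @param centroid centroid DNA string.
#' @param refs a `reference_db`.
#' @param end_missing_max maximum tolerated end overhang in nt (default 5).
#' @param prefilter passed to the best-hit search.
#' @return a list: `fail` (logical), `best_hit_id`, `identity`,
#'   `overhang_5p`, `overhang_3p`, `evaluable`.
#' @export
end_integrity_screen <- function(centroid, refs, end_missing_max = 5L,
                                 prefilter = TRUE) {
  stopifnot(nrow(refs) >= 1L)
  long_enough <- nchar(refs$seq) >= nchar(centroid)
  if (!any(long_enough)) {
    return(list(fail = FALSE, evaluable = FALSE, best_hit_id = NA_character_,
                identity = NA_real_, overhang_5p = NA_integer_,
                overhang_3p = NA_integer_))
  }
  sub <- refs[long_enough, , drop = FALSE]
  hit <- best_hit(centroid, sub, prefilter = prefilter)
  ov <- local_overhangs(centroid, sub$seq[hit$ref_index])
  list(fail = ov$overhang_5p > end_missing_max ||
         ov$overhang_3p > end_missing_max,
       evaluable = TRUE, best_hit_id = hit$ref_id, identity = hit$identity,
       overhang_5p = ov$overhang_5p, overhang_3p = ov$overhang_3p)
}

#' Single-read OTU screen
#'
#' Applies only to OTUs containing exactly one read: the best-hit alignment
#' must span the entire OTU sequence (zero overhang at both ends) and the
#' dissimilar positions (mismatches plus internal gaps) may not exceed
#' `max_dissim` of the OTU length (inclusive: 1% exactly passes).
#'
#' @param centroid centroid DNA string of a single-read OTU.
#' @param refs a `reference_db`.
#' @param max_dissim tolerated dissimilar fraction (default 0.01).
#' @param prefilter passed to the best-hit search.
#' @return a list: `fail`, `best_hit_id`, `identity`, `dissim_frac`,
#'   `spans` (whether the alignment covered the full OTU).
#' @export
singleread_screen <- function(centroid, refs, max_dissim = 0.01,
                              prefilter = TRUE) {
  stopifnot(nrow(refs) >= 1L)
  hit <- best_hit(centroid, refs, prefilter = prefilter)
  al <- hit$alignment
  spans <- al$end_gap_a_5p == 0L && al$end_gap_a_3p == 0L
  dissim <- (al$mismatches + al$internal_gaps) / nchar(centroid)
  list(fail = !spans || dissim > max_dissim,
       best_hit_id = hit$ref_id, identity = hit$identity,
       dissim_frac = dissim, spans = spans)
}

#' Apply all artifact screens to an OTU table
#'
#' Screens run in order chimera -> end integrity -> single-read; an OTU is
#' attributed to the first failing screen and removed together with its
#' reads. A verdict row is logged for every OTU. Applying the screens twice
#' gives the same table as applying them once.
#'
#' @param table an [otu_table].
#' @param refs a `reference_db`.
#' @param cfg a [pipeline_config] supplying the thresholds.
#' @param prefilter passed to the best-hit searches.
#' @return a list with `table` (filtered [otu_table]) and `verdicts` (data
#'   frame: `otu_id`, `verdict`, `best_hit_id`, `best_hit_identity`,
#'   `overhang_5p`, `overhang_3p`, `parent_a`, `parent_b`, `breakpoint`).
#' @export
apply_screens <- function(table, refs, cfg = pipeline_config(),
                          prefilter = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  counts <- otu_counts(table)
  cents <- otu_centroids(table)
  totals <- rowSums(counts)

  rows <- lapply(seq_along(cents), function(i) {
    row <- data.frame(otu_id = names(cents)[i], verdict = "pass",
                      best_hit_id = NA_character_,
                      best_hit_identity = NA_real_,
                      overhang_5p = NA_integer_, overhang_3p = NA_integer_,
                      parent_a = NA_character_, parent_b = NA_character_,
                      breakpoint = NA_integer_, stringsAsFactors = FALSE)
    ch <- chimera_screen(cents[i], refs,
                         seg_identity = cfg$chimera_seg_identity,
                         whole_identity_max = cfg$chimera_whole_identity_max,
                         step = cfg$chimera_step, prefilter = prefilter)
    row$best_hit_id <- ch$best_whole_id
    row$best_hit_identity <- ch$best_whole_identity
    if (isTRUE(ch$chimeric)) {
      row$verdict <- "fail_chimera"
      row$parent_a <- ch$parent_a
      row$parent_b <- ch$parent_b
      row$breakpoint <- ch$breakpoint
      return(row)
    }
    ei <- end_integrity_screen(cents[i], refs,
                               end_missing_max = cfg$end_missing_max,
                               prefilter = prefilter)
    if (isTRUE(ei$evaluable)) {
      row$best_hit_id <- ei$best_hit_id
      row$best_hit_identity <- ei$identity
      row$overhang_5p <- ei$overhang_5p
      row$overhang_3p <- ei$overhang_3p
      if (ei$fail) {
        row$verdict <- "fail_end_integrity"
        return(row)
      }
    }
    if (totals[i] == 1L) {
      sr <- singleread_screen(cents[i], refs,
                              max_dissim = cfg$singleread_max_dissim,
                              prefilter = prefilter)
      if (sr$fail) row$verdict <- "fail_singleread"
    }
    row
  })
  verdicts <- do.call(rbind, rows)

  keep <- verdicts$verdict == "pass"
  filtered <- otu_table(counts[keep, , drop = FALSE], cents[keep])
  list(table = filtered, verdicts = verdicts)
}
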