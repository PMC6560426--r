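# Pairwise alignment primitives shared by clustering, artifact screens and
# best-hit taxonomy. One scoring scheme is used throughout: match +1,
# mismatch -1, gap -2, end gaps free. Distances and identities are computed
# over the aligned columns only (end-gap columns excluded), so length
# differences left over from trimming are not counted as divergence.

#' Align two sequences
#'
#' Two modes share one scoring scheme. The default semi-global mode leaves
#' end gaps free on both sequences, which is right for searching a partial
#' query against longer references. The `global = TRUE` mode penalizes end
#' gaps during optimization — forcing the alignment to span both sequences —
#' and then reports terminal gap runs as end gaps excluded from the column
#' counts; this is the mode distances are computed in, because free end
#' gaps would let the best-scoring alignment of two unrelated amplicons
#' shrink to a short chance overlap.
#'
#' @param a,b DNA strings (case-insensitive; any non-identical character pair
#'   counts as a mismatch).
#' @param return_alignment also return the gapped aligned strings.
#' @param global penalize end gaps during optimization (see above).
#' @return a list with the score, column counts (`matches`, `mismatches`,
#'   `internal_gaps`, `columns`), the 1-based aligned region bounds
#'   (`a_start`..`a_end`, `b_start`..`b_end`) and the end-gap (overhang)
#'   lengths `end_gap_a_5p`, `end_gap_a_3p`, `end_gap_b_5p`, `end_gap_b_3p`.
#' @examples
#' align_pair("ACGTACGT", "ACGTTCGT")$mismatches
#' @export
align_pair <- function(a, b, return_alignment = FALSE, global = FALSE) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  .align_pair_cpp(toupper(a), toupper(b), return_alignment, global)
}

#' Pairwise genetic distance
#'
#' Distance is `(mismatches + internal gap columns) / aligned columns` of
#' the global alignment, with terminal gap columns excluded from both
#' counts; a run of g internal gap positions counts as g difference
#' columns. Symmetric (arguments are ordered canonically before aligning,
#' so co-optimal traceback choices cannot break symmetry) and in \[0, 1\].
#'
#' @param a,b DNA strings.
#' @return the dissimilarity fraction.
#' @examples
#' pairwise_distance("AAAACCCC", "AAAACCCC")  # 0
#' @export
pairwise_distance <- function(a, b) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  al <- align_pair(a, b, global = TRUE)
  if (al$columns == 0L) return(1)
  (al$mismatches + al$internal_gaps) / al$columns
}

#' Pairwise alignment identity
#'
#' `matches / aligned columns`, end gaps excluded; the complement of
#' [pairwise_distance()].
#'
#' @param a,b DNA strings.
#' @return identity fraction in \[0, 1\].
#' @export
alignment_identity <- function(a, b) {
  al <- align_pair(a, b)
  if (al$columns == 0L) return(0)
  al$matches / al$columns
}

# Sorted k-mer multiset (2-bit packed); used by the search prefilters.
kmer_profile <- function(seq, k = 12L) .kmer_profile_cpp(seq, as.integer(k))

shared_kmers <- function(p, q) .shared_kmers_cpp(p, q)

# Exhaustive best-hit search against a reference set. The hit is the
# reference maximizing the alignment SCORE, with ties broken by higher
# identity and then lexicographically smallest ref_id; the winner's
# identity (matches over aligned columns) is reported. Ranking by raw
# identity would be degenerate under free-end-gap alignment: a spurious
# 15-25 nt perfect overlap against an unrelated reference yields identity
# 1.0 and would outrank a genuine 97% full-length hit, so the score -- which
# weighs alignment length as well as agreement -- carries the intended
# "closest relative" semantics.
#
# The optional shared-12-mer prefilter is purely for speed: references
# sharing no 12-mer with the query are skipped, and if the filter removes
# everything the search falls back to the full set, so the best hit never
# changes.
best_hit <- function(query, refs, prefilter = TRUE, ref_profiles = NULL) {
  stopifnot(nrow(refs) >= 1L)
  idx <- seq_len(nrow(refs))
  if (prefilter && nchar(query) >= 12L) {
    qp <- kmer_profile(query, 12L)
    if (is.null(ref_profiles))
      ref_profiles <- lapply(refs$seq, kmer_profile, k = 12L)
    hitcount <- vapply(ref_profiles, shared_kmers, integer(1), q = qp)
    keep <- which(hitcount >= 1L)
    if (length(keep)) idx <- keep
  }
  best <- NULL
  best_score <- -Inf
  best_id <- -1
  best_ref <- ""
  for (i in idx) {
    al <- align_pair(query, refs$seq[i])
    ident <- if (al$columns == 0L) 0 else al$matches / al$columns
    better <- al$score > best_score ||
      (al$score == best_score &&
         (ident > best_id ||
            (ident == best_id && refs$ref_id[i] < best_ref)))
    if (better) {
      best_score <- al$score
      best_id <- ident
      best_ref <- refs$ref_id[i]
      best <- c(al, list(ref_index = i))
    }
  }
  list(ref_id = best_ref, ref_index = best$ref_index, identity = best_id,
       score = best_score, alignment = best)
}
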