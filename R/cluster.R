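# Greedy abundance-sorted centroid clustering at a fixed dissimilarity
# cutoff (default 5%), the de-facto standard for cutoff-based OTUs. Reads
# are dereplicated first; unique sequences are processed in order of
# multiplicity (descending), then length (descending), then sequence
# (lexicographic), so clustering is fully deterministic. A sequence joins
# the first existing centroid at distance <= cutoff, else founds a new OTU.

#' Construct an OTU table
#'
#' @param counts integer matrix, OTUs x samples.
#' @param centroids character vector of centroid sequences named by OTU id
#'   (same order as `counts` rows).
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, centroids) {
  stopifnot(is.matrix(counts), nrow(counts) == length(centroids))
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) rownames(counts) <- names(centroids)
  stopifnot(nrow(counts) == 0L ||
              identical(rownames(counts), names(centroids)))
  if (nrow(counts) && any(rowSums(counts) < 1L))
    stop("every OTU must contain at least one read")
  structure(list(counts = counts, centroids = centroids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTU(s) x %d sample(s), %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' OTU count matrix
#' @param x an `otu_table`.
#' @return integer matrix, OTUs x samples.
#' @export
otu_counts <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  x$counts
}

#' OTU centroid sequences
#' @param x an `otu_table`.
#' @return named character vector.
#' @export
otu_centroids <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  x$centroids
}

#' Relative abundance in percent
#'
#' Columns sum to 100 (before any rounding); computed on demand from the
#' integer counts, never stored.
#'
#' @param x an `otu_table` or a counts matrix (OTUs x samples).
#' @return numeric matrix of percentages.
#' @export
relative_abundance <- function(x) {
  counts <- if (inherits(x, "otu_table")) x$counts else x
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample(s) with zero reads: ",
                             paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 2L, totals, "/") * 100
}

# Conservative lower bound on the pairwise distance from shared-8-mer
# counts: an alignment with d difference columns can destroy at most 8*d of
# the shorter sequence's 8-mers, and end overhangs at most |la - lb| more.
# Used (when `prefilter = TRUE`) to skip alignments that provably exceed
# the cutoff; a 0.02 safety margin keeps the filter strictly conservative.
kmer_distance_lower_bound <- function(shared, la, lb, k = 8L) {
  qmin <- min(la, lb) - k + 1L
  max(0, (qmin - shared - abs(la - lb)) / (k * max(la, lb)))
}

#' Cluster reads into OTUs by greedy centroid assignment
#'
#' @param seqs character vector of (primer-trimmed) read sequences.
#' @param sample_ids character vector assigning each read to a sample.
#' @param cutoff dissimilarity cutoff (default 0.05).
#' @param prefix OTU id prefix; ids are zero-padded ordinals in founding
#'   order.
#' @param prefilter use the shared-k-mer lower bound to skip centroid
#'   comparisons that provably exceed the cutoff (never changes the result,
#'   only the speed).
#' @return an [otu_table] whose column sums equal the per-sample read counts.
#' @export
cluster_greedy <- function(seqs, sample_ids, cutoff = 0.05,
                           prefix = "OTU-", prefilter = TRUE) {
  stopifnot(length(seqs) == length(sample_ids))
  samples <- sort(unique(as.character(sample_ids)))
  if (length(seqs) == 0L)
    return(otu_table(matrix(0L, 0L, length(samples),
                            dimnames = list(NULL, samples)),
                    setNames(character(), character())))
  seqs <- toupper(seqs)

  # dereplicate with per-sample multiplicities
  uniq <- sort(unique(seqs))
  idx <- match(seqs, uniq)
  tab <- table(factor(idx, levels = seq_along(uniq)),
               factor(as.character(sample_ids), levels = samples))
  counts_u <- matrix(as.integer(tab), nrow = length(uniq),
                     dimnames = list(NULL, samples))
  mult <- rowSums(counts_u)

  ord <- order(-mult, -nchar(uniq), uniq)
  uniq <- uniq[ord]
  counts_u <- counts_u[ord, , drop = FALSE]

  k <- 8L
  centroid_seq <- character()
  centroid_prof <- list()
  centroid_len <- integer()
  assign_to <- integer(length(uniq))

  for (u in seq_along(uniq)) {
    s <- uniq[u]
    ls <- nchar(s)
    prof <- if (prefilter) kmer_profile(s, k) else NULL
    hit <- 0L
    for (ci in seq_along(centroid_seq)) {
      if (prefilter) {
        sh <- shared_kmers(prof, centroid_prof[[ci]])
        lb <- kmer_distance_lower_bound(sh, ls, centroid_len[ci], k)
        if (lb > cutoff + 0.02) next
      }
      if (pairwise_distance(s, centroid_seq[ci]) <= cutoff) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      centroid_seq <- c(centroid_seq, s)
      centroid_len <- c(centroid_len, ls)
      if (prefilter) centroid_prof[[length(centroid_seq)]] <- prof
      hit <- length(centroid_seq)
    }
    assign_to[u] <- hit
  }

  n_otu <- length(centroid_seq)
  otu_ids <- sprintf("%s%05d", prefix, seq_len(n_otu))
  counts <- matrix(0L, n_otu, length(samples),
                   dimnames = list(otu_ids, samples))
  for (u in seq_along(uniq))
    counts[assign_to[u], ] <- counts[assign_to[u], ] + counts_u[u, ]

  otu_table(counts, setNames(centroid_seq, otu_ids))
}
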