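# Naive-Bayes k-mer taxonomy with bootstrap confidence, the standard
# word-frequency classifier for 16S reads, plus a separate best-hit identity
# search used to report the closest relative. The two routes are kept
# apart deliberately: ranked lineage (domain..genus) comes from the
# classifier, while species-level naming and the identity percentage come
# only from the best alignment hit.

#' Train the naive-Bayes k-mer classifier
#'
#' References are pooled by genus (the last of the six lineage ranks). For
#' each k-mer word w and genus g, the word probability is
#' `P(w|g) = (n_w + 0.5) / (N_g + 1)` where `n_w` is the number of that
#' genus's references containing w (presence, not multiplicity) and `N_g`
#' the number of references in the genus.
#'
#' @param refs a `reference_db` containing at least two distinct genera.
#' @param k word length (4 to 12; default 8).
#' @return an object of class `nb_classifier`.
#' @export
train_classifier <- function(refs, k = 8L) {
  if (k < 4L || k > 12L) stop("k must be between 4 and 12")
  ranks <- lineage_ranks(refs)
  genus <- ranks[, "genus"]
  if (any(is.na(genus) | !nzchar(genus)))
    stop("every reference needs a genus rank")
  if (length(unique(genus)) < 2L)
    stop("need at least 2 distinct genera to train")

  words_per_ref <- lapply(refs$seq, function(s) unique(kmer_profile(s, k)))
  genera <- sort(unique(genus))
  vocab <- sort(unique(unlist(words_per_ref, use.names = FALSE)))

  n_word <- matrix(0L, length(vocab), length(genera),
                   dimnames = list(NULL, genera))
  n_refs <- table(factor(genus, levels = genera))
  for (i in seq_along(words_per_ref)) {
    g <- genus[i]
    pos <- match(words_per_ref[[i]], vocab)
    n_word[pos, g] <- n_word[pos, g] + 1L
  }
  log_p <- log(sweep(n_word + 0.5, 2L, as.numeric(n_refs) + 1, "/"))
  log_p_unseen <- log(0.5 / (as.numeric(n_refs) + 1))
  names(log_p_unseen) <- genera

  lineages <- ranks[match(genera, genus), seq_len(6L), drop = FALSE]
  rownames(lineages) <- genera

  structure(list(k = as.integer(k), vocab = vocab, log_p = log_p,
                 log_p_unseen = log_p_unseen, genera = genera,
                 n_refs = as.integer(n_refs), lineages = lineages),
            class = "nb_classifier")
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat(sprintf("<nb_classifier> k=%d, %d genera, %d words\n",
              x$k, length(x$genera), length(x$vocab)))
  invisible(x)
}

#' Word probability for one k-mer and genus
#'
#' Mainly for inspection and testing of the smoothing formula.
#'
#' @param model an `nb_classifier`.
#' @param word a k-mer string.
#' @param genus a genus present in the model.
#' @return the probability `P(word | genus)`.
#' @export
word_probability <- function(model, word, genus) {
  stopifnot(inherits(model, "nb_classifier"), genus %in% model$genera)
  code <- kmer_profile(word, model$k)
  if (length(code) != 1L) stop("word must be a single unambiguous k-mer")
  pos <- match(code, model$vocab)
  if (is.na(pos)) return(unname(exp(model$log_p_unseen[genus])))
  unname(exp(model$log_p[pos, genus]))
}

# log-probability matrix (unique query words x genera), unseen words filled
# with the per-genus smoothing floor
query_word_matrix <- function(model, centroid) {
  words <- unique(kmer_profile(centroid, model$k))
  if (length(words) == 0L)
    stop("centroid shorter than k (", model$k, ")")
  pos <- match(words, model$vocab)
  qm <- matrix(rep(model$log_p_unseen, each = length(words)),
               nrow = length(words),
               dimnames = list(NULL, model$genera))
  seen <- !is.na(pos)
  qm[seen, ] <- model$log_p[pos[seen], , drop = FALSE]
  qm
}

#' Classify a centroid with bootstrap confidence
#'
#' The full-word-set assignment is the genus maximizing the summed log word
#' probabilities over all unique query words. Each of `n_bootstrap`
#' replicates redraws `ceiling(W/8)` of the `W` unique words with
#' replacement and re-picks the argmax genus; the confidence at a rank is
#' the fraction of replicates whose winning genus agrees with the full
#' assignment's lineage down to that rank (so confidences are non-increasing
#' from domain to genus). Ranks below `conf_threshold` are reported as
#' `"unclassified <deepest confident parent>"`.
#'
#' @param centroid DNA string (length >= k).
#' @param model an `nb_classifier`.
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param conf_threshold reporting threshold (default 0.8).
#' @param seed optional RNG seed for reproducible confidences.
#' @return a list: `genus` (raw winner), `lineage` (raw winner lineage),
#'   `reported` (lineage after thresholding), `confidence` (named numeric,
#'   domain..genus).
#' @export
classify <- function(centroid, model, n_bootstrap = 100L,
                     conf_threshold = 0.8, seed = NULL) {
  stopifnot(inherits(model, "nb_classifier"))
  qm <- query_word_matrix(model, centroid)
  W <- nrow(qm)
  full_scores <- colSums(qm)
  winner <- which.max(full_scores)
  full_lineage <- model$lineages[winner, ]

  m <- ceiling(W / 8)
  boot_winners <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      idx <- sample.int(W, m, replace = TRUE)
      which.max(colSums(qm[idx, , drop = FALSE]))
    }, integer(1))
  })
  boot_lineages <- model$lineages[boot_winners, , drop = FALSE]
  agree_depth <- apply(boot_lineages, 1L, function(lin) {
    eq <- lin == full_lineage
    if (all(eq)) 6L else which.min(eq) - 1L
  })
  confidence <- vapply(seq_len(6L),
                       function(r) mean(agree_depth >= r), numeric(1))
  names(confidence) <- RANK_NAMES

  reported <- full_lineage
  below <- confidence < conf_threshold
  if (any(below)) {
    first_bad <- which(below)[1L]
    parent <- if (first_bad == 1L) "Root" else full_lineage[first_bad - 1L]
    reported[first_bad:6L] <- paste("unclassified", parent)
  }
  list(genus = model$genera[winner],
       lineage = unname(full_lineage),
       reported = unname(reported),
       confidence = confidence)
}

#' Best-hit identity of a centroid against the reference set
#'
#' Returns the best-scoring reference hit (score ranks hits; a raw-identity
#' ranking would be won by trivially short perfect overlaps), with ties
#' broken by higher identity and then lexicographically smallest reference
#' id. The winner's identity (matches over aligned columns, end gaps
#' excluded) is rounded to an integer percent.
#'
#' @param centroid DNA string.
#' @param refs a `reference_db`.
#' @param prefilter passed to the best-hit search.
#' @return a list: `ref_id`, `identity_percent`.
#' @export
best_hit_identity <- function(centroid, refs, prefilter = TRUE) {
  hit <- best_hit(centroid, refs, prefilter = prefilter)
  list(ref_id = hit$ref_id,
       identity_percent = as.integer(round(100 * hit$identity)))
}

#' Classify every OTU in a table
#'
#' Combines the naive-Bayes lineage with the best-hit identity, one row per
#' OTU.
#'
#' @param table an [otu_table].
#' @param model an `nb_classifier`.
#' @param refs a `reference_db` for the best-hit search.
#' @param n_bootstrap,conf_threshold passed to [classify()].
#' @param seed RNG seed; each OTU uses an offset of it.
#' @return a data frame: `otu_id`, the six reported ranks, per-rank
#'   confidences, `best_hit_id`, `best_hit_identity`.
#' @export
classify_otus <- function(table, model, refs, n_bootstrap = 100L,
                          conf_threshold = 0.8, seed = 1L) {
  cents <- otu_centroids(table)
  rows <- lapply(seq_along(cents), function(i) {
    cl <- classify(cents[i], model, n_bootstrap, conf_threshold,
                   seed = if (is.null(seed)) NULL else seed + i)
    bh <- best_hit_identity(cents[i], refs)
    df <- data.frame(otu_id = names(cents)[i], stringsAsFactors = FALSE)
    for (r in seq_len(6L)) df[[RANK_NAMES[r]]] <- cl$reported[r]
    for (r in seq_len(6L)) df[[paste0("conf_", RANK_NAMES[r])]] <- cl$confidence[r]
    df$best_hit_id <- bh$ref_id
    df$best_hit_identity <- bh$identity_percent
    df
  })
  do.call(rbind, rows)
}
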