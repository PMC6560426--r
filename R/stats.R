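# Two-group statistics behind the publication-style tables: the 1% main-OTU
# rule, unpaired pooled-variance Student t-tests (computable from raw values
# or directly from printed mean +/- SEM summaries, as produced by the common
# online calculators), Pearson correlations, and fold changes. P-values are
# reported unadjusted, matching standard practice for these tables; a
# Benjamini-Hochberg option is available downstream but off by default.

#' Select main OTUs
#'
#' An OTU is "main" iff its mean relative abundance reaches the threshold
#' (default 1%) in at least one of the two groups (inclusive boundary).
#'
#' @param rel relative abundance matrix in percent, OTUs x samples.
#' @param groups factor/character of group labels, one per sample column.
#' @param threshold_percent mean relative abundance cutoff in percent.
#' @return character vector of main OTU ids, in table order.
#' @export
select_main_otus <- function(rel, groups, threshold_percent = 1) {
  stopifnot(ncol(rel) == length(groups))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  means <- vapply(levels(groups), function(g)
    rowMeans(rel[, groups == g, drop = FALSE]), numeric(nrow(rel)))
  rownames(rel)[apply(means >= threshold_percent, 1L, any)]
}

#' Unpaired pooled-variance t-test from printed summaries
#'
#' Recovers the group SDs as `sem * sqrt(n)` and computes the classical
#' Student t-test with pooled variance and `df = n_a + n_b - 2`. For equal
#' group sizes this reduces to `t = (mean_a - mean_b) /
#' sqrt(sem_a^2 + sem_b^2)`. With both SEMs zero the comparison is
#' degenerate: p = 1 when the means are equal, otherwise p = 0 with the
#' `degenerate` flag set.
#'
#' @param mean_a,sem_a,n_a group A mean, SEM and size.
#' @param mean_b,sem_b,n_b group B mean, SEM and size.
#' @param feature_id optional label carried into the result.
#' @return a one-row data frame of class `group_comparison`: means, SEMs,
#'   sizes, `t_stat`, `df`, `p_value`, `fold_change` (mean_a / mean_b) and
#'   `degenerate`.
#' @export
ttest_from_summary <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b,
                               feature_id = NA_character_) {
  stopifnot(n_a >= 2L, n_b >= 2L, sem_a >= 0, sem_b >= 0)
  df <- n_a + n_b - 2L
  sd_a <- sem_a * sqrt(n_a)
  sd_b <- sem_b * sqrt(n_b)
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  degenerate <- FALSE
  if (se == 0) {
    if (mean_a == mean_b) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(mean_a - mean_b) * Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    t_stat <- (mean_a - mean_b) / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  out <- data.frame(feature_id = feature_id,
                    mean_a = mean_a, sem_a = sem_a, n_a = n_a,
                    mean_b = mean_b, sem_b = sem_b, n_b = n_b,
                    t_stat = t_stat, df = df, p_value = p,
                    fold_change = fold_change(mean_a, mean_b),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Unpaired pooled-variance t-test from raw values
#'
#' Computes each group's mean and SEM and delegates to
#' [ttest_from_summary()]; the two forms agree exactly on the same data.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param feature_id optional label.
#' @return a `group_comparison` row (see [ttest_from_summary()]).
#' @export
ttest_from_raw <- function(values_a, values_b, feature_id = NA_character_) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  ttest_from_summary(mean(values_a), sd(values_a) / sqrt(length(values_a)),
                     length(values_a),
                     mean(values_b), sd(values_b) / sqrt(length(values_b)),
                     length(values_b), feature_id = feature_id)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment r with `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both with non-zero
#'   variance.
#' @param otu_id,covariate optional labels carried into the result.
#' @return a one-row data frame: `otu_id`, `covariate`, `r`, `n`, `p_value`.
#' @export
pearson_cor <- function(x, y, otu_id = NA_character_,
                        covariate = NA_character_) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(-abs(t_stat), n - 2)
  }
  data.frame(otu_id = otu_id, covariate = covariate, r = r, n = n,
             p_value = p, stringsAsFactors = FALSE)
}

#' Fold change between group means
#'
#' @param mean_a,mean_b group means; `mean_b` must be positive (a zero
#'   denominator yields `Inf` as the undefined-ratio marker).
#' @return the ratio `mean_a / mean_b` (round to one decimal for display).
#' @export
fold_change <- function(mean_a, mean_b) {
  if (mean_b == 0) return(Inf)
  mean_a / mean_b
}
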