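# Rarefaction, alpha diversity, Bray-Curtis dissimilarity, principal
# coordinates analysis, and canonical correspondence analysis. Index
# conventions follow the common mothur definitions: Simpson is reported as
# the dominance form D = sum n(n-1) / (N(N-1)) (low D = high diversity),
# Chao1 uses the bias-corrected estimator so zero doubletons are defined,
# and coverage is Good's 1 - F1/N.

#' Rarefy an OTU count matrix
#'
#' Draws exactly `depth` reads per sample without replacement. Samples with
#' fewer reads than `depth` raise an error naming the sample. A single draw
#' is taken (no averaging over iterations) unless `iters > 1`, in which case
#' the element-wise mean of the draws is returned (rounded counts).
#'
#' @param counts integer matrix, OTUs x samples.
#' @param depth target depth (default 1800 reads).
#' @param seed optional RNG seed for a reproducible draw.
#' @param iters number of rarefaction draws to average (default 1).
#' @return an integer matrix of the same shape with all column sums equal to
#'   `depth` (exactly, when `iters = 1`).
#' @export
rarefy <- function(counts, depth = 1800L, seed = NULL, iters = 1L) {
  if (inherits(counts, "otu_table")) counts <- otu_counts(counts)
  stopifnot(is.matrix(counts), all(counts >= 0))
  depth <- as.integer(depth)
  totals <- colSums(counts)
  short <- totals < depth
  if (any(short))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(colnames(counts)[short], collapse = ", "))
  draw_one <- function() {
    out <- counts
    for (s in seq_len(ncol(counts))) {
      pool <- rep.int(seq_len(nrow(counts)), counts[, s])
      kept <- pool[sample.int(length(pool), depth)]
      out[, s] <- tabulate(kept, nbins = nrow(counts))
    }
    out
  }
  with_seed(seed, {
    if (iters == 1L) {
      draw_one()
    } else {
      acc <- Reduce(`+`, lapply(seq_len(iters), function(i) draw_one()))
      round(acc / iters)
    }
  })
}

#' Alpha diversity indices for rarefied counts
#'
#' Per sample: observed OTUs; bias-corrected Chao1
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1/F2 the singleton/doubleton
#' counts; Shannon `-sum p_i ln p_i`; Simpson dominance
#' `sum n_i (n_i - 1) / (N (N - 1))`; Good's coverage `1 - F1/N`.
#'
#' @param counts integer matrix (OTUs x samples) or a single count vector.
#' @return a data frame with one row per sample: `sample_id`, `observed_otus`,
#'   `chao1`, `shannon`, `simpson`, `coverage`.
#' @export
alpha_indices <- function(counts) {
  if (inherits(counts, "otu_table")) counts <- otu_counts(counts)
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L,
                                             dimnames = list(NULL, "sample_1"))
  stopifnot(all(counts >= 0))
  one <- function(n, id) {
    n <- n[n > 0]
    N <- sum(n)
    if (N == 0) stop("all-zero count vector for sample ", id)
    s_obs <- length(n)
    f1 <- sum(n == 1)
    f2 <- sum(n == 2)
    p <- n / N
    data.frame(
      sample_id = id,
      observed_otus = s_obs,
      chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)),
      shannon = -sum(p * log(p)),
      simpson = if (N > 1) sum(n * (n - 1)) / (N * (N - 1)) else 1,
      coverage = 1 - f1 / N,
      stringsAsFactors = FALSE
    )
  }
  ids <- colnames(counts) %||% paste0("sample_", seq_len(ncol(counts)))
  out <- do.call(rbind, lapply(seq_len(ncol(counts)),
                               function(s) one(counts[, s], ids[s])))
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = 1 - 2 sum_k min(x_ik, x_jk) / (N_i + N_j)`; symmetric, zero
#' diagonal, in \[0, 1\]. Intended for equal-depth (rarefied) counts.
#'
#' @param m matrix with samples as rows and OTUs as columns.
#' @return a symmetric numeric matrix of dissimilarities.
#' @export
bray_curtis <- function(m) {
  stopifnot(is.matrix(m) || is.data.frame(m))
  m <- as.matrix(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  totals <- rowSums(m)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      shared <- sum(pmin(m[i, ], m[j, ]))
      d[i, j] <- d[j, i] <- 1 - 2 * shared / (totals[i] + totals[j])
    }
  }
  d
}

new_ordination <- function(method, site, eigenvalues, proportion_explained,
                           species = NULL, biplot = NULL,
                           total_inertia = NULL, constrained_inertia = NULL,
                           covariates = NULL, negative_eigenvalues = NULL) {
  structure(list(method = method, site_coords = site,
                 species_coords = species, biplot_arrows = biplot,
                 eigenvalues = eigenvalues,
                 proportion_explained = proportion_explained,
                 total_inertia = total_inertia,
                 constrained_inertia = constrained_inertia,
                 covariates = covariates,
                 negative_eigenvalues = negative_eigenvalues),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination: %s> %d site(s), %d axis/axes\n", x$method,
              nrow(x$site_coords), ncol(x$site_coords)))
  cat("  proportion explained:",
      paste(sprintf("%.3f", head(x$proportion_explained, 4L)), collapse = " "),
      "\n")
  invisible(x)
}

# deterministic axis orientation: the largest-magnitude loading is positive
fix_signs <- function(m) {
  for (k in seq_len(ncol(m))) {
    i <- which.max(abs(m[, k]))
    if (m[i, k] < 0) m[, k] <- -m[, k]
  }
  m
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported but contribute no
#' coordinates, and proportions explained are taken over the positive
#' eigenvalues. Axis signs are fixed so the largest-magnitude loading on
#' each axis is positive.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @return an `ordination` object (method `"pcoa"`).
#' @export
pcoa_ord <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  a <- -0.5 * d^2
  b <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eg <- eigen(b, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  coords <- fix_signs(coords)
  dimnames(coords) <- list(rownames(d), paste0("PC", seq_len(ncol(coords))))
  new_ordination("pcoa", coords,
                 eigenvalues = eg$values,
                 proportion_explained = eg$values[pos] / sum(eg$values[pos]),
                 negative_eigenvalues = eg$values[eg$values < -tol])
}

#' Canonical correspondence analysis
#'
#' Chi-square standardization of the relative count matrix, weighted
#' least-squares regression of it on the standardized covariates (row
#' weights = sample totals), and SVD of the fitted values. Eigenvalues are
#' squared singular values; total inertia is the chi-square statistic of the
#' count table divided by the grand total, and the constrained inertia (sum
#' of eigenvalues) can never exceed it. Site scores are linear-combination
#' scores; species scores are scaled by the singular values (scaling 2);
#' biplot arrows are weighted correlations of each covariate with the site
#' axes, scaled by the relative singular values.
#'
#' @param species count matrix, samples x OTUs.
#' @param env data frame or matrix of numeric covariates (rows match
#'   `species`; fewer covariates than samples; none constant or collinear).
#' @return an `ordination` object (method `"cca"`).
#' @export
cca_ord <- function(species, env) {
  x <- as.matrix(species)
  e <- as.matrix(env)
  if (!is.numeric(e)) stop("covariates must be numeric")
  if (nrow(x) != nrow(e)) stop("species and env row counts differ")
  if (ncol(e) >= nrow(x)) stop("need fewer covariates than samples")
  if (is.null(colnames(e))) colnames(e) <- paste0("env", seq_len(ncol(e)))

  grand <- sum(x)
  p <- x / grand
  r <- rowSums(p)
  cc <- colSums(p)
  if (any(r == 0) || any(cc == 0))
    stop("empty sample or OTU row in species matrix")
  q <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  total_inertia <- sum(q^2)

  wmean <- colSums(r * e)
  ec <- sweep(e, 2L, wmean)
  wsd <- sqrt(colSums(r * ec^2))
  if (any(wsd < 1e-12))
    stop("constant covariate(s): ",
         paste(colnames(e)[wsd < 1e-12], collapse = ", "))
  es <- sweep(ec, 2L, wsd, "/")

  xw <- sqrt(r) * es
  qr_xw <- qr(xw)
  if (qr_xw$rank < ncol(xw)) {
    dep <- colnames(e)[qr_xw$pivot[(qr_xw$rank + 1L):ncol(xw)]]
    stop("collinear covariate(s): ", paste(dep, collapse = ", "))
  }
  fitted <- qr.fitted(qr_xw, q)

  sv <- svd(fitted)
  tol <- max(sv$d) * 1e-9
  keep <- which(sv$d > tol)
  d <- sv$d[keep]
  eig <- d^2

  site <- (sv$u[, keep, drop = FALSE] %*% diag(d, length(keep))) / sqrt(r)
  spec <- sweep(sv$v[, keep, drop = FALSE], 1L, sqrt(cc), "/") %*%
    diag(d, length(keep))

  # orient axes deterministically (largest-magnitude site score positive),
  # flipping species scores along with the sites
  flips <- vapply(seq_along(keep), function(k) {
    if (site[which.max(abs(site[, k])), k] < 0) -1 else 1
  }, numeric(1))
  site <- sweep(site, 2L, flips, "*")
  spec <- sweep(spec, 2L, flips, "*")

  wcor <- function(v, z) {
    vm <- sum(r * v) / sum(r)
    zm <- sum(r * z) / sum(r)
    sum(r * (v - vm) * (z - zm)) /
      sqrt(sum(r * (v - vm)^2) * sum(r * (z - zm)^2))
  }
  axis_names <- paste0("CCA", seq_along(keep))
  biplot <- matrix(0, ncol(e), length(keep),
                   dimnames = list(colnames(e), axis_names))
  for (jj in seq_len(ncol(e)))
    for (kk in seq_along(keep))
      biplot[jj, kk] <- wcor(es[, jj], site[, kk]) * d[kk] / max(d)

  dimnames(site) <- list(rownames(x), axis_names)
  dimnames(spec) <- list(colnames(x), axis_names)

  new_ordination("cca", site, eigenvalues = eig,
                 proportion_explained = eig / total_inertia,
                 species = spec, biplot = biplot,
                 total_inertia = total_inertia,
                 constrained_inertia = sum(eig),
                 covariates = colnames(e))
}
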