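test_that("rarefy draws exactly depth reads and errors on short samples", {
  counts <- matrix(c(900L, 2700L, 0L,
                     100L, 50L, 30L), nrow = 3L,
                   dimnames = list(paste0("o", 1:3), c("big", "small")))
  # sample with exactly the target depth is returned unchanged
  exact <- matrix(c(600L, 600L, 600L), 3L,
                  dimnames = list(paste0("o", 1:3), "s"))
  expect_identical(rarefy(exact, depth = 1800L, seed = 1L), exact)

  r <- rarefy(counts[, "big", drop = FALSE], depth = 1800L, seed = 42L)
  expect_equal(unname(colSums(r)), 1800L)
  expect_true(all(r <= counts[, "big"]))

  expect_error(rarefy(counts, depth = 1800L), "small")
  # determinism
  expect_identical(rarefy(counts[, "big", drop = FALSE], 1800L, seed = 9L),
                   rarefy(counts[, "big", drop = FALSE], 1800L, seed = 9L))
})

test_that("rarefied counts match the hypergeometric mean", {
  counts <- matrix(c(900L, 1800L, 600L, 300L), 4L,
                   dimnames = list(paste0("o", 1:4), "s"))
  draws <- vapply(1:1000, function(i)
    rarefy(counts, depth = 1800L, seed = i)[1L, 1L], integer(1))
  # E[count] = 1800 * 900/3600 = 450; allow 3 standard errors
  v <- 1800 * 0.25 * 0.75 * (3600 - 1800) / (3600 - 1)
  expect_lt(abs(mean(draws) - 450), 3 * sqrt(v / 1000))
})

test_that("alpha indices reproduce their closed forms", {
  a <- alpha_indices(c(450L, 450L, 450L, 450L))
  expect_equal(a$observed_otus, 4L)
  expect_equal(a$shannon, log(4))
  expect_equal(a$simpson, 4 * 450 * 449 / (1800 * 1799))
  expect_equal(a$chao1, 4)
  expect_equal(a$coverage, 1)

  single <- alpha_indices(c(0L, 100L))
  expect_equal(single$shannon, 0)
  expect_equal(single$simpson, 1)

  # F1 = 2, F2 = 1 -> chao1 = S_obs + 2*1/(2*2) = S_obs + 0.5
  v <- c(1L, 1L, 2L, 10L)
  expect_equal(alpha_indices(v)$chao1, 4 + 0.5)

  expect_error(alpha_indices(c(0L, 0L)), "all-zero")
  # invariance to OTU ordering
  set.seed(3)
  w <- rpois(30L, 5L)
  expect_equal(alpha_indices(w)[, -1L], alpha_indices(rev(w))[, -1L])
})

test_that("bray_curtis matches its formula and a brute-force oracle", {
  m <- rbind(a = c(5, 5, 0), b = c(5, 5, 0), c = c(0, 0, 10))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)

  set.seed(11)
  x <- matrix(rpois(100L, 4L), 5L, 20L,
              dimnames = list(paste0("s", 1:5), NULL))
  d2 <- bray_curtis(x)
  for (i in 1:5) {
    expect_equal(d2[i, i], 0)
    for (j in 1:5) {
      ref <- 1 - 2 * sum(pmin(x[i, ], x[j, ])) / (sum(x[i, ]) + sum(x[j, ]))
      expect_equal(d2[i, j], ref)
      expect_equal(d2[i, j], d2[j, i])
      expect_gte(d2[i, j], 0); expect_lte(d2[i, j], 1)
    }
  }
  if (requireNamespace("vegan", quietly = TRUE)) {
    expect_equal(as.matrix(vegan::vegdist(x, "bray")), d2,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pcoa handles equidistant points and reconstructs Euclidean input", {
  d3 <- matrix(0.5, 3L, 3L); diag(d3) <- 0
  ord <- pcoa_ord(d3)
  ev <- ord$eigenvalues
  expect_equal(ev[1L], ev[2L], tolerance = 1e-10)
  expect_lt(abs(ev[3L]), 1e-10)

  set.seed(21)
  pts <- matrix(rnorm(10L), 5L, 2L)
  dE <- as.matrix(dist(pts))
  ordE <- pcoa_ord(dE)
  expect_equal(length(ordE$negative_eigenvalues), 0L)
  rec <- as.matrix(dist(ordE$site_coords[, 1:2]))
  expect_lt(max(abs(rec - dE)), 1e-8)
  expect_equal(sum(ordE$proportion_explained), 1)

  # deterministic sign convention
  expect_identical(pcoa_ord(dE)$site_coords, ordE$site_coords)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2L)), "symmetric")
})

test_that("cca total inertia equals the chi-square statistic on a toy table", {
  set.seed(14)
  x <- matrix(c(10, 2, 3, 1, 8, 6,
                2, 12, 1, 3, 2, 9,
                5, 5, 9, 2, 1, 1,
                1, 3, 2, 14, 4, 2), 4L, 6L, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("o", 1:6)))
  env <- data.frame(cov1 = c(1.2, 3.4, 2.2, 5.1), cov2 = c(0.3, 0.1, 0.9, 0.4))
  ord <- cca_ord(x, env)

  # independent hand computation: sum((O - E)^2 / E) / grand total
  grand <- sum(x)
  E <- outer(rowSums(x), colSums(x)) / grand
  chisq <- sum((x - E)^2 / E)
  expect_equal(ord$total_inertia, chisq / grand, tolerance = 1e-12)
  expect_lte(ord$constrained_inertia, ord$total_inertia + 1e-12)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
})

test_that("cca agrees with the vegan oracle on eigenvalues and inertia", {
  skip_if_not_installed("vegan")
  set.seed(33)
  x <- matrix(rpois(60L, 6L) + 1L, 6L, 10L,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
  env <- data.frame(e1 = rnorm(6L), e2 = runif(6L))
  ord <- cca_ord(x, env)
  vg <- vegan::cca(x ~ e1 + e2, data = env)
  expect_equal(ord$total_inertia, vg$tot.chi, tolerance = 1e-10)
  expect_equal(unname(ord$eigenvalues),
               unname(vg$CCA$eig), tolerance = 1e-8)
  expect_equal(ord$constrained_inertia, vg$CCA$tot.chi, tolerance = 1e-10)
})

test_that("cca detects a perfect gradient and rejects degenerate covariates", {
  set.seed(8)
  n <- 8L
  gradient <- seq_len(n)
  # community whose composition tracks the gradient
  x <- t(vapply(gradient, function(g)
    rpois(12L, lambda = 5 * exp(-abs(seq_len(12L) - 1.5 * g) / 2)) + 1L,
    integer(12L)))
  rownames(x) <- paste0("s", seq_len(n))
  ord <- cca_ord(x, data.frame(grad = gradient))
  expect_gt(abs(cor(ord$site_coords[, 1L], gradient)), 0.99)

  # orthogonal (permuted) covariates carry far less constrained inertia
  perms <- vapply(1:50, function(i) {
    cca_ord(x, data.frame(grad = sample(gradient)))$constrained_inertia
  }, numeric(1))
  expect_gt(ord$constrained_inertia, quantile(perms, 0.95))

  expect_error(cca_ord(x, data.frame(c1 = rep(1, n))), "constant")
  expect_error(cca_ord(x, data.frame(a = gradient, b = 2 * gradient)),
               "collinear")
})

test_that("cca constrained inertia grows monotonically with covariates", {
  set.seed(99)
  x <- matrix(rpois(80L, 5L) + 1L, 8L, 10L)
  rownames(x) <- paste0("s", 1:8)
  env <- data.frame(a = rnorm(8L), b = rnorm(8L), c = rnorm(8L))
  ci <- vapply(1:3, function(k)
    cca_ord(x, env[, seq_len(k), drop = FALSE])$constrained_inertia,
    numeric(1))
  expect_true(all(diff(ci) >= -1e-12))
})
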