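test_that("select_main_otus applies the inclusive 1% rule per group", {
  rel <- rbind(
    at_boundary = c(1.00, 1.00, 0.20, 0.20),   # exactly 1% in group A
    below = c(0.99, 0.99, 0.99, 0.99),
    high_b = c(0.10, 0.10, 3.00, 5.00))
  colnames(rel) <- paste0("s", 1:4)
  groups <- c("A", "A", "B", "B")
  expect_setequal(select_main_otus(rel, groups), c("at_boundary", "high_b"))
  expect_error(select_main_otus(rel, c("A", "A", "A", "A")), "two groups")
})

test_that("planted abundant taxa are exactly the selected main OTUs", {
  set.seed(41)
  n <- 30L
  base <- c(rep(8, 5L), runif(n - 5L, 0.01, 0.25))  # 5 clearly abundant taxa
  w <- t(replicate(8L, base * exp(rnorm(n, 0, 0.1))))
  rel <- 100 * w / rowSums(w)
  rel <- t(rel)
  rownames(rel) <- c(paste0("big", 1:5), paste0("small", 6:n))
  colnames(rel) <- paste0("s", 1:8)
  got <- select_main_otus(rel, rep(c("A", "B"), each = 4L))
  expect_setequal(got, paste0("big", 1:5))
})

test_that("ttest_from_summary reproduces hand-checked cases", {
  # identical groups
  eq <- ttest_from_summary(5, 1, 10L, 5, 1, 10L)
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$df, 18L)

  # degenerate cases
  expect_equal(ttest_from_summary(3, 0, 5L, 3, 0, 5L)$p_value, 1)
  deg <- ttest_from_summary(3, 0, 5L, 4, 0, 5L)
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)

  # equal n reduces to diff / sqrt(sem_a^2 + sem_b^2)
  cmp <- ttest_from_summary(10, 2, 10L, 7, 1.5, 10L)
  expect_equal(cmp$t_stat, 3 / sqrt(4 + 2.25))
})

test_that("ttest_from_raw agrees with the textbook worked example and stats::t.test", {
  # hand calculation: means 7 and 12, both sd = sqrt(2.5),
  # t = -5 / (sqrt(2.5) * sqrt(2/5)) = -5
  cmp <- ttest_from_raw(c(5, 7, 9, 6, 8), c(10, 12, 14, 11, 13))
  expect_equal(cmp$t_stat, -5)
  expect_equal(cmp$df, 8L)
  expect_equal(cmp$p_value, 2 * pt(-5, 8))

  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(sample(4:12, 1L), 5, 2)
    b <- rnorm(sample(4:12, 1L), 6, 2)
    mine <- ttest_from_raw(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t_stat, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
  }
  expect_error(ttest_from_raw(1, c(1, 2)), "at least 2")
})

test_that("summary and raw forms agree to 1e-12 on the same data", {
  set.seed(5)
  a <- rlnorm(10L); b <- rlnorm(10L)
  raw <- ttest_from_raw(a, b)
  summ <- ttest_from_summary(mean(a), sd(a) / sqrt(10), 10L,
                             mean(b), sd(b) / sqrt(10), 10L)
  expect_equal(raw$t_stat, summ$t_stat, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
})

test_that("pearson_cor matches the closed form and cor.test", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_cor(x, x + 100)$r, 1)

  # r = 0.5, n = 12 -> t = 1.8257, p ~ 0.0979 (verified against tables)
  t_stat <- 0.5 * sqrt(10) / sqrt(0.75)
  expect_equal(t_stat, 1.825742, tolerance = 1e-6)
  set.seed(2)
  for (i in 1:8) {
    x <- rnorm(12L); y <- rnorm(12L)
    mine <- pearson_cor(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate))
    expect_equal(mine$p_value, ref$p.value)
  }
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("fold_change behaves as a ratio with an infinity marker", {
  expect_equal(fold_change(3, 3), 1)
  expect_equal(round(fold_change(19.51, 2.70), 1), 7.2)
  expect_equal(fold_change(1, 0), Inf)
  set.seed(4)
  for (i in 1:10) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50)
    expect_equal(fold_change(a, b) * fold_change(b, a), 1)
  }
})

test_that("build_report produces internally consistent tables", {
  st <- small_study()
  cfg <- pipeline_config(rarefy_depth = 150L, seed = 5L)
  res <- run_pipeline(st$sim$fastq, st$refs, st$sim$metadata, cfg)
  rep <- res$report

  # Total rows equal the column sums of the rounded printed entries
  for (i in seq_len(nrow(rep$main_otu_totals))) {
    ph <- rep$main_otu_totals$phylum[i]
    rows <- rep$main_otus[rep$main_otus$phylum == ph, ]
    expect_equal(rep$main_otu_totals$total_a[i], sum(round(rows$mean_a, 2)))
    expect_equal(rep$main_otu_totals$total_b[i], sum(round(rows$mean_b, 2)))
  }

  # family rows (incl. the "Other" remainder) sum to their phylum's mean
  ts <- rep$taxon_summary
  for (ph in unique(ts$phylum[ts$level == "phylum"])) {
    fam <- ts[ts$level == "family" & ts$phylum == ph, ]
    phr <- ts[ts$level == "phylum" & ts$feature_id == ph, ]
    if (nrow(fam)) {
      expect_equal(sum(fam$mean_a), phr$mean_a, tolerance = 1e-9)
      expect_equal(sum(fam$mean_b), phr$mean_b, tolerance = 1e-9)
    }
  }

  # correlations cover every main OTU x numeric covariate pair
  n_cov <- sum(vapply(st$sim$metadata, is.numeric, logical(1)))
  expect_equal(nrow(rep$correlations), nrow(rep$main_otus) * n_cov)
  expect_true(all(abs(rep$correlations$r) <= 1))

  # alpha summary carries all five indices with a p-value each
  expect_setequal(rep$alpha_summary$feature_id,
                  c("chao1", "observed_otus", "shannon", "simpson", "coverage"))
  expect_true(all(rep$alpha_summary$p_value > 0 &
                    rep$alpha_summary$p_value <= 1))

  # missing metadata sample errors
  md_bad <- st$sim$metadata[-1L, ]
  expect_error(build_report(res$table, res$assignments, md_bad, cfg),
               "missing sample")
})

test_that("the group_comparison df invariant holds", {
  cmp <- ttest_from_raw(rnorm(6), rnorm(9))
  expect_equal(cmp$df, 6L + 9L - 2L)
  expect_gte(cmp$sem_a, 0)
  expect_gte(cmp$sem_b, 0)
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
})
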