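make_toy_model <- function() {
  # two genera, two references each, with controlled 4-mer content
  db <- reference_db(
    c("t1", "t2", "t3", "t4"),
    c("AAAATTTTCCCC", "AAAATTTTGGGG", "CCCCGGGGAAAA", "CCCCGGGGTTTT"),
    c(rep("Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;GenA", 2L),
      rep("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;GenB", 2L)))
  train_classifier(db, k = 4L)
}

test_that("word probabilities follow the (n + 0.5)/(N + 1) smoothing", {
  model <- make_toy_model()
  # word in both GenA refs: (2 + 0.5)/(2 + 1)
  expect_equal(word_probability(model, "AAAT", "GenA"), 2.5 / 3)
  expect_gt(word_probability(model, "AAAT", "GenA"), 0.5)
  # word in one of two refs: (1 + 0.5)/(2 + 1)
  expect_equal(word_probability(model, "TTCC", "GenA"), 1.5 / 3)
  # absent word: 0.5/(2 + 1)
  expect_equal(word_probability(model, "GGTT", "GenA"), 0.5 / 3)

  # with a single-reference genus an absent word gives 0.25
  db1 <- reference_db(
    c("u1", "u2"),
    c("AAAATTTTCCCC", "CCCCGGGGAAAA"),
    c("Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;GenA",
      "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;GenB"))
  m1 <- train_classifier(db1, k = 4L)
  expect_equal(word_probability(m1, "GGGG", "GenA"), 0.25)
})

test_that("train_classifier validates k and genus structure", {
  db <- tiny_refs()
  expect_error(train_classifier(db, k = 3L), "between 4 and 12")
  expect_error(train_classifier(db, k = 13L), "between 4 and 12")
  one_genus <- db[lineage_ranks(db)[, "genus"] == "Genus_01", ]
  class(one_genus) <- class(db)
  expect_error(train_classifier(one_genus), "2 distinct genera")
})

test_that("the model serializes and round-trips", {
  model <- train_classifier(tiny_refs())
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  back <- readRDS(path)
  expect_identical(back, model)
  q <- attr(tiny_refs(), "core")[1L]
  expect_identical(classify(q, model, seed = 4L),
                   classify(q, back, seed = 4L))
})

test_that("self-classification recovers every genus with high confidence", {
  refs <- tiny_refs()
  model <- train_classifier(refs)
  genus <- lineage_ranks(refs)[, "genus"]
  for (i in seq_len(nrow(refs))) {
    cl <- classify(refs$seq[i], model, seed = 100L + i)
    expect_equal(cl$genus, unname(genus[i]))
    expect_gte(cl$confidence[["genus"]], 0.95)
    # confidences never increase from coarse to fine rank
    expect_true(all(diff(cl$confidence) <= 1e-12))
  }
})

test_that("a 50/50 mosaic is unclassified at genus but keeps the shared phylum", {
  refs <- medium_refs()
  ranks <- lineage_ranks(refs)
  # two genera sharing phylum Firmicutes but differing at order/family
  firm <- which(ranks[, "phylum"] == "Firmicutes")
  g <- unique(ranks[firm, "genus"])
  stopifnot(length(g) >= 2L)
  ia <- firm[match(g[1L], ranks[firm, "genus"])]
  ib <- firm[match(g[2L], ranks[firm, "genus"])]
  ca <- attr(refs, "core")[ia]
  cb <- attr(refs, "core")[ib]
  mosaic <- paste0(substr(ca, 1L, nchar(ca) %/% 2L),
                   substr(cb, nchar(cb) %/% 2L + 1L, nchar(cb)))
  model <- train_classifier(refs)
  cl <- classify(mosaic, model, seed = 9L)
  expect_lt(cl$confidence[["genus"]], 0.8)
  expect_match(cl$reported[6L], "^unclassified ")
  expect_equal(cl$reported[2L], "Firmicutes")
})

test_that("classification is deterministic given the seed", {
  model <- train_classifier(tiny_refs())
  q <- attr(tiny_refs(), "core")[5L]
  a <- classify(q, model, seed = 77L)
  b <- classify(q, model, seed = 77L)
  expect_identical(a$confidence, b$confidence)
  expect_error(classify("ACGT", model), "shorter than k")
})

test_that("best_hit_identity counts and rounds correctly", {
  refs <- tiny_refs()
  core <- attr(refs, "core")
  hit <- best_hit_identity(refs$seq[3L], refs)
  expect_equal(hit$ref_id, "REF_003")
  expect_equal(hit$identity_percent, 100L)

  # 100-nt query with 3 mismatches against its source -> 97%
  q100 <- substr(core[3L], 1L, 100L)
  set.seed(6)
  q97 <- mutate_seq(q100, 3L)
  expect_equal(best_hit_identity(q97, refs)$identity_percent, 97L)
})

test_that("best_hit_identity agrees with the exhaustive-alignment oracle", {
  full <- tiny_refs()
  refs <- full[1:6, ]
  class(refs) <- class(full)
  cores <- attr(full, "core")[1:6]
  set.seed(123)
  for (i in 1:50) {
    src <- sample(length(cores), 1L)
    start <- sample(seq(1L, nchar(cores[src]) - 160L), 1L)
    q <- substr(mutate_seq(cores[src], sample(0:5, 1L)),
                start, start + sample(100:150, 1L))
    got <- best_hit_identity(q, refs)
    # oracle: align against every reference with the independent R DP and
    # rank by (score, identity, ref_id)
    o <- lapply(refs$seq, oracle_align, a = q)
    scores <- vapply(o, `[[`, numeric(1), "score")
    ids <- vapply(o, function(z)
      if (z$columns == 0L) 0 else z$matches / z$columns, numeric(1))
    cand <- which(scores == max(scores))
    cand <- cand[ids[cand] == max(ids[cand])]
    winner <- cand[order(refs$ref_id[cand])][1L]
    expect_equal(got$ref_id, refs$ref_id[winner])
    expect_equal(got$identity_percent, as.integer(round(100 * ids[winner])))
  }
})

test_that("classify_otus merges classifier and best-hit evidence per OTU", {
  refs <- tiny_refs()
  cores <- attr(refs, "core")
  tab <- cluster_greedy(rep(cores[c(1L, 4L)], each = 2L), rep("s1", 4L))
  model <- train_classifier(refs)
  asg <- classify_otus(tab, model, refs, seed = 2L)
  expect_equal(nrow(asg), 2L)
  expect_true(all(c("phylum", "genus", "best_hit_id", "best_hit_identity")
                  %in% names(asg)))
  expect_setequal(asg$best_hit_id, c("REF_001", "REF_004"))
  expect_true(all(asg$best_hit_identity == 100L))
})
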