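test_that("simulate_reference_db meets its divergence contract", {
  refs <- simulate_reference_db(2L, seed = 1L)
  expect_equal(nrow(refs), 2L)
  expect_gte(pairwise_distance(refs$seq[1L], refs$seq[2L]), 0.10)

  expect_error(simulate_reference_db(0L), "n_taxa >= 2")

  refs12 <- tiny_refs()
  genus <- lineage_ranks(refs12)[, "genus"]
  phyla <- unique(lineage_ranks(refs12)[, "phylum"])
  expect_gte(length(phyla), 2L)
  # within-genus pairs sit in the 6-9% band, between-genus pairs >= 10%
  for (i in 1:3) {
    for (j in (i + 1):4) {
      d <- pairwise_distance(refs12$seq[i], refs12$seq[j])
      if (genus[i] == genus[j]) {
        expect_gte(d, 0.055)
        expect_lte(d, 0.095)
      } else {
        expect_gte(d, 0.10)
      }
    }
  }
  # amplicons stay inside the QC length window, primer sites are intact
  expect_true(all(nchar(refs12$seq) >= 400 & nchar(refs12$seq) <= 580))
  cfg <- pipeline_config()
  expect_true(all(vapply(refs12$seq, has_intact_primers, logical(1),
                         fwd = cfg$fwd_primer, rev = cfg$rev_primer)))
})

test_that("simulate_reference_db is deterministic given the seed", {
  a <- simulate_reference_db(6L, seed = 33L)
  b <- simulate_reference_db(6L, seed = 33L)
  expect_identical(a$seq, b$seq)
  expect_identical(a$lineage, b$lineage)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  tax <- withr::local_tempfile()
  write_reference_db(a, fa1, tax)
  write_reference_db(b, fa2, tax)
  expect_identical(readLines(fa1), readLines(fa2))
})

test_that("simulation_design validates its fractions and sizes", {
  expect_error(simulation_design(n_per_group = 1L), "is not TRUE")
  expect_error(simulation_design(chimera_frac = 0.5, truncated_frac = 0.4,
                                 offtarget_short_frac = 0.2), "is not TRUE")
  d <- simulation_design(enriched_taxa = data.frame(
    taxon = "REF_001", group = "EO", fold_change = 8))
  expect_equal(d$enriched_taxa$fold_change, 8)
  expect_error(simulation_design(enriched_taxa = data.frame(
    taxon = "REF_001", group = "EO", fold_change = -1)), "is not TRUE")
})

test_that("planted enrichment shows in the emitted ground truth", {
  st <- small_study()
  truth <- st$sim$truth
  rel <- truth$taxon_counts / rowSums(truth$taxon_counts)
  groups <- st$sim$metadata$treatment[
    match(rownames(rel), st$sim$metadata$sample_id)]
  plan <- truth$enrichment
  expect_equal(nrow(plan), 2L)
  for (k in seq_len(nrow(plan))) {
    m_in <- mean(rel[groups == plan$group[k], plan$taxon[k]])
    m_out <- mean(rel[groups != plan$group[k], plan$taxon[k]])
    expect_gt(m_in, m_out)
  }
  # per-sample expected abundances sum to 1
  expect_equal(unname(rowSums(truth$abundances)),
               rep(1, nrow(truth$abundances)), tolerance = 1e-12)
})

test_that("read labels account exactly for every emitted read", {
  st <- small_study()
  lab <- st$sim$truth$read_labels
  design <- st$design
  n_samples <- 2L * design$n_per_group
  expect_equal(nrow(lab), n_samples * design$reads_per_sample)
  # every read in every FASTQ has exactly one label
  for (s in names(st$sim$fastq)) {
    reads <- read_fastq(st$sim$fastq[[s]])
    expect_setequal(reads$read_id, lab$read_id[lab$sample_id == s])
  }
  # class counts fall within a wide binomial CI of the design fractions
  # (the study seed is fixed, so this is a deterministic sanity bound)
  n_total <- nrow(lab)
  for (cls in c("chimera", "truncated", "offtarget")) {
    p <- switch(cls, chimera = design$chimera_frac,
                truncated = design$truncated_frac,
                offtarget = design$offtarget_short_frac)
    n_cls <- sum(lab$class == cls)
    ci <- qbinom(c(0.0005, 0.9995), n_total, p)
    expect_gte(n_cls, ci[1L])
    expect_lte(n_cls, ci[2L])
  }
  # clean-read taxon counts match the label table
  tc <- st$sim$truth$taxon_counts
  clean <- lab[lab$class == "clean", ]
  expect_equal(sum(tc), nrow(clean))
  counted <- table(clean$sample_id, clean$taxon)
  for (s in rownames(tc)) {
    for (tx in colnames(tc)) {
      n_lab <- if (tx %in% colnames(counted) && s %in% rownames(counted))
        counted[s, tx] else 0L
      expect_equal(unname(tc[s, tx]), unname(as.integer(n_lab)))
    }
  }
})

test_that("chimera_frac = 0 yields no chimera labels", {
  refs <- tiny_refs()
  design <- simulation_design(n_per_group = 2L, n_taxa = 8L,
                              reads_per_sample = 60L, chimera_frac = 0,
                              seed = 3L)
  sim <- simulate_study(design, refs, withr::local_tempdir(),
                        rarefy_depth = 30L)
  expect_equal(sum(sim$truth$read_labels$class == "chimera"), 0L)
})

test_that("the same seed gives byte-identical FASTQ and a manifest warning fires", {
  refs <- tiny_refs()
  design <- simulation_design(n_per_group = 2L, n_taxa = 6L,
                              reads_per_sample = 50L, seed = 77L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_study(design, refs, d1, rarefy_depth = 1800L)
  s2 <- simulate_study(design, refs, d2, rarefy_depth = 1800L)
  for (nm in names(s1$fastq))
    expect_identical(readLines(s1$fastq[[nm]]), readLines(s2$fastq[[nm]]))
  manifest <- jsonlite::read_json(s1$manifest_path)
  expect_match(unlist(manifest$warnings), "below intended rarefaction depth")
})

test_that("metadata has the documented column layout and group structure", {
  st <- small_study()
  md <- st$sim$metadata
  expect_named(md, c("sample_id", "treatment", "acetate_mM", "propionate_mM",
                     "butyrate_mM", "isobutyrate_mM", "valerate_mM",
                     "isovalerate_mM", "total_scfa_mM", "body_length",
                     "heart_girth", "hip_width"))
  expect_equal(sort(unique(md$treatment)), c("Control", "EO"))
  expect_equal(md$total_scfa_mM,
               rowSums(md[, c("acetate_mM", "propionate_mM", "butyrate_mM",
                              "isobutyrate_mM", "valerate_mM",
                              "isovalerate_mM")]))
  path <- file.path(st$dir, "metadata.tsv")
  expect_identical(read_metadata(path)$sample_id, md$sample_id)
})
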