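# Ground-truthed synthetic studies: a reference database with controlled
# divergence structure, log-normal community compositions with planted
# treatment-enriched taxa, per-sample FASTQ reads with substitution errors
# and Phred strings that bracket the 1% quality rule, planted artifact
# classes (bimeras, end-damaged reads, off-target short amplicons), and a
# metadata table with group-specific SCFA and growth covariates. Every
# emitted read carries a ground-truth label so downstream screens can be
# scored exactly.

#' Describe a synthetic two-group amplicon study
#'
#' Defaults emulate the study design this package targets: 2 treatment
#' groups ("EO" and "Control") x 10 calves, 2000 assembled reads per sample,
#' log-normal taxon abundances (sigma = 1), two planted EO-enriched taxa at
#' 7.2x and 20.2x, a 0.5% per-base substitution error rate, and 1% each of
#' bimera, end-damaged and off-target-short artifact reads.
#'
#' @param n_per_group samples per group (>= 2).
#' @param n_taxa taxa in the community (must not exceed the reference set).
#' @param lognormal_mu,lognormal_sigma parameters of the log-normal
#'   community abundance distribution across taxa.
#' @param sample_sigma per-sample log-normal jitter of taxon abundances
#'   (biological replicate noise on the log scale).
#' @param enriched_taxa `NULL` (defaults planted at simulation time: the
#'   first taxa of two different phyla at 7.2x and 20.2x in group 1) or a
#'   data frame with columns `taxon` (reference id), `group`, `fold_change`.
#' @param reads_per_sample reads emitted per sample.
#' @param error_rate per-base substitution probability.
#' @param chimera_frac,truncated_frac,offtarget_short_frac expected fractions
#'   of the three artifact classes (their sum must stay below 1).
#' @param poor_quality_frac fraction of reads drawn with a 2% low-quality
#'   base rate (most fail the 1% rule); the rest use 0.2% (virtually all
#'   pass), so realized low-quality fractions bracket the QC threshold.
#' @param group_names labels of the two groups (first = treated).
#' @param seed RNG seed; with the same seed the emitted files are
#'   byte-identical.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n_per_group = 10L,
                              n_taxa = 40L,
                              lognormal_mu = 0,
                              lognormal_sigma = 1,
                              sample_sigma = 0.5,
                              enriched_taxa = NULL,
                              reads_per_sample = 2000L,
                              error_rate = 0.005,
                              chimera_frac = 0.01,
                              truncated_frac = 0.01,
                              offtarget_short_frac = 0.01,
                              poor_quality_frac = 0.1,
                              group_names = c("EO", "Control"),
                              seed = 1L) {
  fracs <- c(chimera_frac, truncated_frac, offtarget_short_frac)
  stopifnot(n_per_group >= 2L, n_taxa >= 2L,
            all(fracs >= 0), all(fracs <= 1), sum(fracs) < 1,
            reads_per_sample >= 1L, error_rate >= 0, error_rate < 1,
            poor_quality_frac >= 0, poor_quality_frac <= 1,
            lognormal_sigma >= 0, sample_sigma >= 0,
            length(group_names) == 2L)
  if (!is.null(enriched_taxa)) {
    stopifnot(is.data.frame(enriched_taxa),
              all(c("taxon", "group", "fold_change") %in% names(enriched_taxa)),
              all(enriched_taxa$fold_change > 0),
              all(enriched_taxa$group %in% group_names))
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_taxa = as.integer(n_taxa),
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 sample_sigma = sample_sigma,
                 enriched_taxa = enriched_taxa,
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 chimera_frac = chimera_frac,
                 truncated_frac = truncated_frac,
                 offtarget_short_frac = offtarget_short_frac,
                 poor_quality_frac = poor_quality_frac,
                 group_names = group_names,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

# lineage scaffold cycled over genera; spans four phyla typical of the
# rumen so family/phylum aggregation has realistic structure
LINEAGE_POOL <- data.frame(
  phylum = c("Firmicutes", "Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Actinobacteria", "Bacteroidetes", "Firmicutes", "Firmicutes"),
  class = c("Clostridia", "Bacteroidia", "Bacilli", "Gammaproteobacteria",
            "Coriobacteriia", "Bacteroidia", "Clostridia", "Negativicutes"),
  order = c("Lachnospirales", "Bacteroidales", "Erysipelotrichales",
            "Pasteurellales", "Coriobacteriales", "Bacteroidales",
            "Oscillospirales", "Veillonellales"),
  family = c("Lachnospiraceae", "Prevotellaceae", "Erysipelotrichaceae",
             "Pasteurellaceae", "Atopobiaceae", "Rikenellaceae",
             "Ruminococcaceae", "Veillonellaceae"),
  stringsAsFactors = FALSE
)

#' Simulate a reference database
#'
#' Generates `n_taxa` reference amplicons organised into genera: core
#' sequences 420-540 nt between primer sites (so full amplicons stay inside
#' the 400-580 nt read window), pairwise dissimilarity 6-9% within a genus
#' and >= 10% between genera (random independent genus roots), each flanked
#' by one fixed concrete instantiation of the 27F/519R primer binding
#' sites. Lineages cycle over a pool spanning four phyla. The generated
#' divergence structure is verified with the package's own aligner and a
#' violation raises a generation error.
#'
#' @param n_taxa number of reference taxa (>= 2).
#' @param seed RNG seed (same seed, byte-identical database).
#' @param taxa_per_genus genus size before a new genus is opened (default 3).
#' @param core_len_range core length range between the primer sites.
#' @param fwd_primer,rev_primer IUPAC primers to instantiate as flanks.
#' @return a `reference_db` with attributes `fwd_site`, `rev_site` (the
#'   concrete primer instantiations) and `core` (primer-free sequences).
#' @export
simulate_reference_db <- function(n_taxa, seed = 1L, taxa_per_genus = 3L,
                                  core_len_range = c(420L, 540L),
                                  fwd_primer = "AGAGTTTGATCMTGGCTCAG",
                                  rev_primer = "GWATTACCGCGGCKGCTG") {
  if (n_taxa < 2L) stop("need n_taxa >= 2")
  n_genera <- max(2L, ceiling(n_taxa / taxa_per_genus))
  members <- rep(seq_len(n_genera), length.out = n_taxa)

  db <- with_seed(seed, {
    inst <- function(p) paste(vapply(strsplit(toupper(p), "")[[1L]],
                                     function(ch) sample(IUPAC_SETS[[ch]], 1L),
                                     character(1)), collapse = "")
    fwd_site <- inst(fwd_primer)
    rev_site_rc <- revcomp(inst(rev_primer))
    flank <- nchar(fwd_site) + nchar(rev_site_rc)

    cores <- character(n_taxa)
    genus_of <- character(n_taxa)
    lineage <- character(n_taxa)
    for (g in seq_len(n_genera)) {
      idx <- which(members == g)
      L <- sample(seq.int(core_len_range[1L], core_len_range[2L]), 1L)
      total_len <- L + flank
      max_frac <- 0.045
      if (length(idx) * max_frac * total_len > L)
        stop("n_taxa too large to satisfy divergence constraints at ",
             "this sequence length")
      root <- strsplit(random_dna(L), "")[[1L]]
      pool <- sample.int(L)
      used <- 0L
      pool_row <- LINEAGE_POOL[((g - 1L) %% nrow(LINEAGE_POOL)) + 1L, ]
      gname <- sprintf("Genus_%02d", g)
      for (i in idx) {
        n_mut <- round(runif(1L, 0.031, 0.044) * total_len)
        pos <- pool[(used + 1L):(used + n_mut)]
        used <- used + n_mut
        mutant <- root
        shift <- sample.int(3L, n_mut, replace = TRUE)
        mutant[pos] <- c("A", "C", "G", "T")[
          (match(mutant[pos], c("A", "C", "G", "T")) - 1L + shift) %% 4L + 1L]
        cores[i] <- paste(mutant, collapse = "")
        genus_of[i] <- gname
        lineage[i] <- paste("Bacteria", pool_row$phylum, pool_row$class,
                            pool_row$order, pool_row$family, gname, sep = ";")
      }
    }
    out <- reference_db(sprintf("REF_%03d", seq_len(n_taxa)),
                        paste0(fwd_site, cores, rev_site_rc), lineage)
    attr(out, "fwd_site") <- fwd_site
    attr(out, "rev_site") <- rev_site_rc
    attr(out, "core") <- cores
    out
  })

  # verify the divergence structure with the aligner itself
  genus <- lineage_ranks(db)[, "genus"]
  pairs <- utils::combn(nrow(db), 2L)
  if (ncol(pairs) > 300L)
    pairs <- pairs[, with_seed(seed + 1L,
                               sample.int(ncol(pairs), 300L)), drop = FALSE]
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    d <- pairwise_distance(db$seq[i], db$seq[j])
    ok <- if (genus[i] == genus[j]) d >= 0.055 && d <= 0.095 else d >= 0.10
    if (!ok)
      stop("generation error: reference divergence constraint violated (",
           db$ref_id[i], " vs ", db$ref_id[j], ", d = ", round(d, 4), ")")
  }
  db
}

# resolve the default enrichment plan: first taxon of the first two phyla,
# enriched in group 1 at the package's reference fold changes
resolve_enrichment <- function(design, refs) {
  if (!is.null(design$enriched_taxa)) {
    missing <- setdiff(design$enriched_taxa$taxon, refs$ref_id)
    if (length(missing))
      stop("enriched taxa absent from references: ",
           paste(missing, collapse = ", "))
    return(design$enriched_taxa)
  }
  phyla <- lineage_ranks(refs)[, "phylum"]
  first_of_phylum <- !duplicated(phyla)
  picks <- refs$ref_id[first_of_phylum][1:2]
  data.frame(taxon = picks, group = design$group_names[1L],
             fold_change = c(7.2, 20.2), stringsAsFactors = FALSE)
}

#' Simulate per-sample community abundances
#'
#' One log-normal base abundance per taxon is shared by both groups; taxa in
#' the enrichment plan have their expectation multiplied by `fold_change`
#' in their group; every sample adds independent log-normal jitter
#' (`sample_sigma`) before normalisation, so each row is a relative
#' abundance vector summing to 1.
#'
#' @param design a [simulation_design].
#' @param refs a `reference_db` with at least `n_taxa` entries.
#' @param seed RNG seed (`NULL` draws from the current stream).
#' @return a list: `weights` (samples x taxa relative abundances), `groups`
#'   (factor), `sample_ids`, `enrichment` (the resolved plan).
#' @export
simulate_abundances <- function(design, refs, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"),
            nrow(refs) >= design$n_taxa)
  refs <- refs[seq_len(design$n_taxa), , drop = FALSE]
  plan <- resolve_enrichment(design, refs)
  groups <- factor(rep(design$group_names, each = design$n_per_group),
                   levels = design$group_names)
  sample_ids <- sprintf("%s_%02d", groups,
                        rep(seq_len(design$n_per_group), times = 2L))
  with_seed(seed, {
    base <- exp(rnorm(design$n_taxa, design$lognormal_mu,
                      design$lognormal_sigma))
    names(base) <- refs$ref_id
    w <- matrix(rep(base, each = length(sample_ids)),
                nrow = length(sample_ids),
                dimnames = list(sample_ids, refs$ref_id))
    for (k in seq_len(nrow(plan))) {
      rows <- groups == plan$group[k]
      w[rows, plan$taxon[k]] <- w[rows, plan$taxon[k]] * plan$fold_change[k]
    }
    jitter <- matrix(exp(rnorm(length(w), 0, design$sample_sigma)),
                     nrow = nrow(w))
    w <- w * jitter
    w <- w / rowSums(w)
    list(weights = w, groups = groups, sample_ids = sample_ids,
         enrichment = plan)
  })
}

BASES <- c("A", "C", "G", "T")

apply_substitutions <- function(chars, rate) {
  err <- which(runif(length(chars)) < rate)
  if (length(err)) {
    shift <- sample.int(3L, length(err), replace = TRUE)
    chars[err] <- BASES[(match(chars[err], BASES) - 1L + shift) %% 4L + 1L]
  }
  chars
}

# "good" reads use a 0.2% per-base low-quality rate, rejection-sampled so
# they always satisfy the 1% rule (retention of clean reads is then 100%
# by construction); "poor" reads use 2% unconditioned, so most of them
# fail and realized low-quality fractions bracket the QC threshold.
draw_quals <- function(n, poor) {
  low_rate <- if (poor) 0.02 else 0.002
  repeat {
    low <- runif(n) < low_rate
    if (poor || sum(low) <= floor(0.01 * n)) break
  }
  q <- sample(36:40, n, replace = TRUE)
  nlow <- sum(low)
  if (nlow) q[low] <- sample(8:14, nlow, replace = TRUE)
  q
}

#' Simulate a full synthetic study
#'
#' Writes one FASTQ per sample, a metadata TSV with SCFA and growth
#' covariates, and a JSON manifest (design echo, seed, file list,
#' warnings), and returns the ground truth: per-sample clean-read taxon
#' counts, a label for every emitted read (`clean`, `chimera` with parents
#' and breakpoint, `truncated`, `offtarget`), the per-sample expected
#' abundances, and the covariate means used. Identical seeds give
#' byte-identical outputs.
#'
#' @param design a [simulation_design].
#' @param refs a `reference_db` from [simulate_reference_db()] (its primer
#'   flank attributes are required).
#' @param outdir output directory (created if needed).
#' @param rarefy_depth intended downstream rarefaction depth; if
#'   `reads_per_sample` is below it a warning is recorded in the manifest.
#' @return a list: `fastq` (named paths), `metadata` (data frame, also
#'   written as TSV), `truth`, `manifest_path`.
#' @export
simulate_study <- function(design, refs, outdir,
                           rarefy_depth = 1800L) {
  stopifnot(inherits(design, "simulation_design"))
  cores <- attr(refs, "core")
  fwd_site <- attr(refs, "fwd_site")
  rev_site <- attr(refs, "rev_site")
  if (is.null(cores) || is.null(fwd_site))
    stop("refs must come from simulate_reference_db()")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  refs_used <- refs[seq_len(design$n_taxa), , drop = FALSE]
  cores <- cores[seq_len(design$n_taxa)]
  genus <- lineage_ranks(refs_used)[, "genus"]

  with_seed(design$seed, {
    ab <- simulate_abundances(design, refs_used, seed = NULL)
    n_samples <- length(ab$sample_ids)
    taxon_counts <- matrix(0L, n_samples, design$n_taxa,
                           dimnames = list(ab$sample_ids, refs_used$ref_id))
    labels <- vector("list", n_samples)
    fastq <- setNames(character(n_samples), ab$sample_ids)

    class_probs <- c(chimera = design$chimera_frac,
                     truncated = design$truncated_frac,
                     offtarget = design$offtarget_short_frac)
    class_probs <- c(clean = 1 - sum(class_probs), class_probs)

    for (s in seq_len(n_samples)) {
      sid <- ab$sample_ids[s]
      N <- design$reads_per_sample
      cls <- sample(names(class_probs), N, replace = TRUE,
                    prob = class_probs)
      poor <- runif(N) < design$poor_quality_frac
      seqs <- character(N)
      quals <- vector("list", N)
      lab <- data.frame(sample_id = sid,
                        read_id = sprintf("%s_R%06d", sid, seq_len(N)),
                        class = cls, taxon = NA_character_,
                        parent_a = NA_character_, parent_b = NA_character_,
                        breakpoint = NA_integer_, poor_quality = poor,
                        stringsAsFactors = FALSE)
      for (i in seq_len(N)) {
        if (cls[i] == "clean") {
          t_i <- sample.int(design$n_taxa, 1L, prob = ab$weights[s, ])
          core <- cores[t_i]
          lab$taxon[i] <- refs_used$ref_id[t_i]
          taxon_counts[s, t_i] <- taxon_counts[s, t_i] + 1L
        } else if (cls[i] == "chimera") {
          repeat {
            pa <- sample.int(design$n_taxa, 1L, prob = ab$weights[s, ])
            pb <- sample.int(design$n_taxa, 1L, prob = ab$weights[s, ])
            if (genus[pa] != genus[pb]) break
          }
          f <- runif(1L, 0.25, 0.75)
          la <- nchar(cores[pa]); lb <- nchar(cores[pb])
          cut_a <- round(f * la)
          core <- paste0(substr(cores[pa], 1L, cut_a),
                         substr(cores[pb], round(f * lb) + 1L, lb))
          lab$parent_a[i] <- refs_used$ref_id[pa]
          lab$parent_b[i] <- refs_used$ref_id[pb]
          lab$breakpoint[i] <- cut_a
        } else if (cls[i] == "truncated") {
          t_i <- sample.int(design$n_taxa, 1L, prob = ab$weights[s, ])
          core <- cores[t_i]
          r <- sample(8:14, 1L)
          junk <- random_dna(r)
          core <- if (runif(1L) < 0.5)
            paste0(junk, substr(core, r + 1L, nchar(core)))
          else
            paste0(substr(core, 1L, nchar(core) - r), junk)
          lab$taxon[i] <- refs_used$ref_id[t_i]
        } else { # offtarget: too short to be the targeted amplicon
          core <- random_dna(sample(150:320, 1L))
        }
        chars <- apply_substitutions(strsplit(core, "")[[1L]],
                                     design$error_rate)
        seqs[i] <- paste0(fwd_site, paste(chars, collapse = ""), rev_site)
        quals[[i]] <- draw_quals(nchar(seqs[i]), poor[i])
      }
      reads <- quality_reads(lab$read_id, seqs, quals)
      fastq[s] <- file.path(outdir, paste0(sid, ".fastq"))
      write_fastq(reads, fastq[s])
      labels[[s]] <- lab
    }

    scfa <- data.frame(
      covariate = c("acetate_mM", "propionate_mM", "butyrate_mM",
                    "isobutyrate_mM", "valerate_mM", "isovalerate_mM"),
      mean_a = c(49.9, 40.25, 8.1, 0.8, 2.3, 1.0),
      mean_b = c(42.9, 31.06, 7.6, 0.7, 1.9, 0.9),
      sd = c(9.6, 9.6, 2.5, 0.3, 0.8, 0.35),
      stringsAsFactors = FALSE)
    growth <- data.frame(
      covariate = c("body_length", "heart_girth", "hip_width"),
      mean_a = c(81, 86, 22.5), mean_b = c(80, 85, 22.0),
      sd = c(3, 3, 1), stringsAsFactors = FALSE)
    covs <- rbind(scfa, growth)

    md <- data.frame(sample_id = ab$sample_ids,
                     treatment = as.character(ab$groups),
                     stringsAsFactors = FALSE)
    is_a <- ab$groups == design$group_names[1L]
    for (k in seq_len(nrow(covs))) {
      mu <- ifelse(is_a, covs$mean_a[k], covs$mean_b[k])
      md[[covs$covariate[k]]] <- pmax(0.01, rnorm(n_samples, mu, covs$sd[k]))
    }
    md$total_scfa_mM <- rowSums(md[, scfa$covariate])
    md <- md[, c("sample_id", "treatment", scfa$covariate, "total_scfa_mM",
                 growth$covariate)]
    md_path <- file.path(outdir, "metadata.tsv")
    write.table(md, md_path, sep = "\t", quote = FALSE, row.names = FALSE)

    truth <- list(taxon_counts = taxon_counts,
                  read_labels = do.call(rbind, labels),
                  abundances = ab$weights,
                  enrichment = ab$enrichment,
                  covariate_means = covs)

    warnings <- character()
    if (design$reads_per_sample < rarefy_depth)
      warnings <- c(warnings, sprintf(
        "reads_per_sample (%d) below intended rarefaction depth (%d)",
        design$reads_per_sample, rarefy_depth))
    manifest <- list(design = unclass(design), seed = design$seed,
                     files = c(unname(fastq), md_path),
                     n_reads_per_sample = design$reads_per_sample,
                     warnings = warnings)
    manifest_path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)

    list(fastq = fastq, metadata = md, truth = truth,
         manifest_path = manifest_path)
  })
}
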