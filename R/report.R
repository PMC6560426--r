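# Publication-shaped study report: phylum/family aggregation with group
# means +/- SEM and unadjusted pooled-t p-values, main-OTU tables split by
# phylum with per-phylum Total rows (column sums of the printed, 2-decimal
# values, so the printed table is internally consistent), an OTU x covariate
# Pearson matrix, and a rarefied alpha-diversity comparison.

group_summary_row <- function(feature_id, va, vb) {
  cmp <- ttest_from_raw(va, vb, feature_id = feature_id)
  cmp
}

#' Build the full study report
#'
#' @param table a screened [otu_table].
#' @param assignments taxonomy assignments from [classify_otus()] covering
#'   all OTUs in `table`.
#' @param metadata sample metadata (see [read_metadata()]); every sample in
#'   `table` must be present.
#' @param cfg a [pipeline_config] (rarefaction depth, main-OTU threshold,
#'   seed).
#' @param groups optional character of length 2 fixing group order (first
#'   group is "A" in all outputs); defaults to order of appearance in the
#'   metadata.
#' @param rarefy_depth override of `cfg$rarefy_depth` for the alpha table.
#' @return a `study_report` list: `taxon_summary`, `main_otus`,
#'   `main_otu_totals`, `correlations`, `alpha_summary`, `groups`.
#' @export
build_report <- function(table, assignments, metadata, cfg = pipeline_config(),
                         groups = NULL, rarefy_depth = cfg$rarefy_depth) {
  counts <- otu_counts(table)
  samples <- colnames(counts)
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  if (is.null(groups)) groups <- unique(md$treatment)
  stopifnot(length(groups) == 2L, all(md$treatment %in% groups))
  in_a <- md$treatment == groups[1L]

  rel <- relative_abundance(table)
  otu_ids <- rownames(rel)
  phylum <- assignments$phylum[match(otu_ids, assignments$otu_id)]
  family <- assignments$family[match(otu_ids, assignments$otu_id)]
  if (anyNA(phylum))
    stop("assignments do not cover all OTUs")

  cmp_rows <- function(features, mat) {
    do.call(rbind, lapply(features, function(f)
      group_summary_row(f, mat[f, in_a], mat[f, !in_a])))
  }

  # --- phylum / family aggregation -------------------------------------
  agg_by <- function(labels) {
    groups_of <- split(seq_along(labels), labels)
    t(vapply(groups_of,
             function(i) colSums(rel[i, , drop = FALSE]),
             numeric(ncol(rel))))
  }
  phy_mat <- agg_by(phylum)
  phy_order <- order(-rowMeans(phy_mat))
  taxon_rows <- list()
  for (ph in rownames(phy_mat)[phy_order]) {
    ph_row <- group_summary_row(ph, phy_mat[ph, in_a], phy_mat[ph, !in_a])
    ph_row$level <- "phylum"
    ph_row$phylum <- ph
    taxon_rows[[length(taxon_rows) + 1L]] <- ph_row
    members <- which(phylum == ph)
    fam_mat <- t(vapply(split(members, family[members]),
                        function(i) colSums(rel[i, , drop = FALSE]),
                        numeric(ncol(rel))))
    keep <- rowMeans(fam_mat[, in_a, drop = FALSE]) >= 1 |
      rowMeans(fam_mat[, !in_a, drop = FALSE]) >= 1
    kept <- rownames(fam_mat)[keep]
    for (fam in kept[order(-rowMeans(fam_mat[kept, , drop = FALSE]))]) {
      fr <- group_summary_row(fam, fam_mat[fam, in_a], fam_mat[fam, !in_a])
      fr$level <- "family"
      fr$phylum <- ph
      taxon_rows[[length(taxon_rows) + 1L]] <- fr
    }
    if (any(!keep)) {
      other <- colSums(fam_mat[!keep, , drop = FALSE])
      orow <- group_summary_row(paste("Other", ph), other[in_a], other[!in_a])
      orow$level <- "family"
      orow$phylum <- ph
      taxon_rows[[length(taxon_rows) + 1L]] <- orow
    }
  }
  taxon_summary <- do.call(rbind, taxon_rows)

  # --- main OTU tables --------------------------------------------------
  main_ids <- select_main_otus(rel, ifelse(in_a, groups[1L], groups[2L]),
                               threshold_percent = 100 * cfg$main_otu_threshold)
  main <- cmp_rows(main_ids, rel)
  main$phylum <- phylum[match(main_ids, otu_ids)]
  bh <- assignments[match(main_ids, assignments$otu_id), ]
  main$closest_taxon <- sprintf("%s (%d%%)", bh$best_hit_id,
                                bh$best_hit_identity)
  main <- main[order(main$phylum, -main$mean_a), ]

  totals <- do.call(rbind, lapply(split(main, main$phylum), function(d)
    data.frame(phylum = d$phylum[1L],
               total_a = sum(round(d$mean_a, 2)),
               total_b = sum(round(d$mean_b, 2)),
               n_otus = nrow(d), stringsAsFactors = FALSE)))
  rownames(totals) <- NULL

  # --- Pearson correlations main OTUs x numeric covariates -------------
  num_cols <- names(md)[vapply(md, is.numeric, logical(1))]
  correlations <- do.call(rbind, unlist(lapply(main_ids, function(o)
    lapply(num_cols, function(cv)
      pearson_cor(rel[o, ], md[[cv]], otu_id = o, covariate = cv))),
    recursive = FALSE))

  # --- alpha diversity comparison --------------------------------------
  rar <- rarefy(counts, depth = rarefy_depth, seed = cfg$seed)
  alpha <- alpha_indices(rar)
  idx_cols <- c("chao1", "observed_otus", "shannon", "simpson", "coverage")
  alpha_summary <- do.call(rbind, lapply(idx_cols, function(ic)
    group_summary_row(ic, alpha[[ic]][in_a], alpha[[ic]][!in_a])))

  structure(list(taxon_summary = taxon_summary,
                 main_otus = main,
                 main_otu_totals = totals,
                 correlations = correlations,
                 alpha_summary = alpha_summary,
                 alpha_per_sample = alpha,
                 groups = groups),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("rumenamp study report (group A = ", x$groups[1L],
      ", group B = ", x$groups[2L], ")\n\n", sep = "")
  cat("Phylum-level relative abundance (%):\n")
  ph <- x$taxon_summary[x$taxon_summary$level == "phylum", ]
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  %-20s %6.2f +/- %5.2f  vs %6.2f +/- %5.2f   p = %.4f\n",
                ph$feature_id[i], ph$mean_a[i], ph$sem_a[i],
                ph$mean_b[i], ph$sem_b[i], ph$p_value[i]))
  cat(sprintf("\n%d main OTU(s); totals per phylum:\n", nrow(x$main_otus)))
  for (i in seq_len(nrow(x$main_otu_totals)))
    cat(sprintf("  %-20s A %6.2f  B %6.2f  (%d OTUs)\n",
                x$main_otu_totals$phylum[i], x$main_otu_totals$total_a[i],
                x$main_otu_totals$total_b[i], x$main_otu_totals$n_otus[i]))
  invisible(x)
}

#' Run the full pipeline on a set of FASTQ files
#'
#' Read screening, OTU clustering, artifact screens, taxonomy, and the study
#' report, in one call.
#'
#' @param fastq_paths named character vector of per-sample FASTQ paths.
#' @param refs a `reference_db`.
#' @param metadata sample metadata data frame.
#' @param cfg a [pipeline_config].
#' @param rarefy_depth override for the alpha-diversity rarefaction depth.
#' @return a list: `qc` (per-sample report), `table` (screened
#'   [otu_table]), `verdicts`, `assignments`, `report`.
#' @export
run_pipeline <- function(fastq_paths, refs, metadata, cfg = pipeline_config(),
                         rarefy_depth = cfg$rarefy_depth) {
  scr <- screen_study(fastq_paths, cfg)
  table <- cluster_greedy(scr$reads$seq, scr$reads$sample_id,
                          cutoff = cfg$cluster_cutoff,
                          prefix = cfg$otu_prefix)
  screened <- apply_screens(table, refs, cfg)
  model <- train_classifier(refs)
  assignments <- classify_otus(screened$table, model, refs, seed = cfg$seed)
  report <- build_report(screened$table, assignments, metadata, cfg,
                         rarefy_depth = rarefy_depth)
  list(qc = scr$report, table = screened$table,
       verdicts = screened$verdicts, assignments = assignments,
       report = report)
}
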