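# Readers/writers for the standard formats the pipeline consumes: FASTQ
# (Phred+33 only; modern MiSeq), reference FASTA + lineage TSV, sample
# metadata TSV, and the publication-shaped output tables. Counts are kept as
# integers end-to-end; percentages are always derived on demand.

#' Construct a set of quality reads
#'
#' @param read_id character vector of read identifiers.
#' @param seq character vector of IUPAC DNA strings.
#' @param quals list of integer Phred score vectors, one per read, each the
#'   same length as its sequence.
#' @return an object of class `quality_reads`.
#' @export
quality_reads <- function(read_id = character(), seq = character(),
                          quals = list()) {
  stopifnot(length(read_id) == length(seq), length(seq) == length(quals))
  seq <- toupper(seq)
  lens_ok <- nchar(seq) == lengths(quals)
  if (!all(lens_ok))
    stop("sequence/quality length mismatch for read(s): ",
         paste(read_id[!lens_ok], collapse = ", "))
  rng <- if (length(quals)) range(unlist(quals, use.names = FALSE)) else c(0, 0)
  if (length(quals) && (rng[1] < 0 || rng[2] > 60))
    stop("Phred scores must lie in [0, 60]")
  structure(list(read_id = read_id, seq = seq, quals = quals),
            class = "quality_reads")
}

#' @export
length.quality_reads <- function(x) length(x$read_id)

#' @export
`[.quality_reads` <- function(x, i) {
  quality_reads(x$read_id[i], x$seq[i], x$quals[i])
}

#' @export
print.quality_reads <- function(x, ...) {
  cat(sprintf("<quality_reads> %d read(s)\n", length(x)))
  if (length(x)) {
    n <- min(3L, length(x))
    for (i in seq_len(n))
      cat(sprintf("  %s  %d nt\n", x$read_id[i], nchar(x$seq[i])))
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTQ file (Phred+33)
#'
#' Parses a well-formed 4-line-record FASTQ file. Malformed records (missing
#' header, sequence/quality length mismatch) raise an error naming the
#' 1-based record index.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a [quality_reads] object (empty file gives zero reads).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(quality_reads())
  if (length(lines) %% 4L != 0L)
    stop("FASTQ file ", path, ": line count not a multiple of 4 (record ",
         length(lines) %/% 4L + 1L, " incomplete)")
  n <- length(lines) %/% 4L
  h <- lines[seq(1L, by = 4L, length.out = n)]
  s <- lines[seq(2L, by = 4L, length.out = n)]
  p <- lines[seq(3L, by = 4L, length.out = n)]
  q <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(h, "@") | !startsWith(p, "+"))
  if (length(bad))
    stop("FASTQ file ", path, ": malformed header at record ", bad[1L])
  bad <- which(nchar(s) != nchar(q))
  if (length(bad))
    stop("FASTQ file ", path,
         ": sequence/quality length mismatch at record ", bad[1L])
  ids <- sub("^@", "", sub("\\s.*$", "", h))
  quals <- lapply(q, function(z) utf8ToInt(z) - 33L)
  quality_reads(ids, s, quals)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads a [quality_reads] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "quality_reads"))
  qstr <- vapply(reads$quals,
                 function(q) intToUtf8(as.integer(q) + 33L),
                 character(1))
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qstr))
  writeLines(out, path)
  invisible(path)
}

#' Read a reference database (FASTA plus lineage TSV)
#'
#' Every FASTA identifier must appear in the taxonomy TSV
#' (`id<TAB>lineage`, lineage ranks semicolon-separated coarse to fine:
#' domain; phylum; class; order; family; genus, optionally species).
#'
#' @param fasta_path path to the reference FASTA.
#' @param taxonomy_path path to the lineage TSV (no header).
#' @return a `reference_db` data frame with columns `ref_id`, `seq`,
#'   `lineage`.
#' @export
read_reference_fasta <- function(fasta_path, taxonomy_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dna))
  tax <- read.delim(taxonomy_path, header = FALSE, sep = "\t",
                    col.names = c("ref_id", "lineage"),
                    colClasses = "character")
  missing <- setdiff(ids, tax$ref_id)
  if (length(missing))
    stop("FASTA id(s) absent from taxonomy file: ",
         paste(missing, collapse = ", "))
  reference_db(ids, as.character(dna),
               tax$lineage[match(ids, tax$ref_id)])
}

#' Construct a reference database object
#'
#' @param ref_id,seq,lineage parallel character vectors; `lineage` holds
#'   semicolon-separated ranks ordered coarse to fine.
#' @return a `reference_db` data frame.
#' @export
reference_db <- function(ref_id, seq, lineage) {
  stopifnot(length(ref_id) == length(seq), length(seq) == length(lineage))
  if (any(!nzchar(lineage)))
    stop("every reference needs a non-empty lineage")
  db <- data.frame(ref_id = ref_id, seq = toupper(seq), lineage = lineage,
                   stringsAsFactors = FALSE)
  class(db) <- c("reference_db", "data.frame")
  db
}

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus")

#' Split reference lineages into a rank matrix
#'
#' @param db a `reference_db` or a character vector of lineage strings.
#' @return a character matrix with one row per reference and the first six
#'   rank columns named `domain` to `genus` (extra ranks kept unnamed).
#' @export
lineage_ranks <- function(db) {
  lin <- if (is.data.frame(db)) db$lineage else db
  parts <- strsplit(lin, ";", fixed = TRUE)
  parts <- lapply(parts, trimws)
  width <- max(lengths(parts), 6L)
  mat <- t(vapply(parts, function(p) c(p, rep(NA_character_, width - length(p))),
                  character(width)))
  colnames(mat) <- c(RANK_NAMES, rep("", width - 6L))[seq_len(width)]
  rownames(mat) <- if (is.data.frame(db)) db$ref_id else NULL
  mat
}

#' Write a reference database to FASTA + taxonomy TSV
#'
#' @param db a `reference_db`.
#' @param fasta_path,taxonomy_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference_db <- function(db, fasta_path, taxonomy_path) {
  dna <- Biostrings::DNAStringSet(setNames(db$seq, db$ref_id))
  Biostrings::writeXStringSet(dna, fasta_path, width = 80L)
  writeLines(paste(db$ref_id, db$lineage, sep = "\t"), taxonomy_path)
  invisible(c(fasta_path, taxonomy_path))
}

#' Read a sample metadata TSV
#'
#' Expects a header with at least `sample_id` and `treatment`; remaining
#' columns (SCFA concentrations in mM, growth metrics) must be numeric.
#'
#' @param path path to the metadata TSV.
#' @return a data frame keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment")
  missing <- setdiff(need, names(md))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  md
}

#' Write the pipeline output tables
#'
#' Emits an OTU count TSV (rows = OTUs, columns = samples), a relative
#' abundance TSV in percent (two decimals, each column summing to 100 before
#' rounding), and a taxonomy TSV. The count table round-trips losslessly via
#' [read_otu_counts()].
#'
#' @param table an `otu_table`.
#' @param assignments a data frame of taxonomy assignments covering all OTU
#'   ids (as from [classify_otus()]), or `NULL` to skip the taxonomy file.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(table, assignments = NULL, outdir = ".") {
  stopifnot(inherits(table, "otu_table"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character()

  counts <- otu_counts(table)
  cpath <- file.path(outdir, "otu_counts.tsv")
  write.table(data.frame(otu_id = rownames(counts), counts,
                         check.names = FALSE),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, cpath)

  rel <- relative_abundance(table)
  rpath <- file.path(outdir, "otu_relabund.tsv")
  write.table(data.frame(otu_id = rownames(rel),
                         format(round(rel, 2), nsmall = 2, trim = TRUE),
                         check.names = FALSE),
              rpath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, rpath)

  if (!is.null(assignments)) {
    missing <- setdiff(rownames(counts), assignments$otu_id)
    if (length(missing))
      stop("assignments missing OTU id(s): ", paste(missing, collapse = ", "))
    tpath <- file.path(outdir, "otu_taxonomy.tsv")
    write.table(assignments, tpath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, tpath)
  }
  invisible(paths)
}

#' Read back an OTU count table written by [write_tables()]
#'
#' @param path path to `otu_counts.tsv`.
#' @return an integer matrix (OTUs x samples).
#' @export
read_otu_counts <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$otu_id
  m
}
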