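# Independent oracles and fixture builders. The aligner oracle is a second,
# pure-R implementation of the published alignment rules (match +1,
# mismatch -1, gap -2, free end gaps; endpoint = max score over last
# row/column with ties to larger i then larger j; traceback prefers
# diagonal, then up, then left) written against the same definition as the
# C++ code, not against the C++ code itself.

oracle_align <- function(a, b, global = FALSE) {
  A <- strsplit(toupper(a), "")[[1L]]
  B <- strsplit(toupper(b), "")[[1L]]
  m <- length(A); n <- length(B); GAP <- -2L
  H <- matrix(0L, m + 1L, n + 1L)
  if (global) {
    H[, 1L] <- GAP * (0:m)
    H[1L, ] <- GAP * (0:n)
  }
  for (i in seq_len(m)) {
    s <- ifelse(A[i] == B, 1L, -1L)
    for (j in seq_len(n)) {
      H[i + 1L, j + 1L] <- max(H[i, j] + s[j], H[i, j + 1L] + GAP,
                               H[i + 1L, j] + GAP)
    }
  }
  if (global) {
    best <- H[m + 1L, n + 1L]; ie <- m; je <- n
  } else {
    best <- -Inf; ie <- 0L; je <- 0L
    for (i in 0:m) {
      sc <- H[i + 1L, n + 1L]
      if (sc > best || (sc == best && (i > ie || (i == ie && n > je)))) {
        best <- sc; ie <- i; je <- n
      }
    }
    for (j in 0:n) {
      sc <- H[m + 1L, j + 1L]
      if (sc > best || (sc == best && (m > ie || (m == ie && j > je)))) {
        best <- sc; ie <- m; je <- j
      }
    }
  }
  i <- ie; j <- je
  moves <- character()
  while (i > 0L && j > 0L) {
    s <- if (A[i] == B[j]) 1L else -1L
    if (H[i, j] + s == H[i + 1L, j + 1L]) {
      moves <- c("d", moves); i <- i - 1L; j <- j - 1L
    } else if (H[i, j + 1L] + GAP == H[i + 1L, j + 1L]) {
      moves <- c("u", moves); i <- i - 1L
    } else {
      moves <- c("l", moves); j <- j - 1L
    }
  }
  if (global) {
    moves <- c(rep("u", i), rep("l", j), moves)
    i <- 0L; j <- 0L
  }
  # strip terminal gap-column runs (end gaps; excluded from counts)
  keep <- seq_along(moves)
  while (length(keep) && moves[keep[1L]] != "d") keep <- keep[-1L]
  while (length(keep) && moves[keep[length(keep)]] != "d")
    keep <- keep[-length(keep)]
  matches <- 0L; mismatches <- 0L; gaps <- 0L
  if (length(keep)) {
    lead <- seq_len(keep[1L] - 1L)
    ia <- i + sum(moves[lead] %in% c("d", "u"))
    ib <- j + sum(moves[lead] %in% c("d", "l"))
    for (p in keep) {
      if (moves[p] == "d") {
        ia <- ia + 1L; ib <- ib + 1L
        if (A[ia] == B[ib]) matches <- matches + 1L
        else mismatches <- mismatches + 1L
      } else if (moves[p] == "u") {
        ia <- ia + 1L; gaps <- gaps + 1L
      } else {
        ib <- ib + 1L; gaps <- gaps + 1L
      }
    }
  }
  cols <- matches + mismatches + gaps
  list(score = best, matches = matches, mismatches = mismatches,
       gaps = gaps, columns = cols,
       distance = if (cols == 0L) 1 else (mismatches + gaps) / cols)
}

# distance oracle matching pairwise_distance(): canonical argument order,
# global alignment, end-gap columns excluded
oracle_distance <- function(a, b) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  oracle_align(a, b, global = TRUE)$distance
}

# exhaustive single-linkage partition at a cutoff (union-find over all
# pairwise distances); returns canonical integer component labels
sl_partition <- function(seqs, cutoff = 0.05) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (pairwise_distance(seqs[i], seqs[j]) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# canonical labels for any partition vector, for partition equality checks
canon_partition <- function(x) match(x, unique(x))

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# mutate exactly `k` distinct positions of a sequence (substitutions only)
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample(length(chars), k)
  shift <- sample(3L, k, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  chars[pos] <- bases[(match(chars[pos], bases) - 1L + shift) %% 4L + 1L]
  paste(chars, collapse = "")
}

# small shared reference database fixtures (built once per test run)
tiny_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_reference_db(12L, seed = 7L)
    cache
  }
})

medium_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_reference_db(24L, seed = 19L)
    cache
  }
})

# handcrafted reference for deterministic end-integrity boundary tests:
# 30 nt of A flank, then a core starting with G-runs so C-junk prefixes are
# guaranteed mismatches wherever they land
flank_ref_db <- function() {
  set.seed(404)
  core <- paste0(strrep("G", 12L), rand_dna(400L))
  reference_db("FR_001", paste0(strrep("A", 30L), core, strrep("A", 30L)),
               "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Genus_X")
}

# small synthetic study shared by the pipeline-level tests
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      refs <- tiny_refs()
      design <- simulation_design(n_per_group = 3L, n_taxa = 12L,
                                  reads_per_sample = 250L, seed = 11L)
      dir <- file.path(tempdir(), "rumenamp-small-study")
      sim <- simulate_study(design, refs, dir, rarefy_depth = 150L)
      cache <<- list(refs = refs, design = design, sim = sim, dir = dir)
    }
    cache
  }
})
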