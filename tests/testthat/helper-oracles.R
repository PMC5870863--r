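# Independent brute-force oracles for the three metric families, plus a
# random-instance generator and a cached mini-cohort shared across files.

library(data.table)

# Literal per-base counting on logical vectors over [0, L).
oracle_nucleotide <- function(gold, pred, L = 1e5) {
  mask <- function(segs, type) {
    m <- new.env(parent = emptyenv())
    for (ch in unique(segs$chrom)) {
      v <- logical(L)
      s <- segs[segs$chrom == ch & segs$type == type, , drop = FALSE]
      if (nrow(s)) for (i in seq_len(nrow(s))) {
        v[(s$start[i] + 1):s$end[i]] <- TRUE
      }
      m[[ch]] <- v
    }
    m
  }
  chroms <- union(unique(gold$chrom), unique(pred$chrom))
  TP <- PP <- GP <- 0
  for (type in c("amp", "del")) {
    gm <- mask(as.data.frame(gold), type); pm <- mask(as.data.frame(pred), type)
    for (ch in chroms) {
      g <- if (!is.null(gm[[ch]])) gm[[ch]] else logical(L)
      p <- if (!is.null(pm[[ch]])) pm[[ch]] else logical(L)
      TP <- TP + sum(g & p); PP <- PP + sum(p); GP <- GP + sum(g)
    }
  }
  list(TP = TP, PP = PP, GP = GP,
       precision = if (PP > 0) TP / PP else NA_real_,
       sensitivity = if (GP > 0) TP / GP else NA_real_)
}

# Exhaustive union-coverage oracle machinery: one per-base mask per
# (chromosome, type), then literal loops over intervals.
oracle_masks <- function(segs, L = 1e5) {
  segs <- as.data.frame(segs)
  m <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(segs))) {
    key <- paste0(segs$chrom[i], "/", segs$type[i])
    if (is.null(m[[key]])) m[[key]] <- logical(L)
    v <- m[[key]]
    v[(segs$start[i] + 1):segs$end[i]] <- TRUE
    m[[key]] <- v
  }
  m
}

oracle_covered_fraction <- function(chrom, start, end, type, masks, L = 1e5) {
  v <- masks[[paste0(chrom, "/", type)]]
  if (is.null(v)) return(0)
  sum(v[(start + 1):end]) / (end - start)
}

oracle_interval <- function(gold, pred, threshold = 0.8, L = 1e5) {
  gold <- as.data.frame(gold); pred <- as.data.frame(pred)
  gm <- oracle_masks(gold, L); pm <- oracle_masks(pred, L)
  TP <- 0L
  if (nrow(pred)) for (i in seq_len(nrow(pred))) {
    if (oracle_covered_fraction(pred$chrom[i], pred$start[i], pred$end[i],
                                pred$type[i], gm, L) >= threshold) {
      TP <- TP + 1L
    }
  }
  TD <- 0L
  if (nrow(gold)) for (i in seq_len(nrow(gold))) {
    if (oracle_covered_fraction(gold$chrom[i], gold$start[i], gold$end[i],
                                gold$type[i], pm, L) >= threshold) {
      TD <- TD + 1L
    }
  }
  PP <- nrow(pred); GP <- nrow(gold)
  list(TP = TP, PP = PP, GP = GP, TD = TD,
       precision = if (PP > 0) TP / PP else NA_real_,
       sensitivity = if (GP > 0) TD / GP else NA_real_)
}

oracle_gene <- function(gold, pred, genes, threshold = 0.8, L = 1e5) {
  genes <- as.data.frame(genes)
  gm <- oracle_masks(gold, L); pm <- oracle_masks(pred, L)
  gene_set <- function(masks, type) {
    hits <- character(0)
    for (i in seq_len(nrow(genes))) {
      if (oracle_covered_fraction(genes$chrom[i], genes$start[i],
                                  genes$end[i], type, masks,
                                  L) >= threshold) {
        hits <- c(hits, genes$name[i])
      }
    }
    hits
  }
  TP <- PP <- GP <- 0L
  for (type in c("amp", "del")) {
    pg <- gene_set(pm, type); gg <- gene_set(gm, type)
    TP <- TP + length(intersect(pg, gg))
    PP <- PP + length(pg); GP <- GP + length(gg)
  }
  list(TP = TP, PP = PP, GP = GP,
       precision = if (PP > 0) TP / PP else NA_real_,
       sensitivity = if (GP > 0) TP / GP else NA_real_)
}

random_segments <- function(n, L = 1e5, chroms = c("c1", "c2"),
                            max_len = 5000) {
  if (n == 0) return(segments())
  start <- floor(runif(n, 0, L - max_len))
  len <- ceiling(runif(n, 1, max_len))
  segments(sample(chroms, n, replace = TRUE), start, start + len,
           sample(c("amp", "del"), n, replace = TRUE))
}

# Mini-cohort cache: built once per test run, shared across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_env$manifest)) {
    dir <- file.path(tempdir(), "scnabench-fixtures")
    .fixture_env$manifest <- generate_fixtures(dir, seed = 101L)
    .fixture_env$dir <- dir
  }
  .fixture_env$manifest
}

fixture_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    .fixture_env$calls <- call_cohort(fixture_cohort())
  }
  .fixture_env$calls
}
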