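# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats rbinom rmultinom rnorm runif qbinom setNames
#' @importFrom utils head tail
NULL

# Run `expr` under a locally-seeded RNG without disturbing the caller's RNG
# state. All exported stochastic operations funnel through this, so a given
# (operation, seed) pair is reproducible regardless of call order.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed; keeps results below .Machine$integer.max.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629L)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("scnabench_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("scnabench_config_error", "error")))
}

# data.table(chrom,start,end) -> sorted, merged (union) per chromosome.
merge_intervals <- function(x) {
  x <- as.data.table(x)[, .(chrom, start = as.numeric(start), end = as.numeric(end))]
  if (nrow(x) == 0L) return(x)
  setorder(x, chrom, start, end)
  x[, grp := cumsum(c(1L, tail(start, -1L) > head(cummax(end), -1L))), by = chrom]
  out <- x[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  out[]
}

# Total width of the pairwise intersection of two interval sets (each first
# reduced to a union), computed per chromosome with IRanges.
intersect_width <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::IRanges(start = a[chrom == ch, start] + 1, end = a[chrom == ch, end])
    ib <- IRanges::IRanges(start = b[chrom == ch, start] + 1, end = b[chrom == ch, end])
    tot <- tot + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  tot
}

interval_width <- function(x) {
  x <- merge_intervals(x)
  if (nrow(x) == 0L) return(0)
  sum(x$end - x$start)
}

# For each query interval, the number of its bases covered by the union of
# subject intervals (same chromosome). Queries need not be disjoint.
overlap_bases_per_query <- function(query, subject) {
  query <- as.data.table(query)
  if (nrow(query) == 0L) return(numeric(0))
  subject <- merge_intervals(subject)
  out <- numeric(nrow(query))
  if (nrow(subject) == 0L) return(out)
  qdt <- data.table(idx = seq_len(nrow(query)), chrom = query$chrom,
                    start = as.numeric(query$start), end = as.numeric(query$end))
  for (ch in intersect(unique(qdt$chrom), unique(subject$chrom))) {
    qi <- qdt[chrom == ch]
    si <- subject[chrom == ch]
    irq <- IRanges::IRanges(start = qi$start + 1, end = qi$end)
    irs <- IRanges::IRanges(start = si$start + 1, end = si$end)
    hits <- IRanges::findOverlaps(irq, irs)
    if (length(hits) == 0L) next
    ov <- IRanges::width(IRanges::pintersect(irq[S4Vectors::queryHits(hits)],
                                             irs[S4Vectors::subjectHits(hits)]))
    contrib <- data.table(i = qi$idx[S4Vectors::queryHits(hits)], w = ov)
    agg <- contrib[, .(w = sum(w)), by = i]
    out[agg$i] <- agg$w
  }
  out
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Read/write plain (optionally gzipped) FASTA via Biostrings.
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
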