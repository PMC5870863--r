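#' Describe a chromosome for the toy-reference generator
#'
#' A chromosome model carries the length, the centromere position (which
#' defines the p and q arms used to place arm-length events) and a target GC
#' content for the sequence generator.
#'
#' @param name chromosome name, e.g. `"chr1"`.
#' @param length chromosome length in bp (> 0).
#' @param centromere centromere position in bp, strictly inside the
#'   chromosome. Defaults to the midpoint.
#' @param gc target GC fraction in `[0, 1]` (default 0.45, roughly the
#'   genome-wide GC of capture targets).
#' @return A one-row `data.table` with class `chrom_model` columns.
#' @export
chrom_model <- function(name, length, centromere = NULL, gc = 0.45) {
  length <- as.numeric(length)
  if (is.na(length) || length <= 0) {
    stop_config("chromosome '", name, "' must have length > 0")
  }
  if (is.null(centromere)) centromere <- floor(length / 2)
  centromere <- as.numeric(centromere)
  if (centromere <= 0 || centromere >= length) {
    stop_config("centromere of '", name, "' must lie strictly inside (0, length)")
  }
  if (gc < 0 || gc > 1) stop_config("gc must be in [0, 1]")
  data.table(name = as.character(name), length = length,
             centromere = centromere, gc = as.numeric(gc))
}

#' Default toy chromosome set
#'
#' Fourteen 1 Mb chromosomes (28 arms), sized so that a full study design --
#' 16 arm-length plus 100 focal somatic events per replicate, on top of the
#' germline background, all mutually non-overlapping in reference space --
#' can be placed at desk-scale runtimes with arms to spare.
#'
#' @param n_chrom number of chromosomes.
#' @param length per-chromosome length in bp.
#' @param gc target GC fraction.
#' @return A `data.table` of chromosome models.
#' @export
default_chrom_models <- function(n_chrom = 14, length = 1e6, gc = 0.45) {
  rbindlist(lapply(seq_len(n_chrom), function(i) {
    chrom_model(sprintf("chr%d", i), length = length, gc = gc)
  }))
}

#' Generate a toy reference genome
#'
#' Produces a deterministic random nucleotide sequence per chromosome whose
#' GC content tracks the model's target in 1 kb windows: each window gets
#' `round(gc * w)` G/C bases at random positions, so windowed GC is exact up
#' to rounding.
#'
#' @param chrom_models a `data.table` of [chrom_model()] rows.
#' @param seed integer seed; the same seed always yields the same genome.
#' @param window window size in bp for GC placement.
#' @return An object of class `toy_reference`: a named character vector of
#'   sequences with the chromosome models attached as attribute `models`.
#' @export
generate_toy_reference <- function(chrom_models = default_chrom_models(),
                                   seed = 1L, window = 1000L) {
  chrom_models <- as.data.table(chrom_models)
  if (any(chrom_models$length <= 0)) stop_config("all chromosome lengths must be > 0")
  seqs <- with_seed(seed, {
    vapply(seq_len(nrow(chrom_models)), function(i) {
      L <- as.integer(chrom_models$length[i])
      gc <- chrom_models$gc[i]
      bases <- character(L)
      starts <- seq.int(1L, L, by = window)
      for (s in starts) {
        w <- min(window, L - s + 1L)
        n_gc <- round(gc * w)
        is_gc <- logical(w)
        if (n_gc > 0) is_gc[sample.int(w, n_gc)] <- TRUE
        b <- character(w)
        b[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
        b[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
        bases[s:(s + w - 1L)] <- b
      }
      paste(bases, collapse = "")
    }, character(1))
  })
  names(seqs) <- chrom_models$name
  structure(seqs, models = chrom_models, class = "toy_reference")
}

#' @export
print.toy_reference <- function(x, ...) {
  m <- attr(x, "models")
  cat(sprintf("toy_reference: %d chromosome(s), %.2f Mb total\n",
              nrow(m), sum(m$length) / 1e6))
  invisible(x)
}

gc_fraction <- function(seq) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq), "GC")
  as.numeric(f) / nchar(seq)
}
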