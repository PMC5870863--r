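#' Export / import the copy-number gold standard
#'
#' Writes the copy-number records of a truth table (germline CNVs and
#' somatic SCNAs; small variants are implanted for read realism but are not
#' part of the copy-number gold standard) as a BED-like TSV with 0-based
#' half-open intervals and columns `chrom, start, end, type, zygosity,
#' clone_ids, origin, arm_flag`. `type` is `amp` or `del`. The file
#' round-trips losslessly through [read_truth()].
#'
#' @param truth a [truth_table()] or variant table.
#' @param path output path.
#' @param what which origins to export (default both).
#' @return `read_truth` returns a `data.table` with the eight columns above.
#' @export
export_truth <- function(truth, path, what = c("germline", "somatic")) {
  dt <- as.data.table(truth)
  cnv <- if (nrow(dt)) {
    dt[vtype %in% c("CNV_DEL", "CNV_AMP") & origin %in% what]
  } else dt
  out <- if (nrow(cnv)) {
    data.table(chrom = cnv$chrom,
               start = format(cnv$start, scientific = FALSE, trim = TRUE),
               end = format(cnv$end, scientific = FALSE, trim = TRUE),
               type = ifelse(cnv$vtype == "CNV_AMP", "amp", "del"),
               zygosity = cnv$zygosity,
               clone_ids = ifelse(cnv$clone_ids == "", ".", cnv$clone_ids),
               origin = cnv$origin,
               arm_flag = ifelse(cnv$arm_flag, 1L, 0L))
  } else {
    data.table(chrom = character(), start = character(), end = character(),
               type = character(), zygosity = character(),
               clone_ids = character(), origin = character(),
               arm_flag = integer())
  }
  fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("chrom", "type", "zygosity",
                                              "clone_ids", "origin")))
  if (nrow(dt)) {
    dt[, start := as.numeric(start)]
    dt[, end := as.numeric(end)]
    dt[, clone_ids := ifelse(clone_ids == ".", "", clone_ids)]
    dt[, arm_flag := arm_flag == 1L]
  } else {
    dt <- data.table(chrom = character(), start = numeric(), end = numeric(),
                     type = character(), zygosity = character(),
                     clone_ids = character(), origin = character(),
                     arm_flag = logical())
  }
  dt[]
}

#' Gold-standard segments from a truth table
#'
#' Collapses truth records to the typed segment form consumed by the
#' evaluation functions. By default only somatic records enter the gold
#' standard (germline CNVs are present in both tumor and control and are
#' not somatic alterations).
#'
#' @param truth a truth table or the output of [read_truth()].
#' @param origins origins to keep.
#' @return `data.table` with chrom, start, end, type (and clone_ids,
#'   zygosity, arm_flag carried through when present).
#' @export
gold_segments <- function(truth, origins = "somatic") {
  dt <- as.data.table(truth)
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), type = character()))
  }
  if ("vtype" %in% names(dt)) {
    dt <- dt[vtype %in% c("CNV_DEL", "CNV_AMP")]
    dt[, type := ifelse(vtype == "CNV_AMP", "amp", "del")]
  }
  dt <- dt[origin %in% origins]
  keep <- intersect(c("chrom", "start", "end", "type", "zygosity",
                      "clone_ids", "arm_flag"), names(dt))
  dt[, ..keep]
}
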