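#' Typed copy-number segments: constructors and file adapters
#'
#' A segment set is a `data.table` with columns `chrom`, `start`, `end`
#' (0-based half-open) and `type` (`"amp"` or `"del"`). `read_segments`
#' reads the generic BED-like TSV dialect `chrom start end type`;
#' `read_seg` reads SEG files (`ID chrom loc.start loc.end num.mark
#' seg.mean`, 1-based closed coordinates) and maps the mean log-ratio
#' column to amp/del by sign against a threshold.
#'
#' @param chrom,start,end,type segment fields (vectors recycled as usual).
#' @return A segment `data.table`.
#' @export
segments <- function(chrom = character(), start = numeric(),
                     end = numeric(), type = character()) {
  dt <- data.table(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), type = as.character(type))
  if (nrow(dt) && any(dt$start >= dt$end)) {
    stop_data("segments must satisfy start < end")
  }
  if (nrow(dt) && !all(dt$type %in% c("amp", "del"))) {
    stop_data("segment type must be 'amp' or 'del'")
  }
  dt
}

#' @rdname segments
#' @param path input file.
#' @export
read_segments <- function(path) {
  dt <- fread(path, header = "auto")
  setnames(dt, seq_len(4L), c("chrom", "start", "end", "type"))
  segments(dt$chrom, dt$start, dt$end, dt$type)
}

#' @rdname segments
#' @param log2_threshold |seg.mean| above which a SEG row becomes a call.
#' @export
read_seg <- function(path, log2_threshold = 0) {
  dt <- fread(path, header = TRUE)
  setnames(dt, seq_len(6L),
           c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean"))
  dt <- dt[abs(seg.mean) > log2_threshold]
  segments(dt$chrom, dt$loc.start - 1, dt$loc.end,
           ifelse(dt$seg.mean > 0, "amp", "del"))
}

#' @rdname segments
#' @param x segment table to write.
#' @export
write_segments <- function(x, path) {
  out <- as.data.table(x)[, .(chrom,
                              start = format(start, scientific = FALSE,
                                             trim = TRUE),
                              end = format(end, scientific = FALSE,
                                           trim = TRUE), type)]
  fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a BED file of intervals (targets or genes)
#'
#' Three columns (chrom, start, end) for targets; a fourth `name` column for
#' gene models.
#'
#' @param path BED(-like) file, 0-based half-open, with or without header.
#' @return A `data.table`.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = "auto")
  nms <- c("chrom", "start", "end", "name")[seq_len(min(4L, ncol(dt)))]
  setnames(dt, seq_along(nms), nms)
  dt[, chrom := as.character(chrom)]
  dt[]
}

#' @rdname read_bed
#' @param x interval table.
#' @export
write_bed <- function(x, path) {
  out <- as.data.table(x)
  out <- copy(out)
  out[, start := format(start, scientific = FALSE, trim = TRUE)]
  out[, end := format(end, scientific = FALSE, trim = TRUE)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Restrict segments to capture-target space
#'
#' In targeted assays only events touching the target regions are
#' observable. `mode = "clip"` intersects segments with the target space
#' (for nucleotide metrics); `mode = "filter"` keeps a segment whole iff it
#' overlaps at least one target by >= 1 bp (for interval and gene metrics).
#'
#' @param segs segment table.
#' @param targets target intervals.
#' @param mode `"clip"` or `"filter"`.
#' @return Restricted segment table (other columns carried through for
#'   `filter`; `clip` keeps chrom/start/end/type plus any attribute columns
#'   of the clipped piece's parent).
#' @export
restrict_to_targets <- function(segs, targets, mode = c("clip", "filter")) {
  mode <- match.arg(mode)
  segs <- as.data.table(segs)
  if (nrow(segs) == 0L) return(segs)
  targets <- merge_intervals(targets)
  if (mode == "filter") {
    ov <- overlap_bases_per_query(segs[, .(chrom, start, end)], targets)
    return(segs[ov >= 1])
  }
  out <- list()
  for (ch in unique(segs$chrom)) {
    tg <- targets[chrom == ch]
    if (nrow(tg) == 0L) next
    si <- segs[chrom == ch]
    irq <- IRanges::IRanges(start = si$start + 1, end = si$end)
    irs <- IRanges::IRanges(start = tg$start + 1, end = tg$end)
    hits <- IRanges::findOverlaps(irq, irs)
    if (length(hits) == 0L) next
    pieces <- IRanges::pintersect(irq[S4Vectors::queryHits(hits)],
                                  irs[S4Vectors::subjectHits(hits)])
    piece <- si[S4Vectors::queryHits(hits)]
    piece[, start := as.numeric(IRanges::start(pieces) - 1)]
    piece[, end := as.numeric(IRanges::end(pieces))]
    out[[ch]] <- piece
  }
  if (length(out) == 0L) return(segs[0L])
  res <- rbindlist(out)
  setorder(res, chrom, start, end)
  res[]
}
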