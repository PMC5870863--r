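#' Per-target depth of a fragment pool
#'
#' Counts, for every capture target, the number of fragment bases whose
#' reference projection falls inside the target. Alignment-free: the
#' projections come from the truth tags carried by the simulator's read
#' names, not from a BAM.
#'
#' @param pool fragment pool with `rproj` (from [capture_filter()] or
#'   [read_pool_fastq()]).
#' @param targets BED-like target table (merged internally; order of the
#'   merged table is preserved in the output).
#' @return `data.table`: chrom, start, end, depth (total on-target bases).
#' @export
target_depth <- function(pool, targets) {
  targets <- merge_intervals(targets)
  if (nrow(targets) == 0L) stop_data("empty target set")
  out <- copy(targets)[, depth := 0]
  blocks <- rproj_blocks(pool)
  if (nrow(blocks) == 0L) return(out[])
  for (ch in unique(out$chrom)) {
    ti <- which(out$chrom == ch)
    bi <- blocks[chrom == ch]
    if (nrow(bi) == 0L) next
    irt <- IRanges::IRanges(start = out$start[ti] + 1, end = out$end[ti])
    irb <- IRanges::IRanges(start = bi$start + 1, end = bi$end)
    hits <- IRanges::findOverlaps(irt, irb)
    if (length(hits) == 0L) next
    w <- IRanges::width(IRanges::pintersect(irt[S4Vectors::queryHits(hits)],
                                            irb[S4Vectors::subjectHits(hits)]))
    agg <- data.table(i = ti[S4Vectors::queryHits(hits)],
                      w = w)[, .(w = sum(w)), by = i]
    out[agg$i, depth := agg$w]
  }
  out[]
}

#' Naive depth-ratio SCNA caller
#'
#' A deliberately simple, fully self-contained caller used to close the
#' simulate-call-evaluate loop without any external tool. Per target it
#' computes `log2(tumor / control)` after library-size normalization
#' (control depths are scaled so both libraries have equal total on-target
#' mass), masks targets with zero control depth, and merges runs of at
#' least `min_consecutive` consecutive targets beyond the threshold into
#' amp (ratio high) or del (ratio low) segments spanning from the first to
#' the last target of the run.
#'
#' @param tumor,control fragment pools (with `rproj`) or per-target depth
#'   tables from [target_depth()].
#' @param targets target table (ignored when depth tables are supplied).
#' @param log2_threshold absolute log2-ratio call threshold (default 0.3).
#' @param min_consecutive minimum run length in targets (default 2).
#' @return A typed segment `data.table` (chrom, start, end, type).
#' @export
naive_depth_caller <- function(tumor, control, targets = NULL,
                               log2_threshold = 0.3, min_consecutive = 2L) {
  as_depth <- function(x) {
    x <- as.data.table(x)
    if ("depth" %in% names(x)) x else target_depth(x, targets)
  }
  td <- as_depth(tumor); cd <- as_depth(control)
  if (nrow(td) != nrow(cd)) stop_data("tumor and control depth tables differ")
  if (sum(td$depth) == 0 || sum(cd$depth) == 0) {
    stop_data("zero total depth in tumor or control")
  }
  scale <- sum(td$depth) / sum(cd$depth)
  dt <- copy(td)
  dt[, ctrl := cd$depth * scale]
  dt[, state := "none"]
  dt[ctrl == 0, state := "masked"]
  dt[state == "none" & log2(depth / ctrl) > log2_threshold, state := "amp"]
  dt[state == "none" & log2(pmax(depth, 0) / ctrl) < -log2_threshold,
     state := "del"]
  calls <- list()
  for (ch in unique(dt$chrom)) {
    di <- dt[chrom == ch]
    r <- rle(di$state)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    sel <- which(r$values %in% c("amp", "del") &
                   r$lengths >= min_consecutive)
    for (k in sel) {
      calls[[length(calls) + 1L]] <-
        data.table(chrom = ch, start = di$start[idx_start[k]],
                   end = di$end[idx_end[k]], type = r$values[k])
    }
  }
  if (length(calls) == 0L) {
    return(segments())
  }
  out <- rbindlist(calls)
  setorder(out, chrom, start)
  out[]
}
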