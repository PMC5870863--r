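#' Metric report container
#'
#' Precision/sensitivity report for one evaluation approach. Precision is
#' TP/PP; sensitivity is TP/GP for the nucleotide and gene approaches and
#' TD/GP for the interval approach (TD = gold intervals recovered). A zero
#' denominator yields `NA`, keeping "no calls" distinct from "all calls
#' wrong".
#'
#' @param approach `"nucleotide"`, `"interval"` or `"gene"`.
#' @param TP,PP,GP,TD counts (TD only for the interval approach).
#' @return A one-row `data.table` of class `metric_report`.
#' @export
metric_report <- function(approach, TP, PP, GP, TD = NA_real_) {
  sens_num <- if (approach == "interval") TD else TP
  dt <- data.table(approach = approach, TP = TP, PP = PP, GP = GP, TD = TD,
                   precision = if (PP > 0) TP / PP else NA_real_,
                   sensitivity = if (GP > 0) sens_num / GP else NA_real_)
  setattr(dt, "class", c("metric_report", class(dt)))
  dt
}

split_by_type <- function(segs) {
  segs <- as.data.table(segs)
  list(amp = segs[type == "amp"], del = segs[type == "del"])
}

#' Nucleotide-based precision and sensitivity
#'
#' TP is the number of nucleotides in the intersection of predicted and
#' gold-standard intervals of the same type; PP and GP are the nucleotides
#' in the (per-type unions of the) predicted and gold intervals.
#'
#' @param gold,pred typed segment tables.
#' @return A [metric_report()].
#' @export
nucleotide_metrics <- function(gold, pred) {
  g <- split_by_type(gold); p <- split_by_type(pred)
  TP <- intersect_width(p$amp, g$amp) + intersect_width(p$del, g$del)
  PP <- interval_width(p$amp) + interval_width(p$del)
  GP <- interval_width(g$amp) + interval_width(g$del)
  metric_report("nucleotide", TP, PP, GP)
}

#' Interval-based precision and sensitivity
#'
#' A predicted interval is a true positive when it overlaps the union of
#' same-type gold intervals over at least `threshold` of its own length
#' (inclusive); a gold interval is discovered (TD) when covered to at least
#' `threshold` of its length by the union of same-type predicted intervals.
#' Precision = TP/PP, sensitivity = TD/GP.
#'
#' @param gold,pred typed segment tables.
#' @param threshold reciprocal-coverage threshold in (0, 1], default 0.8.
#' @return A [metric_report()].
#' @export
interval_metrics <- function(gold, pred, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stop_config("threshold must be in (0, 1]")
  g <- split_by_type(gold); p <- split_by_type(pred)
  TP <- 0L; TD <- 0L
  for (t in c("amp", "del")) {
    if (nrow(p[[t]])) {
      ov <- overlap_bases_per_query(p[[t]], g[[t]])
      TP <- TP + sum(ov >= threshold * (p[[t]]$end - p[[t]]$start))
    }
    if (nrow(g[[t]])) {
      ov <- overlap_bases_per_query(g[[t]], p[[t]])
      TD <- TD + sum(ov >= threshold * (g[[t]]$end - g[[t]]$start))
    }
  }
  metric_report("interval", TP, nrow(p$amp) + nrow(p$del),
                nrow(g$amp) + nrow(g$del), TD)
}

# Gene names covered >= threshold of their length by the union of segments
# of the given type.
covered_genes <- function(segs, gene_model, threshold) {
  gm <- as.data.table(gene_model)
  if (nrow(gm) == 0L) return(character(0))
  ov <- overlap_bases_per_query(gm[, .(chrom, start, end)], segs)
  gm$name[ov >= threshold * (gm$end - gm$start)]
}

#' Gene-based precision and sensitivity
#'
#' PP (GP) is the set of (gene, type) pairs where the gene is covered over
#' at least `threshold` of its length by predicted (gold) segments of that
#' type; TP is the size of their intersection.
#'
#' @param gold,pred typed segment tables.
#' @param gene_model gene intervals with unique `name`s.
#' @param threshold coverage threshold, default 0.8 (inclusive).
#' @return A [metric_report()].
#' @export
gene_metrics <- function(gold, pred, gene_model, threshold = 0.8) {
  gm <- as.data.table(gene_model)
  if (nrow(gm) == 0L) stop_data("empty gene model")
  if (anyDuplicated(gm$name)) stop_data("gene names must be unique")
  g <- split_by_type(gold); p <- split_by_type(pred)
  TP <- 0L; PP <- 0L; GP <- 0L
  for (t in c("amp", "del")) {
    pg <- covered_genes(p[[t]], gm, threshold)
    gg <- covered_genes(g[[t]], gm, threshold)
    TP <- TP + length(intersect(pg, gg))
    PP <- PP + length(pg)
    GP <- GP + length(gg)
  }
  metric_report("gene", TP, PP, GP)
}

#' Sensitivity stratified by allele fraction
#'
#' Bins gold variants by their expected allele fraction and reports, per
#' bin, the fraction discovered under the interval-approach TD rule
#' (covered >= `threshold` of their length by same-type predictions).
#' Default bins put every variant above 0.4 into one class, matching the
#' heterozygous 0.5 ceiling of fully clonal events.
#'
#' @param gold gold segment table with an `af` column (or supply `af`).
#' @param pred predicted segment table.
#' @param af allele fractions aligned with `gold` rows (defaults to
#'   `gold$af`).
#' @param bins bin edges (left-closed, right-open; last bin closed).
#' @param threshold TD coverage threshold.
#' @return `data.table`: bin label, n gold, n detected, sensitivity.
#' @export
stratify_sensitivity_by_af <- function(gold, pred, af = NULL,
                                       bins = c(0, 0.1, 0.2, 0.3, 0.4, 1),
                                       threshold = 0.8) {
  gold <- as.data.table(gold)
  if (is.null(af)) af <- gold$af
  if (length(af) != nrow(gold)) stop_data("need one allele fraction per gold segment")
  detected <- detected_gold(gold, pred, threshold)
  bi <- cut(af, breaks = bins, right = FALSE, include.lowest = TRUE)
  dt <- data.table(bin = bi, detected = detected)
  out <- dt[, .(n_gold = .N, n_detected = sum(detected)), keyby = bin]
  out <- out[data.table(bin = levels(bi)), on = "bin"]
  out[is.na(n_gold), `:=`(n_gold = 0L, n_detected = 0L)]
  out[, sensitivity := ifelse(n_gold > 0, n_detected / n_gold, NA_real_)]
  out[]
}

# TD rule per gold segment: covered >= threshold of its length by the union
# of same-type predictions.
detected_gold <- function(gold, pred, threshold = 0.8) {
  gold <- as.data.table(gold)
  if (nrow(gold) == 0L) return(logical(0))
  p <- split_by_type(pred)
  det <- logical(nrow(gold))
  for (t in c("amp", "del")) {
    sel <- which(gold$type == t)
    if (length(sel) == 0L) next
    ov <- overlap_bases_per_query(gold[sel, .(chrom, start, end)], p[[t]])
    det[sel] <- ov >= threshold * (gold$end[sel] - gold$start[sel])
  }
  det
}

#' Size-class breakdown of gold and called segments
#'
#' Each segment is binned by its own length (log-decade classes by
#' default). Called segments are flagged true positive by the interval
#' 80% rule against the union of same-type gold segments, regardless of the
#' size class of the matching gold event.
#'
#' @param gold,pred typed segment tables.
#' @param breaks size-class edges in bp.
#' @param threshold overlap threshold for the TP flag.
#' @return `data.table`: size class x type with `n_gold`, `n_called`,
#'   `n_called_tp`.
#' @export
stratify_by_size <- function(gold, pred,
                             breaks = c(0, 1e3, 1e4, 1e5, 1e6, 1e7, 1e8, Inf),
                             threshold = 0.8) {
  labels <- c("<1 Kb", "1-10 Kb", "10-100 Kb", "100 Kb-1 Mb", "1-10 Mb",
              "10-100 Mb", ">100 Mb")[seq_len(length(breaks) - 1L)]
  gold <- as.data.table(gold); pred <- as.data.table(pred)
  bin_of <- function(x) cut(x$end - x$start, breaks = breaks, labels = labels,
                            right = FALSE)
  g <- split_by_type(gold)
  tp <- if (nrow(pred)) {
    ov <- numeric(nrow(pred))
    for (t in c("amp", "del")) {
      sel <- which(pred$type == t)
      if (length(sel)) {
        ov[sel] <- overlap_bases_per_query(pred[sel, .(chrom, start, end)],
                                           g[[t]])
      }
    }
    ov >= threshold * (pred$end - pred$start)
  } else logical(0)
  grid <- CJ(size_class = labels, type = c("amp", "del"))
  gcount <- if (nrow(gold)) {
    gold[, .(n_gold = .N), by = .(size_class = bin_of(gold), type)]
  } else NULL
  pcount <- if (nrow(pred)) {
    data.table(size_class = bin_of(pred), type = pred$type, tp = tp)[
      , .(n_called = .N, n_called_tp = sum(tp)), by = .(size_class, type)]
  } else NULL
  out <- grid
  out <- if (!is.null(gcount)) gcount[out, on = c("size_class", "type")] else
    out[, n_gold := 0L]
  out <- if (!is.null(pcount)) pcount[out, on = c("size_class", "type")] else
    out[, `:=`(n_called = 0L, n_called_tp = 0L)]
  for (cc in c("n_gold", "n_called", "n_called_tp")) {
    if (!cc %in% names(out)) out[, (cc) := 0L]
    out[is.na(get(cc)), (cc) := 0L]
  }
  out[, size_class := factor(size_class, levels = labels)]
  setorder(out, size_class, type)
  setcolorder(out, c("size_class", "type", "n_gold", "n_called",
                     "n_called_tp"))
  out[]
}

#' Log ratio of predicted vs gold copy-number-altered gene counts
#'
#' Counts genes covered >= `threshold` of their length by predicted and by
#' gold segments (any type) and reports `log2(n_pred / n_gold)`. Values
#' near zero indicate concordant calling; positive values overcalling. A
#' sample is flagged `low_scna` when its gold standard holds ten or fewer
#' events (after target restriction, if applied upstream).
#'
#' @param gold,pred typed segment tables.
#' @param gene_model gene intervals with names.
#' @param threshold gene-coverage threshold.
#' @param pseudocount added to both counts (0 disables; with 0, a zero
#'   count yields `NA`).
#' @param base logarithm base.
#' @param low_scna_cutoff gold-event count at or below which the sample is
#'   flagged.
#' @return One-row `data.table`: `n_pred_genes`, `n_gold_genes`,
#'   `log_ratio`, `low_scna`.
#' @export
gene_count_log_ratio <- function(gold, pred, gene_model, threshold = 0.8,
                                 pseudocount = 0, base = 2,
                                 low_scna_cutoff = 10L) {
  gm <- as.data.table(gene_model)
  g <- split_by_type(gold); p <- split_by_type(pred)
  n_gold <- length(union(covered_genes(g$amp, gm, threshold),
                         covered_genes(g$del, gm, threshold)))
  n_pred <- length(union(covered_genes(p$amp, gm, threshold),
                         covered_genes(p$del, gm, threshold)))
  num <- n_pred + pseudocount; den <- n_gold + pseudocount
  lr <- if (num > 0 && den > 0) log(num / den, base = base) else NA_real_
  data.table(n_pred_genes = n_pred, n_gold_genes = n_gold, log_ratio = lr,
             low_scna = nrow(as.data.table(gold)) <= low_scna_cutoff)
}

#' Evaluate one call set against one gold standard
#'
#' Applies the target-restriction rule (clip for nucleotide metrics,
#' >= 1 bp filter for interval and gene metrics) to both sides, then
#' computes all three metric families.
#'
#' @param gold,pred typed segment tables (un-restricted).
#' @param targets capture targets; `NULL` skips restriction.
#' @param gene_model gene intervals; `NULL` skips gene metrics.
#' @param threshold overlap threshold for interval/gene approaches.
#' @return `data.table` with one [metric_report()] row per approach.
#' @export
evaluate_calls <- function(gold, pred, targets = NULL, gene_model = NULL,
                           threshold = 0.8) {
  if (!is.null(targets)) {
    gold_clip <- restrict_to_targets(gold, targets, "clip")
    pred_clip <- restrict_to_targets(pred, targets, "clip")
    gold_filt <- restrict_to_targets(gold, targets, "filter")
    pred_filt <- restrict_to_targets(pred, targets, "filter")
  } else {
    gold_clip <- gold_filt <- as.data.table(gold)
    pred_clip <- pred_filt <- as.data.table(pred)
  }
  out <- list(nucleotide_metrics(gold_clip, pred_clip),
              interval_metrics(gold_filt, pred_filt, threshold))
  if (!is.null(gene_model)) {
    out <- c(out, list(gene_metrics(gold_filt, pred_filt, gene_model,
                                    threshold)))
  }
  rbindlist(out)
}
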