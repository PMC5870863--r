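#' Sample design: clone proportions, admixture series, depth
#'
#' The default clone proportions are the five-subclone mixture of the study
#' design this package reproduces (0.27, 0.29, 0.36, 0.06, 0.02), and the
#' default admixture series runs from 0% to 90% control reads in steps of
#' 10%, giving ten admixed tumors per clonal mixture.
#'
#' @param clone_proportions numeric vector summing to 1.
#' @param admixture_levels admixture fractions, each in `[0, 1)`.
#' @param total_read_pairs read pairs per final sample.
#' @param seed integer seed.
#' @return A list of class `sample_design`.
#' @export
sample_design <- function(clone_proportions = c(0.27, 0.29, 0.36, 0.06, 0.02),
                          admixture_levels = seq(0, 0.9, by = 0.1),
                          total_read_pairs = 20000L, seed = 1L) {
  if (abs(sum(clone_proportions) - 1) > 1e-9) {
    stop_config("clone proportions must sum to 1")
  }
  if (length(admixture_levels) == 0L ||
      any(admixture_levels < 0 | admixture_levels >= 1)) {
    stop_config("admixture levels must be non-empty and in [0, 1)")
  }
  structure(list(clone_proportions = clone_proportions,
                 admixture_levels = admixture_levels,
                 total_read_pairs = as.integer(total_read_pairs),
                 seed = seed),
            class = "sample_design")
}

#' Mix clone read pools into a heterogeneous tumor pool
#'
#' Per-clone read counts are drawn from a multinomial with the clone
#' proportions as probabilities; reads are then sampled without replacement
#' within each clone pool.
#'
#' @param clone_pools list of fragment pools (one per clone).
#' @param proportions clone proportions (same length as `clone_pools`).
#' @param n_total number of read pairs to draw.
#' @param seed integer seed.
#' @return A single fragment pool with a `source` column naming the clone.
#' @export
mix_clones <- function(clone_pools, proportions, n_total, seed = 1L) {
  if (length(clone_pools) != length(proportions)) {
    stop_config("need one proportion per clone pool")
  }
  with_seed(seed, {
    counts <- if (n_total > 0) {
      as.integer(rmultinom(1L, n_total, proportions))
    } else integer(length(clone_pools))
    picks <- lapply(seq_along(clone_pools), function(ci) {
      pool <- as.data.table(clone_pools[[ci]])
      if (counts[ci] > nrow(pool)) {
        stop_data("clone ", ci, " pool exhausted: need ", counts[ci],
                  " read pairs, pool holds ", nrow(pool))
      }
      if (counts[ci] == 0L) return(pool[0L])
      sel <- pool[sample.int(nrow(pool), counts[ci])]
      sel[, source := sprintf("clone%d", ci)]
      sel
    })
    rbindlist(picks, use.names = TRUE, fill = TRUE)
  })
}

#' Dilute a tumor pool with control reads
#'
#' The final tumor sample holds `round(a * n_total)` control read pairs and
#' `n_total - round(a * n_total)` tumor read pairs (constant total depth:
#' adding control reads displaces tumor reads), shuffled. An independent
#' matched control sample of the same depth is drawn from the control pool.
#'
#' @param tumor_pool mixed tumor fragment pool (see [mix_clones()]).
#' @param control_pool control fragment pool; must hold at least
#'   `round(a * n_total) + n_total` read pairs (contamination plus matched
#'   normal).
#' @param a admixture level in `[0, 1)`.
#' @param n_total read pairs per sample.
#' @param seed integer seed.
#' @return A list of class `mixed_sample`: `tumor` and `control` fragment
#'   pools, `a`, and `counts` (realized read pairs per source).
#' @export
admix <- function(tumor_pool, control_pool, a, n_total, seed = 1L) {
  if (a < 0 || a >= 1) stop_config("admixture level must be in [0, 1)")
  tumor_pool <- as.data.table(tumor_pool)
  control_pool <- as.data.table(control_pool)
  n_ctrl <- as.integer(round(a * n_total))
  n_tum <- n_total - n_ctrl
  if (n_tum > nrow(tumor_pool)) {
    stop_data("tumor pool exhausted: need ", n_tum, ", have ",
              nrow(tumor_pool))
  }
  if (n_ctrl + n_total > nrow(control_pool)) {
    stop_data("control pool exhausted: need ", n_ctrl + n_total, ", have ",
              nrow(control_pool))
  }
  with_seed(seed, {
    ci <- sample.int(nrow(control_pool), n_ctrl + n_total)
    contam <- control_pool[ci[seq_len(n_ctrl)]]
    if (nrow(contam)) contam[, source := "control"]
    matched <- control_pool[ci[n_ctrl + seq_len(n_total)]]
    if (nrow(matched)) matched[, source := "control"]
    tum <- tumor_pool[sample.int(nrow(tumor_pool), n_tum)]
    tumor <- rbind(tum, contam, use.names = TRUE, fill = TRUE)
    tumor <- tumor[sample.int(nrow(tumor))]
    counts <- table(factor(tumor$source))
    structure(list(tumor = tumor, control = matched, a = a,
                   counts = as.list(counts), n_total = n_total),
              class = "mixed_sample")
  })
}

#' Expected allele fraction of a variant in an admixed sample
#'
#' Linear purity-clonality-zygosity model:
#' `AF = (1 - a) * sum over carrying clones of p_c * z`, with `z = 0.5` for
#' heterozygous and `1` for homozygous variants. For a heterozygous variant
#' carried by every clone this gives the 0.5 ceiling of a fully clonal
#' heterozygous event in a pure tumor.
#'
#' @param variants variant table (needs `zygosity` and `clone_ids`).
#' @param design a [sample_design()] (supplies clone proportions).
#' @param a admixture level.
#' @return Numeric vector of expected allele fractions.
#' @export
expected_allele_fraction <- function(variants, design, a) {
  variants <- as.data.table(variants)
  p <- design$clone_proportions
  if (nrow(variants) == 0L) return(numeric(0))
  mass <- vapply(strsplit(variants$clone_ids, ","), function(ids) {
    ids <- as.integer(ids[nzchar(ids)])
    if (length(ids) == 0L) return(1)  # germline: in every cell
    if (any(ids < 1L | ids > length(p))) {
      stop_data("clone id outside design: ", paste(ids, collapse = ","))
    }
    sum(p[ids])
  }, numeric(1))
  z <- ifelse(variants$zygosity == "hom", 1, 0.5)
  af <- (1 - a) * mass * z
  # germline variants are also in the admixed control reads
  germ <- variants$clone_ids == ""
  af[germ] <- z[germ]
  af
}

#' Truth allele-fraction table across an admixture series
#'
#' @param truth truth table (somatic records are used).
#' @param design a [sample_design()].
#' @return Long `data.table`: variant id, admixture level `a`, `af`.
#' @export
truth_af_table <- function(truth, design) {
  dt <- as.data.table(truth)[origin == "somatic"]
  rbindlist(lapply(design$admixture_levels, function(a) {
    data.table(id = dt$id, a = a,
               af = expected_allele_fraction(dt, design, a))
  }))
}
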