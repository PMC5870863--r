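#' Configuration for synthetic variant-catalog sampling
#'
#' Counts and size distributions for the germline background and the
#' per-replicate somatic events. Copy-number counts default to the study
#' design this package reproduces: 939 germline deletions, 1199 germline
#' duplications, and per tumor replicate 16 arm-length events plus 50 focal
#' deletions and 50 focal amplifications, with 90% of copy-number variants
#' heterozygous. Small-variant counts are desk-scale stand-ins for the
#' millions of SNPs/indels a human genome carries, and are freely scalable.
#'
#' @param germline_snv,germline_indel counts of germline small variants.
#' @param germline_cnv_del,germline_cnv_dup counts of germline copy-number
#'   deletions / duplications.
#' @param somatic_snv,somatic_indel counts of somatic small variants.
#' @param somatic_arm,somatic_del,somatic_amp counts of somatic arm-length
#'   events and focal deletions / amplifications.
#' @param het_prob probability that a sampled CNV is heterozygous.
#' @param het_prob_somatic_del,het_prob_somatic_amp optional per-category
#'   overrides of `het_prob` for somatic focal events.
#' @param germline_cnv_size,somatic_cnv_size size ranges in bp, sampled
#'   log-uniformly. The germline default is the 52 bp - 2 191 569 bp span of
#'   the germline catalog the design mirrors.
#' @param indel_size insertion/deletion length range in bp (log-uniform).
#' @param arm_min_fraction minimum fraction of a chromosome arm an
#'   arm-length event must span.
#' @param amp_copies number of extra tandem copies for amplifications;
#'   either a single integer or a vector to sample from uniformly. Default 1
#'   (one extra copy: 2 -> 3 on one haplotype), the most conservative
#'   reading of "tandem duplication".
#' @param max_retries rejection-sampling budget per requested variant.
#' @return A list of class `catalog_config`.
#' @export
catalog_config <- function(germline_snv = 2000L, germline_indel = 200L,
                           germline_cnv_del = 939L, germline_cnv_dup = 1199L,
                           somatic_snv = 300L, somatic_indel = 30L,
                           somatic_arm = 16L, somatic_del = 50L, somatic_amp = 50L,
                           het_prob = 0.9,
                           het_prob_somatic_del = NULL,
                           het_prob_somatic_amp = NULL,
                           germline_cnv_size = c(52, 2191569),
                           somatic_cnv_size = c(1e3, 1e6),
                           indel_size = c(1, 50),
                           arm_min_fraction = 0.9,
                           amp_copies = 1L,
                           max_retries = 1000L) {
  cfg <- list(germline_snv = germline_snv, germline_indel = germline_indel,
              germline_cnv_del = germline_cnv_del,
              germline_cnv_dup = germline_cnv_dup,
              somatic_snv = somatic_snv, somatic_indel = somatic_indel,
              somatic_arm = somatic_arm, somatic_del = somatic_del,
              somatic_amp = somatic_amp,
              het_prob = het_prob,
              het_prob_somatic_del = het_prob_somatic_del %||% het_prob,
              het_prob_somatic_amp = het_prob_somatic_amp %||% het_prob,
              germline_cnv_size = germline_cnv_size,
              somatic_cnv_size = somatic_cnv_size,
              indel_size = indel_size,
              arm_min_fraction = arm_min_fraction,
              amp_copies = as.integer(amp_copies),
              max_retries = max_retries)
  counts <- cfg[c("germline_snv", "germline_indel", "germline_cnv_del",
                  "germline_cnv_dup", "somatic_snv", "somatic_indel",
                  "somatic_arm", "somatic_del", "somatic_amp")]
  if (any(unlist(counts) < 0)) stop_config("all catalog counts must be >= 0")
  if (het_prob < 0 || het_prob > 1) stop_config("het_prob must be in [0, 1]")
  if (any(cfg$amp_copies < 1L)) stop_config("amp_copies must be >= 1")
  structure(cfg, class = "catalog_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_catalog <- function() {
  data.table(id = character(), chrom = character(), start = numeric(),
             end = numeric(), vtype = character(), alt_seq = character(),
             copies = integer(), zygosity = character(), hap0 = logical(),
             hap1 = logical(), origin = character(), clone_ids = character(),
             arm_flag = logical())
}

rlog_uniform <- function(n, lo, hi) {
  if (lo <= 0) stop_config("log-uniform sizes require positive bounds")
  exp(runif(n, log(lo), log(hi)))
}

# Greedy batch rejection sampler: draw candidate intervals, discard those
# overlapping already-occupied space on a shared haplotype (including
# earlier candidates of the same batch), repeat until `n` are placed or the
# retry budget is spent. `draw(k)` returns a data.table with columns chrom,
# start, end, plus any category-specific columns. With `occupy_both`,
# candidates claim both haplotypes regardless of zygosity: copy-number
# events must not overlap each other even across haplotypes, since an
# amplification and a deletion sharing reference space on opposite
# haplotypes cancel in read depth and corrupt the typed gold standard.
place_nonoverlapping <- function(n, draw, occ, category, max_retries,
                                 occupy_both = FALSE) {
  if (n == 0L) return(list(placed = empty_catalog()[0L], occ = occ))
  placed <- NULL
  draws_used <- 0L
  budget <- max_retries * n
  while (is.null(placed) || nrow(placed) < n) {
    remaining <- n - if (is.null(placed)) 0L else nrow(placed)
    if (draws_used >= budget) {
      stop_data("placement failure: could not place ", remaining, " of ", n,
                " '", category, "' variants without overlap after ",
                draws_used, " draws; genome too small or too crowded")
    }
    k <- min(max(2L * remaining, 50L), budget - draws_used)
    cand <- draw(k)
    draws_used <- draws_used + k
    # occupancy footprint: insertions block one base
    cand[, ostart := start]
    cand[, oend := pmax(end, start + 1)]
    cand[, occ0 := if (occupy_both) TRUE else hap0]
    cand[, occ1 := if (occupy_both) TRUE else hap1]
    # reject against existing occupied space, per haplotype
    keep <- rep(TRUE, nrow(cand))
    for (h in 0:1) {
      hcol <- if (h == 0) "occ0" else "occ1"
      sel <- which(cand[[hcol]])
      if (length(sel) == 0L) next
      occ_h <- occ[hap == h, .(chrom, start, end)]
      ov <- overlap_bases_per_query(
        cand[sel, .(chrom, start = ostart, end = oend)], occ_h)
      keep[sel[ov > 0]] <- FALSE
    }
    cand <- cand[keep]
    if (nrow(cand) == 0L) next
    # resolve self-overlaps greedily: sort by position, accept a candidate
    # only if it clears the running max end on each haplotype it touches
    setorder(cand, chrom, ostart, oend)
    maxend <- new.env(parent = emptyenv())
    acc <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      keys <- paste0(cand$chrom[i], "/", c(0, 1)[c(cand$occ0[i], cand$occ1[i])])
      prev <- vapply(keys, function(k) {
        if (is.null(maxend[[k]])) -1 else maxend[[k]]
      }, numeric(1))
      if (all(cand$ostart[i] >= prev)) {
        acc[i] <- TRUE
        for (k in keys) maxend[[k]] <- max(maxend[[k]] %||% -1, cand$oend[i])
      }
    }
    cand <- cand[acc]
    if (nrow(cand) > remaining) cand <- cand[seq_len(remaining)]
    if (nrow(cand) == 0L) next
    occ <- rbind(occ,
                 rbindlist(lapply(0:1, function(h) {
                   hcol <- if (h == 0) "occ0" else "occ1"
                   cand[get(hcol) == TRUE,
                        .(chrom, hap = h, start = ostart, end = oend)]
                 })))
    cand[, c("ostart", "oend", "occ0", "occ1") := NULL]
    placed <- rbind(placed, cand)
  }
  list(placed = placed, occ = occ)
}

#' Sample a synthetic variant catalog
#'
#' Draws germline and somatic variant specifications on a reference genome
#' so that no two variants touch the same bases on the same haplotype, and
#' copy-number events additionally never share reference space even across
#' haplotypes (overlapping CNVs are avoided outright: an amplification and
#' a deletion on opposite haplotypes would cancel in read depth and corrupt
#' the typed gold standard). Placement is by rejection sampling with an
#' explicit failure when the genome cannot host the requested counts. Arm-length events span at least `arm_min_fraction` of a
#' chromosome arm (p or q, as defined by the centromere) and are typed
#' amp/del with equal probability. Heterozygous variants sit on one
#' uniformly chosen haplotype, homozygous ones on both.
#'
#' @param config a [catalog_config()].
#' @param chrom_models chromosome models (see [chrom_model()]).
#' @param reference optional named character vector of chromosome sequences;
#'   when supplied, SNV alternate bases are guaranteed to differ from the
#'   reference base.
#' @param seed integer seed.
#' @return A list with `germline` and `somatic` variant tables
#'   (`data.table`s with one row per variant; 0-based half-open
#'   coordinates).
#' @export
sample_variant_catalog <- function(config = catalog_config(),
                                   chrom_models = default_chrom_models(),
                                   reference = NULL, seed = 1L) {
  stopifnot(inherits(config, "catalog_config"))
  chrom_models <- as.data.table(chrom_models)
  with_seed(seed, {
    occ <- data.table(chrom = character(), hap = integer(),
                      start = numeric(), end = numeric())
    cm <- chrom_models

    # zygosity fixed per sub-placement: het and hom variants of a category
    # are placed separately so that rejection sampling (which disfavors
    # hom candidates -- they must clear both haplotypes) cannot bias the
    # realized het fraction away from Binomial(n, p_het)
    draw_zyg <- function(k, zyg) {
      hap_pick <- sample(c(TRUE, FALSE), k, replace = TRUE)
      data.table(zygosity = zyg,
                 hap0 = zyg == "hom" | hap_pick,
                 hap1 = zyg == "hom" | !hap_pick)
    }

    draw_interval <- function(k, size_range) {
      ci <- sample.int(nrow(cm), k, replace = TRUE, prob = cm$length)
      size <- pmax(1, round(rlog_uniform(k, size_range[1], size_range[2])))
      size <- pmin(size, cm$length[ci])
      start <- floor(runif(k) * (cm$length[ci] - size + 1))
      data.table(chrom = cm$name[ci], start = start, end = start + size)
    }

    draw_arm <- function(k) {
      ci <- sample.int(nrow(cm), k, replace = TRUE)
      use_p <- runif(k) < 0.5
      a0 <- ifelse(use_p, 0, cm$centromere[ci])
      a1 <- ifelse(use_p, cm$centromere[ci], cm$length[ci])
      arm_len <- a1 - a0
      size <- ceiling(runif(k, config$arm_min_fraction, 1) * arm_len)
      start <- a0 + floor(runif(k) * (arm_len - size + 1))
      data.table(chrom = cm$name[ci], start = start, end = start + size)
    }

    categories <- list(
      list(name = "somatic_arm", n = config$somatic_arm, origin = "somatic",
           arm = TRUE),
      list(name = "germline_cnv_del", n = config$germline_cnv_del,
           origin = "germline", vtype = "CNV_DEL",
           size = config$germline_cnv_size, p_het = config$het_prob),
      list(name = "germline_cnv_dup", n = config$germline_cnv_dup,
           origin = "germline", vtype = "CNV_AMP",
           size = config$germline_cnv_size, p_het = config$het_prob),
      list(name = "somatic_del", n = config$somatic_del, origin = "somatic",
           vtype = "CNV_DEL", size = config$somatic_cnv_size,
           p_het = config$het_prob_somatic_del),
      list(name = "somatic_amp", n = config$somatic_amp, origin = "somatic",
           vtype = "CNV_AMP", size = config$somatic_cnv_size,
           p_het = config$het_prob_somatic_amp),
      list(name = "germline_indel", n = config$germline_indel,
           origin = "germline", indel = TRUE, p_het = config$het_prob),
      list(name = "somatic_indel", n = config$somatic_indel,
           origin = "somatic", indel = TRUE, p_het = config$het_prob),
      list(name = "germline_snv", n = config$germline_snv,
           origin = "germline", snv = TRUE, p_het = config$het_prob),
      list(name = "somatic_snv", n = config$somatic_snv, origin = "somatic",
           snv = TRUE, p_het = config$het_prob)
    )

    out <- list()
    for (cat in categories) {
      if (cat$n == 0L) next
      p_het <- if (isTRUE(cat$arm)) config$het_prob else cat$p_het
      n_het <- sum(runif(cat$n) < p_het)
      for (zg in c("het", "hom")) {
        n_z <- if (zg == "het") n_het else cat$n - n_het
        if (n_z == 0L) next
        draw <- local({
          cat <- cat; zg <- zg
          function(k) {
            if (isTRUE(cat$arm)) {
              d <- draw_arm(k)
              d[, vtype := sample(c("CNV_DEL", "CNV_AMP"), k, replace = TRUE)]
              d <- cbind(d, draw_zyg(k, zg))
              d[, arm_flag := TRUE]
            } else if (isTRUE(cat$indel)) {
              sz <- pmax(1L, round(rlog_uniform(k, config$indel_size[1],
                                                config$indel_size[2])))
              d <- draw_interval(k, config$indel_size)
              is_ins <- runif(k) < 0.5
              d[is_ins, end := start]  # insertion point
              d[, vtype := ifelse(is_ins, "INS", "SMALL_DEL")]
              d[, alt_seq := ifelse(is_ins,
                                    vapply(sz, function(s)
                                      paste(sample(c("A", "C", "G", "T"), s,
                                                   replace = TRUE),
                                            collapse = ""), character(1)),
                                    "")]
              d <- cbind(d, draw_zyg(k, zg))
              d[, arm_flag := FALSE]
            } else if (isTRUE(cat$snv)) {
              d <- draw_interval(k, c(1, 1))
              d[, vtype := "SNV"]
              if (is.null(reference)) {
                d[, alt_seq := sample(c("A", "C", "G", "T"), k,
                                      replace = TRUE)]
              } else {
                refb <- substring(reference[d$chrom], d$start + 1,
                                  d$start + 1)
                d[, alt_seq := vapply(refb, function(b)
                  sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1), USE.NAMES = FALSE)]
              }
              d <- cbind(d, draw_zyg(k, zg))
              d[, arm_flag := FALSE]
            } else {
              d <- draw_interval(k, cat$size)
              d[, vtype := cat$vtype]
              d <- cbind(d, draw_zyg(k, zg))
              d[, arm_flag := FALSE]
            }
            if (!"alt_seq" %in% names(d)) d[, alt_seq := ""]
            d[, copies := ifelse(vtype == "CNV_AMP",
                                 if (length(config$amp_copies) == 1L)
                                   config$amp_copies
                                 else sample(config$amp_copies, k,
                                             replace = TRUE),
                                 NA_integer_)]
            d[, origin := cat$origin]
            d[]
          }
        })
        cnv_cat <- isTRUE(cat$arm) ||
          (!is.null(cat$vtype) && cat$vtype %in% c("CNV_DEL", "CNV_AMP"))
        res <- place_nonoverlapping(n_z, draw, occ,
                                    paste0(cat$name, " (", zg, ")"),
                                    config$max_retries,
                                    occupy_both = cnv_cat)
        occ <- res$occ
        out[[paste0(cat$name, "_", zg)]] <- res$placed
      }
    }

    specs <- rbindlist(out, use.names = TRUE, fill = TRUE)
    if (nrow(specs) == 0L) {
      return(list(germline = empty_catalog(), somatic = empty_catalog()))
    }
    setorder(specs, chrom, start, end)
    specs[, id := sprintf("v%05d", seq_len(.N))]
    specs[, clone_ids := ""]
    setcolorder(specs, c("id", "chrom", "start", "end", "vtype", "alt_seq",
                         "copies", "zygosity", "hap0", "hap1", "origin",
                         "clone_ids", "arm_flag"))
    list(germline = specs[origin == "germline"],
         somatic = specs[origin == "somatic"])
  })
}

#' Write / read a variant catalog as TSV
#'
#' @param specs a variant table as produced by [sample_variant_catalog()].
#' @param path file path.
#' @return `read_catalog` returns the variant `data.table`.
#' @export
write_catalog <- function(specs, path) {
  fwrite(as.data.table(specs), path, sep = "\t")
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("id", "chrom", "vtype",
                                              "alt_seq", "zygosity", "origin",
                                              "clone_ids")))
  dt[is.na(alt_seq), alt_seq := ""]
  dt[is.na(clone_ids), clone_ids := ""]
  dt[]
}
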