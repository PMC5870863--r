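#' Synthetic capture targets and gene models for a toy genome
#'
#' `make_targets` tiles each chromosome with evenly spaced, jittered
#' targets; `make_genes` groups consecutive targets into named genes so
#' that copy-number events spanning a few targets also cover whole genes.
#'
#' @param chrom_models chromosome models.
#' @param n_per_chrom targets per chromosome.
#' @param width target width in bp.
#' @param jitter maximal uniform jitter of target positions in bp.
#' @param seed integer seed.
#' @return BED-like `data.table` (with `name` for genes).
#' @export
make_targets <- function(chrom_models, n_per_chrom = 50L, width = 200L,
                         jitter = 500L, seed = 1L) {
  cm <- as.data.table(chrom_models)
  with_seed(seed, {
    rbindlist(lapply(seq_len(nrow(cm)), function(i) {
      L <- cm$length[i]
      centers <- seq(L / (2 * n_per_chrom), L, length.out = n_per_chrom) +
        round(runif(n_per_chrom, -jitter, jitter))
      start <- pmax(0, pmin(L - width, round(centers - width / 2)))
      data.table(chrom = cm$name[i], start = start, end = start + width)
    }))
  })
}

#' @rdname make_targets
#' @param targets target table from `make_targets`.
#' @param targets_per_gene consecutive targets grouped into one gene.
#' @param pad bp added on each side of the grouped targets.
#' @export
make_genes <- function(targets, targets_per_gene = 3L, pad = 200L) {
  tg <- as.data.table(targets)
  setorder(tg, chrom, start)
  tg[, gi := ceiling(seq_len(.N) / targets_per_gene), by = chrom]
  genes <- tg[, .(start = max(0, min(start) - pad), end = max(end) + pad),
              by = .(chrom, gi)]
  genes[, name := sprintf("gene_%s_%03d", sub("^chr", "", chrom), gi)]
  genes[, gi := NULL]
  genes[]
}

#' Cohort configuration
#'
#' Bundles everything [run_cohort()] needs. Defaults reproduce the full
#' study design at toy-genome scale: 5 replicates, ten admixture levels
#' from 0 to 0.9, per replicate 16 arm-length events plus 50 focal
#' deletions and 50 focal amplifications distributed over 5 clones mixed at
#' proportions (0.27, 0.29, 0.36, 0.06, 0.02), giving 50 tumor-control
#' sample pairs carrying 5800 somatic copy-number records in total.
#' Small-variant counts and event sizes are scaled to the toy genome.
#'
#' @param n_replicates replicates of the whole construction.
#' @param admixture_levels admixture series (strictly increasing).
#' @param chrom_models toy genome layout.
#' @param catalog a [catalog_config()]; default scales germline small
#'   variants and event sizes to the toy genome while keeping the somatic
#'   design counts.
#' @param clone_proportions subclone mixing proportions.
#' @param truncal_fraction probability a somatic event is shared by all
#'   clones (default 0: private events).
#' @param total_read_pairs read pairs per final sample; used directly when
#'   `depth` is `NULL`.
#' @param depth optional requested mean on-target depth; overrides
#'   `total_read_pairs` via a pilot draw.
#' @param fragment,error fragment and error models.
#' @param targets,gene_model target/gene tables; `NULL` generates synthetic
#'   ones with [make_targets()] / [make_genes()].
#' @param probe_pad,gc_center,gc_width,gc_floor capture-model parameters.
#' @param write_fastq write FASTQ pairs per sample (disable to keep only
#'   truth tables and manifests, e.g. for design-count checks).
#' @param seed master seed; all per-stage seeds derive from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_replicates = 5L,
                          admixture_levels = seq(0, 0.9, by = 0.1),
                          chrom_models = default_chrom_models(),
                          catalog = NULL,
                          clone_proportions = c(0.27, 0.29, 0.36, 0.06, 0.02),
                          truncal_fraction = 0,
                          total_read_pairs = 3000L,
                          depth = NULL,
                          fragment = fragment_model(),
                          error = error_model(),
                          targets = NULL,
                          gene_model = NULL,
                          probe_pad = 100L, gc_center = 0.45,
                          gc_width = 0.15, gc_floor = 0.1,
                          write_fastq = TRUE,
                          seed = 1L) {
  if (is.unsorted(admixture_levels, strictly = TRUE)) {
    stop_config("admixture levels must be strictly increasing")
  }
  if (is.null(catalog)) {
    catalog <- catalog_config(germline_snv = 1000L, germline_indel = 100L,
                              germline_cnv_del = 94L, germline_cnv_dup = 120L,
                              somatic_snv = 200L, somatic_indel = 20L,
                              germline_cnv_size = c(52, 2e4),
                              somatic_cnv_size = c(5e3, 4e4))
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 admixture_levels = admixture_levels,
                 chrom_models = as.data.table(chrom_models),
                 catalog = catalog,
                 clone_proportions = clone_proportions,
                 truncal_fraction = truncal_fraction,
                 total_read_pairs = as.integer(total_read_pairs),
                 depth = depth, fragment = fragment, error = error,
                 targets = targets, gene_model = gene_model,
                 probe_pad = probe_pad, gc_center = gc_center,
                 gc_width = gc_width, gc_floor = gc_floor,
                 write_fastq = write_fastq, seed = seed),
            class = "cohort_config")
}

# Draw retained fragments until `need` are available (top-up loop with a
# pilot-estimated retention rate).
retained_pool <- function(genome, fm, cm, need, seed, retention_hint = NULL) {
  ret <- retention_hint %||% 0.05
  pool <- NULL
  for (round in 1:8) {
    have <- if (is.null(pool)) 0L else nrow(pool)
    if (have >= need) break
    n_draw <- ceiling((need - have) / max(ret, 1e-4) * 1.25) + 500L
    fr <- simulate_fragments(genome, fm, n_draw,
                             seed = child_seed(seed, 100L + round))
    kept <- capture_filter(fr, cm, genome,
                           seed = child_seed(seed, 200L + round))
    ret <- max(nrow(kept) / n_draw, 1e-4)
    pool <- rbind(pool, kept)
  }
  if (is.null(pool) || nrow(pool) < need) {
    stop_data("could not accumulate ", need, " retained fragments")
  }
  pool
}

#' Generate a full simulated tumor-control cohort
#'
#' For each replicate: samples a fresh variant catalog, builds the control
#' genome and the clone genomes, simulates capture-filtered read pools per
#' clone and for the control, then for every admixture level mixes the
#' clones at the design proportions, dilutes with control reads, draws an
#' independent matched control of equal depth, and writes per-sample FASTQ
#' pairs, the replicate truth table, and an expected-allele-fraction table.
#' Deterministic for a given configuration seed.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created).
#' @return The cohort manifest `data.table` (one row per tumor-control
#'   pair), invisibly also written to `manifest.tsv`. Attributes `targets`
#'   and `gene_model` carry the interval tables used.
#' @export
run_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  models <- config$chrom_models
  reference <- generate_toy_reference(models, seed = child_seed(config$seed, 1L))
  targets <- config$targets %||%
    make_targets(models, seed = child_seed(config$seed, 2L))
  gene_model <- config$gene_model %||% make_genes(targets)
  write_bed(targets, file.path(outdir, "targets.bed"))
  write_bed(gene_model, file.path(outdir, "genes.bed"))
  write_fasta(unclass(reference), file.path(outdir, "reference.fa"))
  cm <- capture_model(targets, probe_pad = config$probe_pad,
                      gc_center = config$gc_center,
                      gc_width = config$gc_width, gc_floor = config$gc_floor)
  n_clones <- length(config$clone_proportions)
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    rep_seed <- child_seed(config$seed, 1000L + r)
    cat <- sample_variant_catalog(config$catalog, models,
                                  reference = unclass(reference),
                                  seed = rep_seed)
    control <- implant_variants(reference, cat$germline, "control")
    bc <- build_clone_genomes(control, reference, cat$somatic,
                              n_clones = n_clones,
                              truncal_fraction = config$truncal_fraction,
                              seed = child_seed(rep_seed, 2L))
    truth_path <- file.path(outdir, sprintf("rep%d_truth.tsv", r))
    export_truth(bc$truth, truth_path)
    # retained pairs are essentially all on target, so pairs needed for a
    # requested read depth D are D * target_bases / (2 * read_length); the
    # pre-capture fragment count behind them is handled by retained_pool's
    # pilot-estimated retention rate
    n_total <- if (!is.null(config$depth)) {
      ceiling(config$depth * interval_width(cm$targets) /
                (2 * config$fragment$read_length))
    } else config$total_read_pairs
    design <- sample_design(config$clone_proportions,
                            config$admixture_levels, n_total,
                            seed = rep_seed)
    af_tab <- truth_af_table(bc$truth, design)
    af_path <- file.path(outdir, sprintf("rep%d_af.tsv", r))
    fwrite(af_tab, af_path, sep = "\t")
    genomes <- c(setNames(bc$clones,
                          vapply(bc$clones, `[[`, character(1), "id")),
                 list(control = control))
    pools <- NULL
    if (config$write_fastq) {
      # pilot on the control genome: retention is near-identical across
      # clones, and a good hint avoids large over-draws in retained_pool
      hint <- fragments_for_depth(1, control, config$fragment, cm,
                                  pilot_n = 3000L,
                                  seed = child_seed(rep_seed, 9L))$retention
      pools <- lapply(seq_len(n_clones), function(ci) {
        p <- retained_pool(bc$clones[[ci]], config$fragment, cm, n_total,
                           seed = child_seed(rep_seed, 10L + ci),
                           retention_hint = hint)
        p[, source := sprintf("clone%d", ci)]
        p
      })
      control_pool <- retained_pool(control, config$fragment, cm,
                                    2L * n_total,
                                    seed = child_seed(rep_seed, 30L))
      control_pool[, source := "control"]
    }
    for (li in seq_along(config$admixture_levels)) {
      a <- config$admixture_levels[li]
      sample_id <- sprintf("rep%d_a%02.0f", r, a * 100)
      lvl_seed <- child_seed(rep_seed, 100L + li)
      row <- data.table(sample = sample_id, replicate = r, a = a,
                        n_total = n_total, seed = lvl_seed,
                        truth = truth_path, af_table = af_path,
                        tumor_r1 = NA_character_, tumor_r2 = NA_character_,
                        normal_r1 = NA_character_, normal_r2 = NA_character_)
      if (config$write_fastq) {
        tumor_pool <- mix_clones(pools, config$clone_proportions, n_total,
                                 seed = lvl_seed)
        ms <- admix(tumor_pool, control_pool, a, n_total,
                    seed = child_seed(lvl_seed, 1L))
        paths <- file.path(outdir, paste0(sample_id, c("_tumor_R1.fastq.gz",
                                                       "_tumor_R2.fastq.gz",
                                                       "_normal_R1.fastq.gz",
                                                       "_normal_R2.fastq.gz")))
        emit_reads(ms$tumor, genomes, config$error, paste0(sample_id, "_t"),
                   paths[1], paths[2],
                   read_length = config$fragment$read_length,
                   seed = child_seed(lvl_seed, 2L))
        emit_reads(ms$control, genomes, config$error, paste0(sample_id, "_n"),
                   paths[3], paths[4],
                   read_length = config$fragment$read_length,
                   seed = child_seed(lvl_seed, 3L))
        row[, `:=`(tumor_r1 = paths[1], tumor_r2 = paths[2],
                   normal_r1 = paths[3], normal_r2 = paths[4])]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  manifest <- rbindlist(rows)
  fwrite(manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
  setattr(manifest, "targets", targets)
  setattr(manifest, "gene_model", gene_model)
  manifest[]
}

#' Run the naive caller over a cohort
#'
#' @param manifest cohort manifest from [run_cohort()].
#' @param targets target table (defaults to the manifest attribute).
#' @param log2_threshold,min_consecutive caller parameters.
#' @return Named list of call-set `data.table`s, one per sample.
#' @export
call_cohort <- function(manifest, targets = NULL, log2_threshold = 0.3,
                        min_consecutive = 2L) {
  targets <- targets %||% attr(manifest, "targets", exact = TRUE)
  calls <- lapply(seq_len(nrow(manifest)), function(i) {
    tum <- read_pool_fastq(manifest$tumor_r1[i])
    nor <- read_pool_fastq(manifest$normal_r1[i])
    naive_depth_caller(tum, nor, targets, log2_threshold = log2_threshold,
                       min_consecutive = min_consecutive)
  })
  names(calls) <- manifest$sample
  calls
}

#' Evaluate call sets across a cohort
#'
#' Scores each sample's calls against its replicate's somatic gold standard
#' under all three approaches, plus per-type (amp/del) nucleotide metrics.
#'
#' @param manifest cohort manifest.
#' @param calls named list of call sets (as from [call_cohort()]).
#' @param targets,gene_model interval tables (default: manifest
#'   attributes).
#' @return Long `data.table`: sample, replicate, a, approach, type,
#'   TP/PP/GP/TD, precision, sensitivity.
#' @export
evaluate_cohort <- function(manifest, calls, targets = NULL,
                            gene_model = NULL) {
  targets <- targets %||% attr(manifest, "targets", exact = TRUE)
  gene_model <- gene_model %||% attr(manifest, "gene_model", exact = TRUE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    gold <- gold_segments(read_truth(manifest$truth[i]))
    pred <- calls[[manifest$sample[i]]]
    ev <- evaluate_calls(gold, pred, targets, gene_model)
    ev[, type := "all"]
    for (t in c("amp", "del")) {
      nm <- {
        gclip <- restrict_to_targets(gold[type == t], targets, "clip")
        pclip <- restrict_to_targets(pred[type == t], targets, "clip")
        nucleotide_metrics(gclip, pclip)
      }
      nm[, type := t]
      ev <- rbind(ev, nm, fill = TRUE)
    }
    ev[, `:=`(sample = manifest$sample[i], replicate = manifest$replicate[i],
              a = manifest$a[i])]
    ev
  })
  out <- rbindlist(rows)
  setcolorder(out, c("sample", "replicate", "a", "approach", "type"))
  out[]
}

#' Aggregate cohort evaluations
#'
#' Means of precision and sensitivity per admixture level and approach
#' (figure-1 style layout) and per event type (figure-3 style), excluding
#' `NA` values and reporting how many samples contributed.
#'
#' @param evals evaluation table from [evaluate_cohort()].
#' @return List with `by_level` and `by_type` `data.table`s.
#' @export
summarize_cohort <- function(evals) {
  evals <- as.data.table(evals)
  by_level <- evals[type == "all",
                    .(precision = mean(precision, na.rm = TRUE),
                      n_precision = sum(!is.na(precision)),
                      sensitivity = mean(sensitivity, na.rm = TRUE),
                      n_sensitivity = sum(!is.na(sensitivity))),
                    keyby = .(a, approach)]
  by_type <- evals[type != "all",
                   .(precision = mean(precision, na.rm = TRUE),
                     n_precision = sum(!is.na(precision)),
                     sensitivity = mean(sensitivity, na.rm = TRUE),
                     n_sensitivity = sum(!is.na(sensitivity))),
                   keyby = .(type, a)]
  list(by_level = by_level, by_type = by_type)
}

#' Generate the self-contained test fixture tree
#'
#' Builds a small five-chromosome genome (2.5 Mb), ~220 capture targets,
#' ~75 genes, and a 2-replicate x 3-level mini-cohort with truncal,
#' homozygous-biased deletions and +1-copy amplifications -- a
#' configuration in which the naive depth-ratio caller has measurable
#' power, so that directional claims (sensitivity falls with admixture;
#' deletions are easier than amplifications) can be tested end to end.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param total_read_pairs read pairs per sample.
#' @return The mini-cohort manifest (with `targets`/`gene_model`
#'   attributes).
#' @export
generate_fixtures <- function(dir, seed = 1L, total_read_pairs = 20000L) {
  models <- rbindlist(lapply(1:5, function(i) {
    chrom_model(sprintf("chr%d", i), length = 5e5, gc = 0.45)
  }))
  targets <- make_targets(models, n_per_chrom = 44L, width = 200L,
                          jitter = 300L, seed = child_seed(seed, 7L))
  genes <- make_genes(targets)
  catalog <- catalog_config(
    germline_snv = 500L, germline_indel = 50L,
    germline_cnv_del = 20L, germline_cnv_dup = 20L,
    somatic_snv = 100L, somatic_indel = 10L,
    somatic_arm = 4L, somatic_del = 12L, somatic_amp = 12L,
    het_prob = 0.9, het_prob_somatic_del = 0.2,
    germline_cnv_size = c(52, 5e3),
    somatic_cnv_size = c(1.5e4, 4.5e4))
  config <- cohort_config(
    n_replicates = 2L, admixture_levels = c(0, 0.5, 0.9),
    chrom_models = models, catalog = catalog,
    truncal_fraction = 1, total_read_pairs = total_read_pairs,
    targets = targets, gene_model = genes, seed = seed)
  run_cohort(config, dir)
}
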