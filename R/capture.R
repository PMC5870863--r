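#' Models for the capture-sequencing simulator
#'
#' `fragment_model` describes the sheared library: paired-end read length
#' and a truncated-normal insert-size distribution (defaults: 101 bp reads,
#' 300 bp mean insert as in whole-exome libraries; use 200 bp for panel
#' libraries). `capture_model` describes in-silico probe capture: padded
#' target intervals plus a Gaussian GC retention weight
#' `max(gc_floor, exp(-((gc - gc_center)/gc_width)^2 / 2))` emulating
#' hybridization GC bias. `error_model` is a flat per-base substitution
#' model with constant base quality.
#'
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size mean / sd in bp; inserts are
#'   truncated below at `read_length`.
#' @param targets BED-like `data.table` (chrom, start, end), 0-based
#'   half-open; merged and sorted internally.
#' @param probe_pad bp of padding around each target reachable by capture.
#' @param gc_center,gc_width,gc_floor GC-bias curve parameters.
#' @param min_overlap minimum overlap (bp) between a fragment's reference
#'   projection and the padded target space for capture eligibility.
#' @param sub_rate per-base substitution probability.
#' @param quality constant Phred quality for FASTQ output.
#' @return Parameter lists of class `fragment_model`, `capture_model`,
#'   `error_model`.
#' @export
fragment_model <- function(read_length = 101L, insert_mean = 300,
                           insert_sd = 50) {
  if (insert_mean < read_length) {
    stop_config("insert_mean must be >= read_length")
  }
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd),
            class = "fragment_model")
}

#' @rdname fragment_model
#' @export
capture_model <- function(targets, probe_pad = 100L, gc_center = 0.45,
                          gc_width = 0.15, gc_floor = 0.1, min_overlap = 1L) {
  if (gc_floor <= 0 || gc_floor > 1) stop_config("gc_floor must be in (0, 1]")
  structure(list(targets = merge_intervals(targets),
                 probe_pad = as.numeric(probe_pad),
                 gc_center = gc_center, gc_width = gc_width,
                 gc_floor = gc_floor, min_overlap = as.numeric(min_overlap)),
            class = "capture_model")
}

#' @rdname fragment_model
#' @export
error_model <- function(sub_rate = 0.001, quality = 30L) {
  if (sub_rate < 0 || sub_rate >= 1) stop_config("sub_rate must be in [0, 1)")
  structure(list(sub_rate = sub_rate, quality = as.integer(quality)),
            class = "error_model")
}

gc_weight <- function(cm, gc) {
  pmax(cm$gc_floor, exp(-((gc - cm$gc_center) / cm$gc_width)^2 / 2))
}

#' Simulate sheared fragments from a diploid genome
#'
#' Fragment start positions are uniform over the two haplotypes (weighted
#' by haplotype length, so duplicated material yields proportionally more
#' fragments); lengths are drawn from the truncated normal of the fragment
#' model. Coordinates are on the haplotype axis.
#'
#' @param genome a `haplotype_genome`.
#' @param fm a [fragment_model()].
#' @param n number of fragments.
#' @param seed integer seed.
#' @param max_rounds resampling cap for out-of-bounds lengths.
#' @return `data.table` with chrom, hap, start, end (0-based half-open,
#'   haplotype coordinates).
#' @export
simulate_fragments <- function(genome, fm, n, seed = 1L, max_rounds = 100L) {
  hl <- haplotype_lengths(genome)
  if (n == 0L) {
    return(data.table(chrom = character(), hap = integer(),
                      start = numeric(), end = numeric()))
  }
  with_seed(seed, {
    gi <- sample.int(nrow(hl), n, replace = TRUE, prob = hl$length)
    len <- round(rnorm(n, fm$insert_mean, fm$insert_sd))
    bad <- which(len < fm$read_length | len > hl$length[gi])
    rounds <- 0L
    while (length(bad) > 0L) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop_data("could not draw in-bounds fragment lengths after ",
                  max_rounds, " rounds (fragments longer than chromosome?)")
      }
      len[bad] <- round(rnorm(length(bad), fm$insert_mean, fm$insert_sd))
      bad <- bad[len[bad] < fm$read_length | len[bad] > hl$length[gi[bad]]]
    }
    start <- floor(runif(n) * (hl$length[gi] - len + 1))
    data.table(chrom = hl$chrom[gi], hap = hl$hap[gi],
               start = start, end = start + len)
  })
}

# Project haplotype-coordinate fragments through the liftover map onto
# reference coordinates. A fragment crossing a tandem-duplication junction
# projects to several (possibly mutually overlapping) reference blocks; the
# multiset is kept, since the fragment genuinely carries those bases more
# than once. Returns the fragments with an `rproj` column
# ("start-end;start-end" per fragment, "*" when no reference image).
project_fragments <- function(fragments, genome) {
  fragments <- as.data.table(fragments)
  if (nrow(fragments) == 0L) {
    fragments[, rproj := character(0)]
    return(fragments)
  }
  fragments[, `:=`(.frag_id = .I, rproj = "*")]
  lo <- genome$liftover[kind != "I"]
  proj <- list()
  for (grp in split(seq_len(nrow(fragments)),
                    paste(fragments$chrom, fragments$hap))) {
    ch <- fragments$chrom[grp[1]]; h <- fragments$hap[grp[1]]
    blocks <- lo[chrom == ch & hap == h]
    if (nrow(blocks) == 0L) next
    irf <- IRanges::IRanges(start = fragments$start[grp] + 1,
                            end = fragments$end[grp])
    irb <- IRanges::IRanges(start = blocks$hstart + 1, end = blocks$hend)
    hits <- IRanges::findOverlaps(irf, irb)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov_start <- pmax(fragments$start[grp][qi], blocks$hstart[si])
    ov_end <- pmin(fragments$end[grp][qi], blocks$hend[si])
    rs <- blocks$rstart[si] + (ov_start - blocks$hstart[si])
    re <- rs + (ov_end - ov_start)
    proj[[length(proj) + 1L]] <- data.table(
      .frag_id = grp[qi], rstart = rs, rend = re)
  }
  if (length(proj)) {
    pr <- rbindlist(proj)
    setorder(pr, .frag_id, rstart, rend)
    str <- pr[, .(rproj = paste(sprintf("%.0f-%.0f", rstart, rend),
                                collapse = ";")), by = .frag_id]
    fragments[str$.frag_id, rproj := str$rproj]
  }
  fragments[, .frag_id := NULL]
  fragments[]
}

# Expand the rproj column back into one row per reference block.
rproj_blocks <- function(pool) {
  pool <- as.data.table(pool)
  if (nrow(pool) == 0L) {
    return(data.table(frag = integer(), chrom = character(),
                      start = numeric(), end = numeric()))
  }
  keep <- which(pool$rproj != "*" & !is.na(pool$rproj))
  if (length(keep) == 0L) {
    return(data.table(frag = integer(), chrom = character(),
                      start = numeric(), end = numeric()))
  }
  parts <- strsplit(pool$rproj[keep], ";", fixed = TRUE)
  nb <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  se <- matrix(as.numeric(unlist(strsplit(flat, "-", fixed = TRUE),
                                 use.names = FALSE)), ncol = 2, byrow = TRUE)
  data.table(frag = rep(keep, nb),
             chrom = rep(pool$chrom[keep], nb),
             start = se[, 1], end = se[, 2])
}

#' In-silico probe capture
#'
#' A fragment is capture-eligible iff its reference projection overlaps the
#' padded target space by at least `min_overlap` bp; eligible fragments are
#' then retained with probability given by the GC-bias curve evaluated at
#' the fragment's GC content.
#'
#' @param fragments fragment table from [simulate_fragments()].
#' @param cm a [capture_model()].
#' @param genome the `haplotype_genome` the fragments were drawn from.
#' @param seed integer seed for the GC-retention draw.
#' @return The retained fragments, with `rproj` (reference projection) and
#'   `gc` columns added.
#' @export
capture_filter <- function(fragments, cm, genome, seed = 1L) {
  fragments <- project_fragments(fragments, genome)
  if (nrow(fragments) == 0L) {
    fragments[, gc := numeric(0)]
    return(fragments)
  }
  padded <- merge_intervals(copy(cm$targets)[, `:=`(
    start = pmax(0, start - cm$probe_pad), end = end + cm$probe_pad)])
  blocks <- rproj_blocks(fragments)
  ov <- numeric(nrow(fragments))
  if (nrow(blocks)) {
    bov <- overlap_bases_per_query(blocks[, .(chrom, start, end)], padded)
    agg <- data.table(frag = blocks$frag, w = bov)[, .(w = sum(w)), by = frag]
    ov[agg$frag] <- agg$w
  }
  eligible <- which(ov >= cm$min_overlap)
  if (length(eligible) == 0L) {
    out <- fragments[0L]
    out[, gc := numeric(0)]
    return(out)
  }
  el <- fragments[eligible]
  el[, gc := NA_real_]
  for (grp in split(seq_len(nrow(el)), paste(el$chrom, el$hap))) {
    ch <- el$chrom[grp[1]]; h <- el$hap[grp[1]]
    dna <- Biostrings::DNAString(genome$seq[[ch]][h + 1L])
    v <- Biostrings::Views(dna, start = el$start[grp] + 1, end = el$end[grp])
    gcf <- Biostrings::letterFrequency(v, "GC")[, 1] / (el$end[grp] - el$start[grp])
    el[grp, gc := gcf]
  }
  with_seed(seed, {
    keep <- runif(nrow(el)) < gc_weight(cm, el$gc)
    el[keep]
  })
}

#' Write a fragment pool as paired FASTQ
#'
#' Read 1 is the fragment's 5' prefix, read 2 the reverse complement of its
#' 3' suffix. Read names carry truth tags
#' `sample|source|chrom|hap|hapstart-hapend|refprojection|index` (source is
#' the originating clone or control pool), which downstream alignment-free
#' depth counting parses back. Substitution errors are
#' injected at the error model's rate; quality strings are constant.
#'
#' @param fragments fragment pool (needs `rproj`; see [capture_filter()]).
#' @param genome the source `haplotype_genome`, or a named list of genomes
#'   keyed by a `source` column for mixed pools.
#' @param em an [error_model()].
#' @param sample_name sample label used in read names.
#' @param r1,r2 output FASTQ paths (gzipped when ending in `.gz`).
#' @param read_length read length in bp (match the fragment model used).
#' @param seed integer seed for error injection.
#' @return Invisibly, a list with `n_pairs` written and `n_skipped`
#'   (fragments shorter than the read length).
#' @export
emit_reads <- function(fragments, genome, em, sample_name, r1, r2,
                       read_length = 101L, seed = 1L) {
  fragments <- as.data.table(copy(fragments))
  genomes <- if (inherits(genome, "haplotype_genome")) {
    if (!"source" %in% names(fragments)) fragments[, source := genome$id]
    setNames(list(genome), genome$id)
  } else genome
  if (!"source" %in% names(fragments) && length(genomes) == 1L) {
    fragments[, source := names(genomes)]
  }
  fm_len <- fragments$end - fragments$start
  rl <- as.integer(read_length)
  skipped <- sum(fm_len < rl)
  fragments <- fragments[fm_len >= rl]
  n <- nrow(fragments)
  seq1 <- character(n); seq2 <- character(n)
  if (n > 0) {
    for (grp in split(seq_len(n),
                      paste(fragments$source, fragments$chrom, fragments$hap))) {
      g <- genomes[[fragments$source[grp[1]]]]
      if (is.null(g)) stop_data("no genome for source '",
                                fragments$source[grp[1]], "'")
      s <- g$seq[[fragments$chrom[grp[1]]]][fragments$hap[grp[1]] + 1L]
      seq1[grp] <- substring(s, fragments$start[grp] + 1,
                             fragments$start[grp] + rl)
      seq2[grp] <- reverse_complement(
        substring(s, fragments$end[grp] - rl + 1, fragments$end[grp]))
    }
  }
  with_seed(seed, {
    if (em$sub_rate > 0 && n > 0) {
      all_seq <- c(seq1, seq2)
      total <- 2L * n * rl
      m <- rbinom(1L, total, em$sub_rate)
      if (m > 0) {
        pos <- sample.int(total, m)
        ri <- (pos - 1L) %/% rl + 1L
        off <- (pos - 1L) %% rl + 1L
        for (j in seq_len(m)) {
          cur <- substring(all_seq[ri[j]], off[j], off[j])
          substr(all_seq[ri[j]], off[j], off[j]) <-
            sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
      seq1 <- all_seq[seq_len(n)]
      seq2 <- all_seq[n + seq_len(n)]
    }
    NULL
  })
  nm <- if (n > 0) {
    sprintf("%s|%s|%s|%d|%.0f-%.0f|%s|%d", sample_name, fragments$source,
            fragments$chrom, fragments$hap, fragments$start, fragments$end,
            fragments$rproj %||% "*", seq_len(n))
  } else character(0)
  qual <- strrep(rawToChar(as.raw(em$quality + 33L)), rl)
  write_one <- function(path, seqs, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    if (n > 0) {
      lines <- character(4L * n)
      lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", nm, "/", mate)
      lines[seq(2L, by = 4L, length.out = n)] <- seqs
      lines[seq(3L, by = 4L, length.out = n)] <- "+"
      lines[seq(4L, by = 4L, length.out = n)] <- qual
      writeLines(lines, con)
    } else writeLines(character(0), con)
  }
  write_one(r1, seq1, 1L)
  write_one(r2, seq2, 2L)
  invisible(list(n_pairs = n, n_skipped = skipped))
}

#' Parse a truth-tagged FASTQ back into a fragment pool
#'
#' Reads the R1 file of a pair written by [emit_reads()] and reconstructs
#' the fragment table (source, chrom, hap, haplotype coordinates, reference
#' projection) from the read names. Sequences are not retained; this is the
#' alignment-free path into depth counting.
#'
#' @param r1 path to the R1 FASTQ written by [emit_reads()].
#' @return A fragment pool `data.table`.
#' @export
read_pool_fastq <- function(r1) {
  con <- if (grepl("\\.gz$", r1)) gzfile(r1, "rt") else file(r1, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(data.table(sample = character(), source = character(),
                      chrom = character(), hap = integer(),
                      start = numeric(), end = numeric(),
                      rproj = character()))
  }
  nm <- sub("^@", "", sub("/1$", "", lines[seq(1L, length(lines), by = 4L)]))
  parts <- tstrsplit(nm, "|", fixed = TRUE)
  se <- tstrsplit(parts[[5]], "-", fixed = TRUE)
  data.table(sample = parts[[1]], source = parts[[2]], chrom = parts[[3]],
             hap = as.integer(parts[[4]]),
             start = as.numeric(se[[1]]), end = as.numeric(se[[2]]),
             rproj = parts[[6]])
}

#' Mean on-target depth of a fragment pool
#'
#' Depth is the total number of on-target fragment bases (reference
#' projections intersected with the merged target space) divided by the
#' total target length.
#'
#' @param pool fragment pool with `rproj` (from [capture_filter()] or
#'   [read_pool_fastq()]).
#' @param targets BED-like target table.
#' @return Mean depth (numeric scalar).
#' @export
estimate_coverage <- function(pool, targets) {
  targets <- merge_intervals(targets)
  tw <- interval_width(targets)
  if (tw == 0) stop_data("empty target set")
  blocks <- rproj_blocks(pool)
  if (nrow(blocks) == 0L) return(0)
  sum(overlap_bases_per_query(blocks[, .(chrom, start, end)], targets)) / tw
}

#' Fragment count needed for a requested mean on-target depth
#'
#' Runs a pilot draw through shearing and capture and scales: the number of
#' fragments to simulate is `depth * target_bases / (mean on-target bases
#' contributed per drawn fragment)`.
#'
#' @param depth requested mean on-target depth.
#' @param genome a `haplotype_genome`.
#' @param fm,cm fragment and capture models.
#' @param pilot_n pilot draw size.
#' @param seed integer seed.
#' @return List with `n_fragments` (to simulate) and `retention` (pilot
#'   capture retention rate).
#' @export
fragments_for_depth <- function(depth, genome, fm, cm, pilot_n = 10000L,
                                seed = 1L) {
  pilot <- simulate_fragments(genome, fm, pilot_n, seed = seed)
  kept <- capture_filter(pilot, cm, genome, seed = child_seed(seed, 1L))
  tw <- interval_width(cm$targets)
  on_target <- if (nrow(kept)) {
    sum(overlap_bases_per_query(rproj_blocks(kept)[, .(chrom, start, end)],
                                cm$targets))
  } else 0
  if (on_target == 0) stop_data("pilot draw yielded no on-target bases")
  per_frag <- on_target / pilot_n
  list(n_fragments = ceiling(depth * tw / per_frag),
       retention = nrow(kept) / pilot_n)
}
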