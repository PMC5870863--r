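#' Implant variants into a reference to build a diploid genome
#'
#' Applies a non-overlapping variant set to the reference, producing two
#' haplotype sequences per chromosome plus a liftover block map back to
#' reference coordinates. Amplifications are realized as tandem
#' duplications: the extra copies are inserted immediately after the source
#' interval on the carrying haplotype(s), and their liftover blocks point
#' back at the source reference interval. Deletions remove the interval;
#' deleted reference bases have no haplotype image.
#'
#' @param reference named character vector of chromosome sequences (e.g. a
#'   [generate_toy_reference()] object).
#' @param specs variant table (rows as produced by
#'   [sample_variant_catalog()]); must be non-overlapping per haplotype.
#' @param genome_id label stored on the result.
#' @return An object of class `haplotype_genome`: list with `seq` (list of
#'   `chrom` -> character vector of the two haplotype sequences), `liftover`
#'   (`data.table` with chrom, hap, hstart, hend, rstart, rend, kind) and
#'   `specs`. Liftover blocks of kind `"M"` are one-to-one, `"D"` marks
#'   extra tandem copies, `"I"` marks inserted sequence (zero-width
#'   reference image).
#' @export
implant_variants <- function(reference, specs, genome_id = "genome") {
  ref <- unclass(reference)
  attr(ref, "models") <- NULL
  if (!is.character(ref) || is.null(names(ref))) {
    stop_config("reference must be a named character vector of sequences")
  }
  specs <- as.data.table(specs)
  if (nrow(specs) > 0) {
    bad <- specs[start > end | start < 0 |
                   end > nchar(ref[chrom]) | !(chrom %in% names(ref))]
    if (nrow(bad) > 0) {
      stop_data("variant outside chromosome bounds: ", bad$chrom[1], ":",
                bad$start[1], "-", bad$end[1])
    }
    if (any(specs$vtype != "INS" & specs$start >= specs$end)) {
      stop_data("zero-width interval on a non-insertion variant")
    }
  }
  seqs <- list()
  lift <- vector("list", 2L * length(ref))
  li <- 0L
  for (ch in names(ref)) {
    L <- nchar(ref[[ch]])
    for (h in 0:1) {
      hcol <- if (h == 0) "hap0" else "hap1"
      sp <- if (nrow(specs)) specs[chrom == ch & get(hcol) == TRUE] else specs
      if (nrow(sp)) setorder(sp, start, end)
      pieces <- character(0)
      blocks <- list()
      cur_ref <- 0    # next unconsumed reference base
      cur_hap <- 0    # current haplotype length
      emit <- function(seq_piece, rstart, rend, kind) {
        n <- nchar(seq_piece)
        if (n == 0 && kind != "I") return(invisible())
        pieces[[length(pieces) + 1L]] <<- seq_piece
        blocks[[length(blocks) + 1L]] <<-
          data.table(chrom = ch, hap = h, hstart = cur_hap,
                     hend = cur_hap + n, rstart = rstart, rend = rend,
                     kind = kind)
        cur_hap <<- cur_hap + n
      }
      if (nrow(sp)) {
        for (i in seq_len(nrow(sp))) {
          s <- sp$start[i]; e <- sp$end[i]; vt <- sp$vtype[i]
          if (s > cur_ref) {
            emit(substring(ref[[ch]], cur_ref + 1, s), cur_ref, s, "M")
          }
          cur_ref <- s
          if (vt == "SNV") {
            emit(sp$alt_seq[i], s, e, "M")
            cur_ref <- e
          } else if (vt == "INS") {
            if (nchar(sp$alt_seq[i]) > 0) emit(sp$alt_seq[i], s, s, "I")
          } else if (vt %in% c("SMALL_DEL", "CNV_DEL")) {
            cur_ref <- e  # interval dropped
          } else if (vt == "CNV_AMP") {
            seg <- substring(ref[[ch]], s + 1, e)
            emit(seg, s, e, "M")
            for (k in seq_len(sp$copies[i])) emit(seg, s, e, "D")
            cur_ref <- e
          } else {
            stop_data("unknown variant type: ", vt)
          }
        }
      }
      if (cur_ref < L) emit(substring(ref[[ch]], cur_ref + 1, L), cur_ref, L, "M")
      li <- li + 1L
      lift[[li]] <- rbindlist(blocks)
      seqs[[ch]][h + 1L] <- paste(pieces, collapse = "")
    }
  }
  structure(list(seq = seqs,
                 liftover = rbindlist(lift),
                 specs = specs,
                 reference_names = names(ref),
                 reference_lengths = nchar(ref),
                 id = genome_id),
            class = "haplotype_genome")
}

#' @export
print.haplotype_genome <- function(x, ...) {
  lens <- haplotype_lengths(x)
  cat(sprintf("haplotype_genome '%s': %d chromosome(s), hap lengths %.0f / %.0f bp, %d variant(s)\n",
              x$id, length(x$seq), sum(lens[hap == 0, length]),
              sum(lens[hap == 1, length]), nrow(x$specs)))
  invisible(x)
}

#' Per-haplotype sequence lengths
#' @param genome a `haplotype_genome`.
#' @return `data.table` with chrom, hap, length.
#' @export
haplotype_lengths <- function(genome) {
  rbindlist(lapply(names(genome$seq), function(ch) {
    data.table(chrom = ch, hap = 0:1, length = nchar(genome$seq[[ch]]))
  }))
}

#' Build tumor clone genomes on top of a control genome
#'
#' Each clone genome carries the full germline background plus the somatic
#' events assigned to that clone. Assignment is private by default: every
#' somatic event is given to one uniformly chosen clone; with probability
#' `truncal_fraction` an event is instead truncal (present in all clones).
#' Because all variants are placed without overlap on the reference, a clone
#' genome is constructed in a single pass from the reference with the
#' combined germline + clone-somatic spec set, which is identical to editing
#' the control genome.
#'
#' @param control a `haplotype_genome` built from the germline specs (its
#'   `specs` provide the germline background), or `NULL` to use
#'   `germline_specs`.
#' @param reference the reference sequences used to build `control`.
#' @param somatic_specs somatic variant table.
#' @param n_clones number of tumor clones (default 5).
#' @param truncal_fraction probability an event is shared by all clones.
#' @param seed integer seed for the clone assignment.
#' @return List with `clones` (list of `haplotype_genome`) and `truth` (a
#'   [truth_table()] of all variants with `clone_ids` filled in).
#' @export
build_clone_genomes <- function(control, reference, somatic_specs,
                                n_clones = 5L, truncal_fraction = 0,
                                seed = 1L) {
  if (n_clones < 1L) stop_config("n_clones must be >= 1")
  germline_specs <- if (is.null(control)) empty_catalog() else control$specs
  somatic_specs <- as.data.table(somatic_specs)
  somatic_specs <- with_seed(seed, {
    sp <- copy(somatic_specs)
    if (nrow(sp) > 0) {
      truncal <- runif(nrow(sp)) < truncal_fraction
      one <- sample.int(n_clones, nrow(sp), replace = TRUE)
      sp[, clone_ids := ifelse(truncal,
                               paste(seq_len(n_clones), collapse = ","),
                               as.character(one))]
    }
    sp
  })
  clones <- lapply(seq_len(n_clones), function(ci) {
    mine <- if (nrow(somatic_specs)) {
      somatic_specs[vapply(strsplit(clone_ids, ","),
                           function(z) as.character(ci) %in% z, logical(1))]
    } else somatic_specs
    implant_variants(reference, rbind(germline_specs, mine, fill = TRUE),
                     genome_id = sprintf("clone%d", ci))
  })
  truth <- truth_table(rbind(germline_specs, somatic_specs, fill = TRUE),
                       seed = seed)
  list(clones = clones, truth = truth)
}

#' Construct a truth table
#'
#' A truth table is the gold-standard record set: the implanted variants
#' with their reference-coordinate intervals (for tandem duplications, the
#' source interval), plus bookkeeping metadata.
#'
#' @param specs variant table.
#' @param seed,replicate metadata stored as attributes.
#' @return A `data.table` of class `truth_table`.
#' @export
truth_table <- function(specs, seed = NA_integer_, replicate = NA_integer_) {
  dt <- as.data.table(specs)
  setattr(dt, "seed", seed)
  setattr(dt, "replicate", replicate)
  setattr(dt, "class", c("truth_table", class(dt)))
  dt
}
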