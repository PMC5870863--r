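test_that("toy reference generation is deterministic with controlled GC", {
  m <- rbind(chrom_model("chrA", 1000, gc = 0.5),
             chrom_model("chrB", 2000, gc = 0.3))
  ref1 <- generate_toy_reference(m, seed = 7)
  ref2 <- generate_toy_reference(m, seed = 7)
  expect_identical(unclass(ref1), unclass(ref2))
  expect_identical(nchar(ref1[["chrA"]]), 1000L)
  gcA <- lengths(regmatches(ref1[["chrA"]], gregexpr("[GC]", ref1[["chrA"]]))) / 1000
  expect_gt(gcA, 0.45); expect_lt(gcA, 0.55)
  # boundary: gc 1 -> only G/C
  pure <- generate_toy_reference(chrom_model("chrC", 500, gc = 1), seed = 1)
  expect_false(grepl("[AT]", pure[["chrC"]]))
  # different seed, different sequence
  expect_false(identical(unclass(ref1),
                         unclass(generate_toy_reference(m, seed = 8))))
  expect_error(chrom_model("bad", 0), "length")
})

test_that("catalog sampling matches requested counts and avoids overlap", {
  m <- default_chrom_models(4, 2e5)
  cfg <- catalog_config(germline_snv = 50, germline_indel = 10,
                        germline_cnv_del = 30, germline_cnv_dup = 30,
                        somatic_snv = 20, somatic_indel = 5,
                        somatic_arm = 4, somatic_del = 50, somatic_amp = 50,
                        germline_cnv_size = c(52, 2000),
                        somatic_cnv_size = c(500, 3000))
  cat0 <- sample_variant_catalog(cfg, m, seed = 11)
  som_scna <- cat0$somatic[vtype %in% c("CNV_DEL", "CNV_AMP")]
  expect_identical(nrow(som_scna), 104L)  # 4 arm + 50 del + 50 amp
  expect_identical(sum(som_scna$arm_flag), 4L)
  expect_identical(nrow(som_scna[vtype == "CNV_DEL" & !arm_flag]), 50L)
  expect_identical(nrow(som_scna[vtype == "CNV_AMP" & !arm_flag]), 50L)
  expect_identical(nrow(cat0$germline[vtype == "SNV"]), 50L)
  # pairwise non-overlap per haplotype across ALL variants
  all_specs <- rbind(cat0$germline, cat0$somatic)
  for (h in c("hap0", "hap1")) {
    sp <- all_specs[get(h) == TRUE]
    sp[, oend := pmax(end, start + 1)]
    setkey(sp, chrom, start)
    ov <- sp[, any(start[-1] < head(cummax(oend), -1)), by = chrom]$V1
    expect_false(any(ov))
  }
  # het/hom encoding invariant
  expect_true(all(all_specs[zygosity == "het", xor(hap0, hap1)]))
  expect_true(all(all_specs[zygosity == "hom", hap0 & hap1]))
  # copy-number events never share reference space, even across haplotypes
  # (an amp over a del on the other haplotype would cancel in read depth)
  cnv <- all_specs[vtype %in% c("CNV_DEL", "CNV_AMP")]
  setkey(cnv, chrom, start)
  expect_false(any(cnv[, .(ov = start[-1] < head(end, -1)), by = chrom]$ov))
})

test_that("catalog degenerate configurations behave", {
  m <- default_chrom_models(2, 5e4)
  zero <- catalog_config(germline_snv = 0, germline_indel = 0,
                         germline_cnv_del = 0, germline_cnv_dup = 0,
                         somatic_snv = 0, somatic_indel = 0, somatic_arm = 0,
                         somatic_del = 0, somatic_amp = 0)
  cat0 <- sample_variant_catalog(zero, m, seed = 1)
  expect_identical(nrow(cat0$germline), 0L)
  expect_identical(nrow(cat0$somatic), 0L)
  # het probability 1 -> all het
  allhet <- catalog_config(germline_snv = 0, germline_indel = 0,
                           germline_cnv_del = 100, germline_cnv_dup = 100,
                           somatic_snv = 0, somatic_indel = 0,
                           somatic_arm = 0, somatic_del = 0, somatic_amp = 0,
                           het_prob = 1, germline_cnv_size = c(52, 200))
  cat1 <- sample_variant_catalog(allhet, m, seed = 2)
  expect_identical(nrow(cat1$germline), 200L)
  expect_true(all(cat1$germline$zygosity == "het"))
  # genome too small -> explicit placement failure naming the category
  big <- catalog_config(germline_snv = 0, germline_indel = 0,
                        germline_cnv_del = 500, germline_cnv_dup = 0,
                        somatic_snv = 0, somatic_indel = 0, somatic_arm = 0,
                        somatic_del = 0, somatic_amp = 0,
                        germline_cnv_size = c(5e3, 4e4), max_retries = 20)
  expect_error(
    sample_variant_catalog(big, default_chrom_models(1, 3e4), seed = 3),
    "germline_cnv_del")
})

test_that("implantation bookkeeping: tandem duplication and deletion", {
  ref <- structure(setNames(paste(rep("ACGT", 25), collapse = ""), "chr1"))
  amp <- data.table::data.table(
    id = "v1", chrom = "chr1", start = 40, end = 50, vtype = "CNV_AMP",
    alt_seq = "", copies = 1L, zygosity = "het", hap0 = TRUE, hap1 = FALSE,
    origin = "somatic", clone_ids = "", arm_flag = FALSE)
  g <- implant_variants(ref, amp)
  hl <- haplotype_lengths(g)
  expect_identical(hl[hap == 0, length], 110L)
  expect_identical(hl[hap == 1, length], 100L)
  # the duplicated copy is inserted immediately after the source interval
  expect_identical(substr(g$seq[["chr1"]][1], 41, 60),
                   unname(strrep(substr(ref, 41, 50), 2)))
  # truth interval stays in reference coordinates
  expect_identical(g$specs[1, .(start, end)],
                   data.table::data.table(start = 40, end = 50))
  del <- data.table::copy(amp)[, `:=`(vtype = "CNV_DEL", copies = NA_integer_,
                                      start = 10, end = 30, zygosity = "hom",
                                      hap0 = TRUE, hap1 = TRUE)]
  g2 <- implant_variants(ref, del)
  expect_identical(haplotype_lengths(g2)$length, c(80L, 80L))
  expect_identical(g2$seq[["chr1"]][1],
                   paste0(substr(ref, 1, 10), substr(ref, 31, 100)))
  # out of bounds -> rejected with coordinates
  bad <- data.table::copy(amp)[, `:=`(start = 90, end = 120)]
  expect_error(implant_variants(ref, bad), "90-120")
})

test_that("haplotype length equals the closed-form edit formula", {
  m <- default_chrom_models(3, 6e4)
  ref <- generate_toy_reference(m, seed = 5)
  cfg <- catalog_config(germline_snv = 40, germline_indel = 30,
                        germline_cnv_del = 25, germline_cnv_dup = 25,
                        somatic_snv = 0, somatic_indel = 0, somatic_arm = 2,
                        somatic_del = 10, somatic_amp = 10,
                        germline_cnv_size = c(52, 800),
                        somatic_cnv_size = c(200, 2000),
                        amp_copies = c(1L, 2L, 3L))
  cat0 <- sample_variant_catalog(cfg, m, unclass(ref), seed = 6)
  specs <- rbind(cat0$germline, cat0$somatic)
  g <- implant_variants(ref, specs)
  hl <- haplotype_lengths(g)
  for (h in 0:1) {
    hc <- if (h == 0) "hap0" else "hap1"
    for (ch in names(ref)) {
      sp <- specs[chrom == ch & get(hc) == TRUE]
      delta <- sp[vtype == "INS", sum(nchar(alt_seq))] -
        sp[vtype %in% c("SMALL_DEL", "CNV_DEL"), sum(end - start)] +
        sp[vtype == "CNV_AMP", sum((end - start) * copies)]
      expect_identical(hl[chrom == ch & hap == h, length],
                       as.integer(nchar(ref[[ch]]) + delta))
    }
  }
  # liftover blocks sorted and non-overlapping on the haplotype axis
  lo <- g$liftover
  bad <- lo[, any(hstart[-1] < head(hend, -1)), by = .(chrom, hap)]$V1
  expect_false(any(bad))
  expect_true(all(lo$hend - lo$hstart >= 0))
})

test_that("clone construction assigns every somatic event", {
  m <- default_chrom_models(4, 1e5)
  ref <- generate_toy_reference(m, seed = 3)
  cfg <- catalog_config(germline_snv = 0, germline_indel = 0,
                        germline_cnv_del = 0, germline_cnv_dup = 0,
                        somatic_snv = 0, somatic_indel = 0, somatic_arm = 0,
                        somatic_del = 30, somatic_amp = 30,
                        somatic_cnv_size = c(200, 1500))
  cat0 <- sample_variant_catalog(cfg, m, seed = 4)
  bc <- build_clone_genomes(NULL, ref, cat0$somatic, n_clones = 5,
                            truncal_fraction = 0, seed = 9)
  ids <- bc$truth[origin == "somatic", clone_ids]
  expect_true(all(grepl("^[1-5]$", ids)))  # private: exactly one clone
  counts <- table(factor(ids, levels = as.character(1:5)))
  expect_identical(sum(counts), 60L)
  # truncal fraction 1 -> every clone carries every event
  bc2 <- build_clone_genomes(NULL, ref, cat0$somatic, n_clones = 3,
                             truncal_fraction = 1, seed = 9)
  expect_true(all(bc2$truth[origin == "somatic", clone_ids] == "1,2,3"))
  # 0 somatic events -> clones identical to control background
  bc3 <- build_clone_genomes(NULL, ref, cat0$somatic[0], n_clones = 2,
                             seed = 1)
  expect_identical(bc3$clones[[1]]$seq, bc3$clones[[2]]$seq)
  expect_identical(bc3$clones[[1]]$seq[["chr1"]][1], ref[["chr1"]])
  expect_error(build_clone_genomes(NULL, ref, cat0$somatic, n_clones = 0),
               "n_clones")
})

test_that("truth export round-trips and is byte-deterministic", {
  m <- default_chrom_models(2, 8e4)
  ref <- generate_toy_reference(m, seed = 2)
  cfg <- catalog_config(germline_snv = 5, germline_indel = 5,
                        germline_cnv_del = 10, germline_cnv_dup = 10,
                        somatic_snv = 0, somatic_indel = 0, somatic_arm = 1,
                        somatic_del = 5, somatic_amp = 5,
                        germline_cnv_size = c(52, 500),
                        somatic_cnv_size = c(200, 1000))
  run <- function() {
    cat0 <- sample_variant_catalog(cfg, m, unclass(ref), seed = 13)
    bc <- build_clone_genomes(NULL, ref, cat0$somatic, 5, 0, seed = 14)
    truth <- truth_table(rbind(cat0$germline, bc$truth[origin == "somatic"]))
    f <- tempfile(fileext = ".tsv")
    export_truth(truth, f)
    f
  }
  f1 <- run(); f2 <- run()
  expect_identical(readLines(f1), readLines(f2))
  back <- read_truth(f1)
  # all CNV records present with the expected columns
  expect_identical(nrow(back), 31L)  # 20 germline + 11 somatic
  expect_identical(names(back), c("chrom", "start", "end", "type",
                                  "zygosity", "clone_ids", "origin",
                                  "arm_flag"))
  expect_true(all(back$type %in% c("amp", "del")))
  expect_identical(sum(back$arm_flag), 1L)
  # format contract on a literal record
  one <- truth_table(data.table::data.table(
    id = "v1", chrom = "chr1", start = 40, end = 50, vtype = "CNV_AMP",
    alt_seq = "", copies = 1L, zygosity = "het", hap0 = TRUE, hap1 = FALSE,
    origin = "somatic", clone_ids = "2", arm_flag = FALSE))
  f3 <- tempfile(); export_truth(one, f3)
  expect_identical(readLines(f3)[2], "chr1\t40\t50\tamp\thet\t2\tsomatic\t0")
  # empty table -> header-only file
  f4 <- tempfile(); export_truth(truth_table(one[0]), f4)
  expect_identical(length(readLines(f4)), 1L)
  expect_identical(nrow(read_truth(f4)), 0L)
})

test_that("zygosity sampling hits the 90% heterozygous design", {
  m <- default_chrom_models(8, 4e5)
  cfg <- catalog_config(germline_snv = 0, germline_indel = 0,
                        germline_cnv_del = 1000, germline_cnv_dup = 1000,
                        somatic_snv = 0, somatic_indel = 0, somatic_arm = 0,
                        somatic_del = 0, somatic_amp = 0,
                        germline_cnv_size = c(52, 600))
  cat0 <- sample_variant_catalog(cfg, m, seed = 21)
  n <- nrow(cat0$germline)
  expect_identical(n, 2000L)
  k <- sum(cat0$germline$zygosity == "het")
  ci <- qbinom(c(0.005, 0.995), n, 0.9)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
})
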