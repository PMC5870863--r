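seg <- function(chrom, start, end, type) segments(chrom, start, end, type)

test_that("target restriction clips or filters as requested", {
  targets <- data.table::data.table(chrom = "c1", start = c(50, 300),
                                    end = c(150, 400))
  s <- seg("c1", c(0, 500), c(100, 600), c("del", "del"))
  clipped <- restrict_to_targets(s, targets, "clip")
  expect_identical(clipped$start, 50)
  expect_identical(clipped$end, 100)
  filtered <- restrict_to_targets(s, targets, "filter")
  expect_identical(nrow(filtered), 1L)
  expect_identical(filtered$start, 0)  # kept whole
  # disjoint segment dropped in both modes
  far <- seg("c1", 1000, 2000, "amp")
  expect_identical(nrow(restrict_to_targets(far, targets, "clip")), 0L)
  expect_identical(nrow(restrict_to_targets(far, targets, "filter")), 0L)
  # clip then nucleotide GP equals the sum of per-target intersections
  g <- seg("c1", 0, 1000, "del")
  gp <- nucleotide_metrics(restrict_to_targets(g, targets, "clip"), seg("c1", 1, 2, "del"))$GP
  expect_equal(gp, (150 - 50) + (400 - 300))
})

test_that("nucleotide metrics count intersecting bases by type", {
  gold <- seg("c1", 100, 200, "del")
  pred <- seg("c1", 150, 250, "del")
  m <- nucleotide_metrics(gold, pred)
  expect_equal(m$TP, 50); expect_equal(m$PP, 100); expect_equal(m$GP, 100)
  expect_equal(m$precision, 0.5); expect_equal(m$sensitivity, 0.5)
  # identity
  mi <- nucleotide_metrics(gold, gold)
  expect_equal(mi$precision, 1); expect_equal(mi$sensitivity, 1)
  # type mismatch -> no credit
  expect_equal(nucleotide_metrics(gold, seg("c1", 100, 200, "amp"))$TP, 0)
  # zero denominators -> NA
  expect_true(is.na(nucleotide_metrics(gold, gold[0])$precision))
  expect_true(is.na(nucleotide_metrics(gold[0], pred)$sensitivity))
})

test_that("interval metrics use inclusive 80% union coverage", {
  # boundary: overlap exactly 80% of the prediction counts as TP
  m <- interval_metrics(seg("c1", 0, 80, "del"), seg("c1", 0, 100, "del"))
  expect_identical(m$TP, 1L)
  m2 <- interval_metrics(seg("c1", 0, 79, "del"), seg("c1", 0, 100, "del"))
  expect_identical(m2$TP, 0L)
  # two adjacent predictions jointly cover one gold interval: TD once
  gold <- seg("c1", 0, 100, "amp")
  pred <- seg("c1", c(0, 50), c(50, 100), c("amp", "amp"))
  m3 <- interval_metrics(gold, pred)
  expect_identical(m3$TD, 1L)
  expect_equal(m3$sensitivity, 1)
  # no predictions: precision NA, sensitivity 0
  m4 <- interval_metrics(gold, gold[0])
  expect_true(is.na(m4$precision))
  expect_equal(m4$sensitivity, 0)
})

test_that("gene metrics demand 80% gene coverage of matching type", {
  genes <- data.table::data.table(chrom = "c1", start = c(0, 1000),
                                  end = c(100, 1100),
                                  name = c("gA", "gB"))
  gold <- seg("c1", 0, 500, "del")
  pred <- seg("c1", 0, 500, "del")
  m <- gene_metrics(gold, pred, genes)
  expect_identical(m$TP, 1L); expect_equal(m$precision, 1)
  # 79% coverage is excluded from PP
  pred79 <- seg("c1", 0, 79, "del")
  m2 <- gene_metrics(gold, pred79, genes)
  expect_identical(m2$PP, 0L)
  pred80 <- seg("c1", 0, 80, "del")
  expect_identical(gene_metrics(gold, pred80, genes)$PP, 1L)
  # amp prediction over a del gold gene is not a TP
  m3 <- gene_metrics(gold, seg("c1", 0, 500, "amp"), genes)
  expect_identical(m3$TP, 0L)
  expect_error(gene_metrics(gold, pred, genes[0]), "empty gene model")
})

test_that("metrics agree with brute-force oracles on random instances", {
  genes <- data.table::data.table(
    chrom = rep(c("c1", "c2"), each = 10),
    start = rep(seq(0, 90000, by = 10000), 2),
    end = rep(seq(0, 90000, by = 10000), 2) + 4000,
    name = sprintf("g%02d", 1:20))
  set.seed(424)
  for (i in 1:25) {
    gold <- random_segments(sample(0:30, 1))
    pred <- random_segments(sample(0:30, 1))
    mn <- nucleotide_metrics(gold, pred)
    on <- oracle_nucleotide(gold, pred)
    expect_equal(mn$TP, on$TP); expect_equal(mn$PP, on$PP)
    expect_equal(mn$GP, on$GP)
    mi <- interval_metrics(gold, pred)
    oi <- oracle_interval(gold, pred)
    expect_equal(mi$TP, oi$TP); expect_equal(mi$TD, oi$TD)
    mg <- gene_metrics(gold, pred, genes)
    og <- oracle_gene(gold, pred, genes)
    expect_equal(mg$TP, og$TP); expect_equal(mg$PP, og$PP)
    expect_equal(mg$GP, og$GP)
  }
})

test_that("splitting predictions preserves nucleotide and gene metrics", {
  genes <- data.table::data.table(chrom = "c1",
                                  start = seq(0, 9000, by = 1000),
                                  end = seq(0, 9000, by = 1000) + 800,
                                  name = sprintf("g%02d", 1:10))
  set.seed(77)
  for (i in 1:20) {
    gold <- random_segments(10, L = 1e4, chroms = "c1", max_len = 2000)
    pred <- random_segments(8, L = 1e4, chroms = "c1", max_len = 2000)
    # split every prediction into two contiguous same-type pieces
    mid <- floor((pred$start + pred$end) / 2)
    ok <- mid > pred$start & mid < pred$end
    split_pred <- rbind(
      data.table::data.table(chrom = pred$chrom[ok], start = pred$start[ok],
                             end = mid[ok], type = pred$type[ok]),
      data.table::data.table(chrom = pred$chrom[ok], start = mid[ok],
                             end = pred$end[ok], type = pred$type[ok]),
      pred[!ok])
    expect_equal(nucleotide_metrics(gold, pred)$TP,
                 nucleotide_metrics(gold, split_pred)$TP)
    expect_equal(nucleotide_metrics(gold, pred)$PP,
                 nucleotide_metrics(gold, split_pred)$PP)
    expect_equal(gene_metrics(gold, pred, genes)$TP,
                 gene_metrics(gold, split_pred, genes)$TP)
  }
})

test_that("swapping gold and prediction swaps the metric roles", {
  set.seed(99)
  for (i in 1:20) {
    a <- random_segments(12); b <- random_segments(12)
    mn <- nucleotide_metrics(a, b); mn_sw <- nucleotide_metrics(b, a)
    expect_equal(mn$precision, mn_sw$sensitivity)
    expect_equal(mn$sensitivity, mn_sw$precision)
    mi <- interval_metrics(a, b); mi_sw <- interval_metrics(b, a)
    expect_identical(mi$TP, mi_sw$TD)  # TP/TD roles swap
    expect_identical(mi$TD, mi_sw$TP)
  }
})

test_that("AF stratification bins gold variants and applies the TD rule", {
  gold <- seg("c1", c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500), "del")
  af <- c(0.05, 0.15, 0.25, 0.45)
  # detect only the two high-AF variants
  pred <- seg("c1", c(2000, 3000), c(2500, 3500), "del")
  tab <- stratify_sensitivity_by_af(gold, pred, af = af)
  expect_identical(nrow(tab), 5L)
  expect_equal(tab$sensitivity[1:2], c(0, 0))
  expect_equal(tab$sensitivity[3], 1)
  expect_true(is.na(tab$sensitivity[4]))  # empty bin
  expect_equal(tab$sensitivity[5], 1)
  # all detected -> every non-empty bin 1
  tab2 <- stratify_sensitivity_by_af(gold, gold, af = af)
  expect_true(all(tab2[n_gold > 0, sensitivity] == 1))
})

test_that("size stratification bins by own length with the 80% TP rule", {
  gold <- seg("c1", c(0, 10000), c(500, 10000 + 5e6), c("del", "amp"))
  tab0 <- stratify_by_size(gold, segments())
  expect_identical(tab0[size_class == "<1 Kb" & type == "del", n_gold], 1L)
  expect_identical(tab0[size_class == "1-10 Mb" & type == "amp", n_gold], 1L)
  expect_true(all(tab0$n_called == 0L))
  # a 50 kb prediction inside the 5 Mb gold amp: TP in the 10-100 Kb bin
  pred <- seg("c1", 20000, 70000, "amp")
  tab1 <- stratify_by_size(gold, pred)
  expect_identical(tab1[size_class == "10-100 Kb" & type == "amp",
                        .(n_called, n_called_tp)],
                   data.table::data.table(n_called = 1L, n_called_tp = 1L))
  # a prediction with < 80% support is called but not TP
  bad <- seg("c1", 0, 5000, "del")  # only 500/5000 supported
  tab2 <- stratify_by_size(gold, bad)
  expect_identical(tab2[size_class == "1-10 Kb" & type == "del",
                        .(n_called, n_called_tp)],
                   data.table::data.table(n_called = 1L, n_called_tp = 0L))
})

test_that("gene-count log ratio measures over/under-calling", {
  genes <- data.table::data.table(chrom = "c1",
                                  start = seq(0, 9000, by = 1000),
                                  end = seq(0, 9000, by = 1000) + 500,
                                  name = sprintf("g%02d", 1:10))
  gold <- seg("c1", 0, 600, "amp")        # covers g01
  pred8 <- seg("c1", 0, 7600, "amp")      # covers g01..g08
  r <- gene_count_log_ratio(gold, pred8, genes)
  expect_equal(r$log_ratio, 3)  # log2(8/1)
  expect_true(r$low_scna)
  r0 <- gene_count_log_ratio(gold, gold, genes)
  expect_equal(r0$log_ratio, 0)
  # zero gold genes without pseudocount -> NA; with pseudocount defined
  none <- seg("c1", 20000, 21000, "del")
  rna <- gene_count_log_ratio(none, pred8, genes)
  expect_true(is.na(rna$log_ratio))
  rp <- gene_count_log_ratio(none, pred8, genes, pseudocount = 1)
  expect_equal(rp$log_ratio, log2(9))
})

test_that("segment file adapters round-trip and map SEG sign to type", {
  s <- seg(c("c1", "c2"), c(0, 100), c(50, 500), c("amp", "del"))
  f <- tempfile(fileext = ".tsv")
  write_segments(s, f)
  expect_equal(read_segments(f), s)
  # SEG dialect: 1-based closed, sign of seg.mean
  fseg <- tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s\tc1\t101\t200\t10\t0.8",
               "s\tc1\t301\t400\t10\t-0.7",
               "s\tc1\t501\t600\t10\t0.05"), fseg)
  sg <- read_seg(fseg, log2_threshold = 0.3)
  expect_identical(nrow(sg), 2L)
  expect_equal(sg$start, c(100, 300))
  expect_identical(sg$type, c("amp", "del"))
})
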