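# NGS QC, GC normalization, segmentation and CNV-value classification.

ngs_g <- genome_model(as.character(1:22))
ngs_w <- simulate_mda(ngs_g, tile_kb = 1000, sigma_log = 0, seed = 1)
ngs_dis <- cell_karyotype(genome = ngs_g)

exact_sig <- function(truth, ...) {
  render_ngs(truth, ngs_w, gc_coeffs = c(0, 0), overdispersion = 0,
             exact = TRUE, genome = ngs_g, seed = 2, ...)
}

test_that("run QC gates reads, map ratio, GC content and SD", {
  s <- exact_sig(biopsy_truth(list(ngs_dis), 1))
  qc <- ngs_qc(s)
  expect_true(qc$pass)
  expect_lt(qc$sd, 3.5)

  fail_meta <- function(sig, field, value) {
    attr(sig, "meta")[[field]] <- value
    sig
  }
  expect_false(ngs_qc(fail_meta(s, "map_ratio", 75))$pass)
  expect_false(ngs_qc(fail_meta(s, "gc_content", 38))$pass)
  expect_false(ngs_qc(fail_meta(s, "gc_content", 46))$pass)
  expect_false(ngs_qc(fail_meta(s, "total_reads", 650000))$pass)
  expect_error(ngs_qc(s[0, ]), "empty")
})

test_that("GC normalization removes an injected bias curve", {
  # flat counts, uniform GC: all ratios 1
  s <- exact_sig(biopsy_truth(list(ngs_dis), 1))
  n0 <- gc_normalize(s)
  expect_lt(max(abs(n0$ratio - 1)), 1e-9)

  # the default log-quadratic GC curve on a disomic genome normalizes to ~1
  s1 <- render_ngs(biopsy_truth(list(ngs_dis), 1), ngs_w,
                   gc_coeffs = c(1, -10), overdispersion = 0, exact = TRUE,
                   genome = ngs_g, seed = 3)
  n1 <- gc_normalize(s1)
  expect_lt(stats::quantile(abs(n1$ratio - 1), 0.95), 0.02)

  # dosage survives normalization: trisomy-21 bins sit near ratio 1.5
  tri <- cell_karyotype(parse_mosaic_notation("+21", ngs_g), genome = ngs_g)
  s2 <- render_ngs(biopsy_truth(list(tri), 1), ngs_w,
                   gc_coeffs = c(1, -10), overdispersion = 0, exact = TRUE,
                   genome = ngs_g, seed = 4)
  n2 <- gc_normalize(s2)
  expect_equal(median(n2$ratio[n2$chrom == "21"]), 1.5, tolerance = 0.02)
})

test_that("segmentation recovers whole-chromosome dosage at the 4 Mb floor", {
  segs0 <- segment_cnv(gc_normalize(exact_sig(biopsy_truth(list(ngs_dis), 1))),
                       ngs_g)
  expect_true(all(segs0$scope == "whole"))
  expect_equal(segs0$cnv_value, rep(2, nrow(segs0)), tolerance = 1e-9)

  tri <- cell_karyotype(parse_mosaic_notation("+21", ngs_g), genome = ngs_g)
  segs1 <- segment_cnv(gc_normalize(exact_sig(biopsy_truth(list(tri), 1))),
                       ngs_g)
  s21 <- segs1[segs1$chrom == "21", ]
  expect_equal(s21$scope, "whole")
  expect_equal(s21$cnv_value, 3, tolerance = 1e-9)

  # a 3 Mb deletion is below the resolution floor: no event is reported
  del3 <- cell_karyotype(cn_event("2", "segment", "loss",
                                  start = 100e6, end = 103e6, genome = ngs_g),
                         genome = ngs_g)
  d3 <- call_ngs(exact_sig(biopsy_truth(list(del3), 1)), ngs_g)
  expect_equal(nrow(d3$events), 0)

  # a 20 Mb full deletion is resolved with its coordinates and CNV ~ 1
  del20 <- cell_karyotype(cn_event("2", "segment", "loss",
                                   start = 100e6, end = 120e6,
                                   genome = ngs_g), genome = ngs_g)
  segs3 <- segment_cnv(gc_normalize(exact_sig(biopsy_truth(list(del20), 1))),
                       ngs_g)
  hit <- segs3[segs3$chrom == "2" & segs3$scope == "segment" &
                 segs3$cnv_value < 1.2, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$cnv_value, 1, tolerance = 0.05)
  expect_lt(abs(hit$start - 100e6), 2e6)
  expect_lt(abs(hit$end - 120e6), 2e6)
})

test_that("CNV classification partitions the axis with closed mosaic ends", {
  expect_equal(classify_cnv(2.0)$class, "euploid")
  g22 <- classify_cnv(2.2)
  expect_equal(g22$class, "mosaic")
  expect_equal(g22$direction, "gain")
  expect_equal(g22$level_percent, 20)
  l15 <- classify_cnv(1.5)
  expect_equal(l15$class, "mosaic")
  expect_equal(l15$direction, "loss")
  expect_equal(l15$level_percent, 50)
  expect_equal(classify_cnv(3.0)$class, "aneuploid")
  expect_equal(classify_cnv(3.0)$direction, "gain")
  expect_equal(classify_cnv(1.1)$class, "aneuploid")
  # shared interval endpoints belong to the mosaic classes
  expect_equal(classify_cnv(1.8)$class, "mosaic")
  expect_equal(classify_cnv(2.8)$class, "mosaic")
  expect_error(classify_cnv(-0.1))
})

test_that("classification is exhaustive and monotone over a fine grid", {
  order_classes <- c("aneuploid loss", "mosaic loss", "euploid NA",
                     "mosaic gain", "aneuploid gain")
  grid <- seq(0, 4, by = 0.005)
  cls <- vapply(grid, function(v) {
    r <- classify_cnv(v)
    paste(r$class, r$direction)
  }, "")
  expect_true(all(cls %in% order_classes))
  # monotone: class index never decreases along the CNV axis
  idx <- match(cls, order_classes)
  expect_true(all(diff(idx) >= 0))
  # level identity before rounding
  for (v in c(1.2, 1.37, 1.8, 2.2, 2.544, 2.8)) {
    r <- classify_cnv(v)
    expect_equal(r$level_percent, round(abs(v - 2) * 100))
  }
})

test_that("the NGS caller reports mosaic events with levels", {
  tri <- cell_karyotype(parse_mosaic_notation("+21", ngs_g), genome = ngs_g)
  mono <- cell_karyotype(parse_mosaic_notation("-21", ngs_g), genome = ngs_g)

  d0 <- call_ngs(exact_sig(biopsy_truth(list(ngs_dis), 1)), ngs_g)
  expect_equal(d0$overall_class, "euploid")

  # the complementary-error mixture: 40% monosomy + 60% trisomy -> 20% gain
  dmix <- call_ngs(exact_sig(biopsy_truth(list(mono, tri), c(0.4, 0.6))),
                   ngs_g)
  ev <- dmix$events
  expect_equal(nrow(ev), 1)
  expect_true(ev$mosaic)
  expect_equal(ev$direction, "gain")
  expect_equal(ev$level_percent, 20)
  expect_equal(ev$cnv_value, 2.2, tolerance = 1e-9)

  d100 <- call_ngs(exact_sig(biopsy_truth(list(tri), 1)), ngs_g)
  expect_equal(d100$overall_class, "aneuploid")
  expect_equal(d100$events$cnv_value, 3, tolerance = 1e-9)
})

test_that("complementary mixtures are inseparable for the caller", {
  tri <- cell_karyotype(parse_mosaic_notation("+21", ngs_g), genome = ngs_g)
  mono <- cell_karyotype(parse_mosaic_notation("-21", ngs_g), genome = ngs_g)
  t_a <- biopsy_truth(list(mono, tri), c(0.4, 0.6))
  t_b <- biopsy_truth(list(ngs_dis, tri), c(0.8, 0.2))
  # matched seeds and noise: identical signals, identical diagnoses
  for (s in 1:3) {
    w <- simulate_mda(ngs_g, tile_kb = 1000, sigma_log = 0.2, seed = 40 + s)
    da <- call_ngs(render_ngs(t_a, w, genome = ngs_g, seed = s), ngs_g)
    db <- call_ngs(render_ngs(t_b, w, genome = ngs_g, seed = s), ngs_g)
    expect_equal(da$events, db$events)
    expect_equal(da$segments$cnv_value, db$segments$cnv_value)
  }
})

test_that("noiseless CNV estimates equal the copy-number oracle", {
  tri <- cell_karyotype(parse_mosaic_notation("+16", ngs_g), genome = ngs_g)
  for (f in c(0.2, 0.5, 0.9)) {
    truth <- biopsy_truth(list(ngs_dis, tri), c(1 - f, f))
    segs <- segment_cnv(gc_normalize(exact_sig(truth)), ngs_g)
    got <- segs$cnv_value[segs$chrom == "16"]
    expect_equal(got, expected_copy_number(truth, "16", genome = ngs_g),
                 tolerance = 1e-6)
  }
})
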