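# Mixture arithmetic, binomial biopsy quantization, MDA layer moments,
# and the two renderers' noiseless values.

test_that("expected copy number follows mixture arithmetic", {
  # the two complementary mixtures share mean CN 2.2
  t1 <- biopsy_truth(list(karyo("-21"), karyo("+21")), c(0.4, 0.6))
  t2 <- biopsy_truth(list(disomic, karyo("+21")), c(0.8, 0.2))
  expect_equal(expected_copy_number(t1, "21", genome = GENOME), 2.2)
  expect_equal(expected_copy_number(t2, "21", genome = GENOME), 2.2)
  # pure disomy and the balanced mono/tri mixture both average 2
  expect_equal(expected_copy_number(biopsy_truth(list(disomic), 1), "7",
                                    genome = GENOME), 2)
  bal <- biopsy_truth(list(karyo("-21"), karyo("+21")), c(0.5, 0.5))
  expect_equal(expected_copy_number(bal, "21", genome = GENOME), 2)
  # regions untouched by events stay disomic
  expect_equal(expected_copy_number(t1, "1", genome = GENOME), 2)
  expect_equal(expected_copy_number(t1, "21", scope = "p", genome = GENOME), 2.2)
})

test_that("expected copy number is permutation-invariant and linear", {
  set.seed(11)
  for (i in 1:10) {
    f <- runif(1, 0.1, 0.9)
    ta <- biopsy_truth(list(disomic, karyo("+16")), c(1 - f, f))
    tb <- biopsy_truth(list(karyo("+16"), disomic), c(f, 1 - f))
    expect_equal(expected_copy_number(ta, "16", genome = GENOME),
                 expected_copy_number(tb, "16", genome = GENOME))
    # linear in the fraction: CN = 2 + f for a trisomic line
    expect_equal(expected_copy_number(ta, "16", genome = GENOME), 2 + f)
  }
})

test_that("biopsy sampling quantizes the fraction binomially", {
  # degenerate mixtures
  t0 <- make_biopsy("+21", 0, n_cells = 5, seed = 1, genome = GENOME)
  expect_equal(nrow(t0$components), 1)
  expect_equal(expected_copy_number(t0, "21", genome = GENOME), 2)
  t1 <- make_biopsy("+21", 1, n_cells = 5, seed = 1, genome = GENOME)
  expect_equal(expected_copy_number(t1, "21", genome = GENOME), 3)
  expect_error(make_biopsy("+21", 1.2, seed = 1), "fraction")

  # with 5 cells realized fractions live on the 0.2 grid
  fr5 <- vapply(1:50, function(s) {
    tt <- make_biopsy("+21", 0.4, n_cells = 5, seed = s, genome = GENOME)
    (expected_copy_number(tt, "21", genome = GENOME) - 2)
  }, 0)
  expect_true(all(abs(fr5 * 5 - round(fr5 * 5)) < 1e-12))

  # realized abnormal-cell counts follow Binomial(10, 0.4)
  ks <- vapply(1:4000, function(s) {
    tt <- make_biopsy("+21", 0.4, n_cells = 10, seed = 10000 + s,
                      genome = GENOME)
    round(10 * (expected_copy_number(tt, "21", genome = GENOME) - 2))
  }, 0)
  obs <- tabulate(ks + 1, nbins = 11)
  p <- dbinom(0:10, 10, 0.4)
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 1e-4)
})

test_that("MDA weight layer has the configured moments", {
  w0 <- simulate_mda(GENOME, tile_kb = 1000, sigma_log = 0, seed = 3)
  expect_true(all(w0$weight == 1))
  # reproducible under the same seed
  wa <- simulate_mda(GENOME, tile_kb = 500, sigma_log = 0.2, seed = 5)
  wb <- simulate_mda(GENOME, tile_kb = 500, sigma_log = 0.2, seed = 5)
  expect_identical(wa$weight, wb$weight)
  expect_gt(min(wa$weight), 0)
  expect_equal(mean(wa$weight), 1, tolerance = 1e-9)
  # empirical SD of log2 weights matches sigma_log within 2% at ~1e5 tiles
  wc <- simulate_mda(GENOME, tile_kb = 30, sigma_log = 0.2, seed = 6)
  expect_gt(nrow(wc), 1e5)
  expect_equal(sd(log2(wc$weight)), 0.2, tolerance = 0.02)
})

test_that("noiseless SNP rendering reproduces allele-copy arithmetic", {
  small <- genome_model(c("20", "21"))
  wflat <- simulate_mda(small, tile_kb = 1000, sigma_log = 0, seed = 1)
  rs <- function(truth) render_snp(truth, wflat, n_markers = 6000,
                                   sigma_lrr = 0, sigma_baf = 0,
                                   nocall_prob = 0, genome = small, seed = 2)
  # disomic: LogR 0 everywhere, het markers at BAF 0.5
  s0 <- rs(biopsy_truth(list(cell_karyotype(genome = small)), 1))
  expect_equal(max(abs(s0$logr)), 0)
  expect_setequal(round(unique(s0$baf), 6), c(0, 0.5, 1))

  # 100% trisomy-21: LogR log2(1.5), het BAF bands 1/3 and 2/3
  tri <- cell_karyotype(parse_mosaic_notation("+21", small), genome = small)
  s1 <- rs(biopsy_truth(list(tri), 1))
  on21 <- s1$chrom == "21"
  expect_equal(unique(s1$logr[on21]), log2(1.5))
  hets <- on21 & s1$baf > 0.1 & s1$baf < 0.9
  expect_setequal(round(unique(s1$baf[hets]), 6), round(c(1/3, 2/3), 6))
  expect_equal(unique(s1$logr[!on21]), 0)

  # 20% trisomy (mean CN 2.2): het bands at 1/2.2 and 1.2/2.2
  dis <- cell_karyotype(genome = small)
  s2 <- rs(biopsy_truth(list(dis, tri), c(0.8, 0.2)))
  hets <- s2$chrom == "21" & s2$baf > 0.1 & s2$baf < 0.9
  expect_setequal(round(unique(s2$baf[hets]), 6),
                  round(c(1 / 2.2, 1.2 / 2.2), 6))
  expect_equal(unique(s2$logr[s2$chrom == "21"]), log2(1.1))
})

test_that("exact NGS rendering is dosage- and width-proportional", {
  small <- genome_model(c("1", "2", "21"))
  wflat <- simulate_mda(small, tile_kb = 1000, sigma_log = 0, seed = 1)
  dis <- cell_karyotype(genome = small)
  # disomic, no GC curve: counts proportional to bin width
  s0 <- render_ngs(biopsy_truth(list(dis), 1), wflat, gc_coeffs = c(0, 0),
                   overdispersion = 0, exact = TRUE, genome = small, seed = 2)
  rate <- s0$read_count / (s0$end - s0$start + 1)
  expect_lt(diff(range(rate)), 1e-9)

  # 100% trisomy-21: chr21 rate 1.5x the autosomal baseline
  tri <- cell_karyotype(parse_mosaic_notation("+21", small), genome = small)
  s1 <- render_ngs(biopsy_truth(list(tri), 1), wflat, gc_coeffs = c(0, 0),
                   overdispersion = 0, exact = TRUE, genome = small, seed = 2)
  rate <- s1$read_count / (s1$end - s1$start + 1)
  expect_equal(mean(rate[s1$chrom == "21"]) / mean(rate[s1$chrom == "1"]),
               1.5, tolerance = 1e-9)
})

test_that("sampled NGS depth matches the complementary-error ratio", {
  small <- genome_model(c("1", "2", "3", "21"))
  wflat <- simulate_mda(small, tile_kb = 1000, sigma_log = 0, seed = 1)
  dis <- cell_karyotype(genome = small)
  tri <- cell_karyotype(parse_mosaic_notation("+21", small), genome = small)
  mono <- cell_karyotype(parse_mosaic_notation("-21", small), genome = small)
  t_mix <- biopsy_truth(list(mono, tri), c(0.4, 0.6))
  # small bins give ~1e4 bins for a tight standard error
  s <- render_ngs(t_mix, wflat, bin_kb = 80, gc_coeffs = c(0, 0),
                  overdispersion = 0, genome = small, seed = 4)
  rate <- s$read_count / (s$end - s$start + 1)
  on21 <- s$chrom == "21"
  ratio <- mean(rate[on21]) / mean(rate[!on21])
  se <- ratio * sqrt(1 / sum(s$read_count[on21]) +
                       1 / sum(s$read_count[!on21]))
  expect_lt(abs(ratio - 1.1), 3 * se)

  # the 80/20 disomy/trisomy mixture is indistinguishable in the mean
  t_dil <- biopsy_truth(list(dis, tri), c(0.8, 0.2))
  s2 <- render_ngs(t_dil, wflat, bin_kb = 80, gc_coeffs = c(0, 0),
                   overdispersion = 0, genome = small, seed = 5)
  rate2 <- s2$read_count / (s2$end - s2$start + 1)
  ratio2 <- mean(rate2[s2$chrom == "21"]) / mean(rate2[s2$chrom != "21"])
  se2 <- ratio2 * sqrt(1 / sum(s2$read_count[on21]) +
                         1 / sum(s2$read_count[!on21]))
  expect_lt(abs(ratio2 - ratio), 3 * sqrt(se^2 + se2^2))
})
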