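# Contingency tests, the Fisher fallback rule, and cohort aggregation.

# independent oracle: two-sided Fisher p by exhaustive hypergeometric
# enumeration over all tables with the observed marginals
fisher_enum <- function(t) {
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(t[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Pearson chi-square reproduces printed stratified p-values", {
  # whole-chromosome vs segmental mosaicism: 21/49 vs 29/55
  r <- pearson_chi2(matrix(c(21, 28, 29, 26), 2, byrow = TRUE))
  expect_lt(abs(r$p_value - 0.315), 0.001)
  # age < 35 vs >= 35: 37/82 vs 13/23
  r <- pearson_chi2(matrix(c(37, 45, 13, 10), 2, byrow = TRUE))
  expect_lt(abs(r$p_value - 0.333), 0.001)
  # good vs low quality: 38/80 vs 12/25
  r <- pearson_chi2(matrix(c(38, 42, 12, 13), 2, byrow = TRUE))
  expect_lt(abs(r$p_value - 0.965), 0.001)
  # a homogeneous table carries no signal
  r <- pearson_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("continuity correction would break the printed values", {
  # the printed 0.315 is only reproduced without Yates' correction
  t <- matrix(c(21, 28, 29, 26), 2, byrow = TRUE)
  yates <- stats::chisq.test(t, correct = TRUE)$p.value
  expect_lt(abs(yates - 0.418), 0.001)
  expect_gt(abs(yates - pearson_chi2(t)$p_value), 0.05)
})

test_that("the statistic matches the closed form", {
  set.seed(70)
  for (i in 1:20) {
    t <- matrix(rpois(4, 20) + 1, 2)
    a <- t[1, 1]; b <- t[1, 2]; c_ <- t[2, 1]; d <- t[2, 2]; n <- sum(t)
    closed <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(pearson_chi2(t)$statistic, closed, tolerance = 1e-10)
  }
})

test_that("Fisher's exact test agrees with enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(2, 3, 3, 2), 2, byrow = TRUE)), 1)
  set.seed(80)
  for (i in 1:30) {
    t <- matrix(rpois(4, 4), 2)
    if (sum(t) == 0 || any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact(t), fisher_enum(t), tolerance = 1e-7)
  }
})

test_that("the fallback rule picks Fisher below expected count 5", {
  r <- compare_groups(matrix(c(38, 42, 12, 13), 2, byrow = TRUE))
  expect_equal(r$method, "chi2")
  expect_lt(abs(r$p_value - 0.965), 0.001)
  r <- compare_groups(matrix(c(21, 28, 29, 26), 2, byrow = TRUE))
  expect_equal(r$method, "chi2")
  expect_gt(r$min_expected, 5)
  r <- compare_groups(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(r$method, "fisher")
  expect_equal(r$min_expected, 1.5)
  expect_equal(r$p_value, fisher_enum(matrix(c(2, 1, 1, 2), 2, byrow = TRUE)),
               tolerance = 1e-7)
})

make_records <- function(categories, ngs_class = NULL, max_level = NULL,
                         age = 30, quality = TRUE, type = "whole") {
  n <- length(categories)
  if (is.null(ngs_class))
    ngs_class <- ifelse(categories %in% c("complete", "partial",
                                          "discordant_mosaic"), "mosaic",
                        ifelse(categories == "aneuploid_by_ngs",
                               "aneuploid", "euploid"))
  if (is.null(max_level))
    max_level <- ifelse(ngs_class == "mosaic", 40, NA_real_)
  tibble::tibble(
    embryo_id = sprintf("E%03d", seq_len(n)),
    category = categories, ngs_class = ngs_class, max_level = max_level,
    transferable = ngs_class == "euploid" |
      (ngs_class == "mosaic" & max_level <= 50),
    maternal_age = rep_len(age, n), good_quality = rep_len(quality, n),
    mosaic_type_snp = rep_len(type, n))
}

test_that("a single complete record gives a pure rate vector", {
  s <- cohort_summary(make_records("complete"))
  expect_equal(s$concordance$rate_percent, c(100, 0, 0, 0, 0))
  expect_equal(s$n, 1)
})

test_that("cohort accounting matches a hand-counted fixture", {
  cats <- c(rep("complete", 10), rep("partial", 4),
            rep("discordant_mosaic", 2), rep("aneuploid_by_ngs", 3),
            rep("euploid_by_ngs", 1))
  lv <- c(rep(30, 8), rep(60, 8), rep(NA, 4))
  rec <- make_records(cats, max_level = lv,
                      age = c(rep(30, 12), rep(38, 8)),
                      quality = c(rep(TRUE, 15), rep(FALSE, 5)),
                      type = c(rep("whole", 10), rep("segmental", 9), "both"))
  s <- cohort_summary(rec)
  expect_equal(s$n, 20)
  expect_equal(s$concordance$n, c(10, 4, 2, 3, 1))
  expect_equal(sum(s$concordance$n), 20)
  expect_equal(sum(s$concordance$rate_percent), 100, tolerance = 0.05)
  # NGS outcomes: 16 mosaic records, 8 at level <= 50
  expect_equal(s$ngs_outcomes$n[s$ngs_outcomes$outcome == "mosaic"], 16)
  expect_equal(s$ngs_outcomes$n[s$ngs_outcomes$outcome == "mosaic_level_le50"], 8)
  # transferable: 1 euploid + 8 low-level mosaics
  expect_equal(s$transferability$n, c(9, 11))
  # the "both" embryo is excluded from the type stratum
  type_row <- s$strata[s$strata$stratum == "mosaic_type", ]
  expect_equal(type_row$n1 + type_row$n2, 19)
  expect_true(all(s$strata$method %in% c("chi2", "fisher")))

  # unclassified rows are reported by id
  bad <- rec
  bad$category[3] <- NA
  expect_error(cohort_summary(bad), "E003")
})
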