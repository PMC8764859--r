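# Contingency-table tests with the Fisher fallback rule, and cohort
# aggregation into the stratified concordance tables.

check_table <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2))) stop("need a 2x2 table")
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (sum(t) == 0) stop("empty table")
  t
}

expected_counts <- function(t) outer(rowSums(t), colSums(t)) / sum(t)

#' Pearson chi-square test on a 2x2 table
#'
#' Classical Pearson statistic without continuity correction (the convention
#' needed to reproduce printed two-group rate comparisons), with the p-value
#' from the chi-square distribution on 1 df.
#'
#' @param t 2x2 matrix of non-negative counts.
#' @return A one-row tibble: `statistic`, `p_value`.
#' @examples
#' pearson_chi2(matrix(c(21, 28, 29, 26), 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(t) {
  t <- check_table(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("zero marginal total")
  res <- stats::chisq.test(t, correct = FALSE)
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = unname(res$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value: the sum of hypergeometric probabilities of all
#' tables with the observed marginals no more probable than the observed
#' one.
#'
#' @param t 2x2 matrix of non-negative counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(t) {
  t <- check_table(t)
  unname(stats::fisher.test(t)$p.value)
}

#' Compare two groups with the chi-square / Fisher fallback rule
#'
#' Computes the expected counts; if any expected count is below 5 the
#' comparison uses Fisher's exact test, otherwise the Pearson chi-square
#' test without continuity correction.
#'
#' @param t 2x2 matrix of non-negative counts.
#' @return A one-row tibble: `method` (`"chi2"` or `"fisher"`), `statistic`
#'   (`NA` for Fisher), `p_value`, `min_expected`.
#' @examples
#' compare_groups(matrix(c(38, 42, 12, 13), 2, byrow = TRUE))
#' @export
compare_groups <- function(t) {
  t <- check_table(t)
  mex <- min(expected_counts(t))
  if (mex < 5) {
    tibble::tibble(method = "fisher", statistic = NA_real_,
                   p_value = fisher_exact(t), min_expected = mex)
  } else {
    res <- pearson_chi2(t)
    tibble::tibble(method = "chi2", statistic = res$statistic,
                   p_value = res$p_value, min_expected = mex)
  }
}

concordance_levels <- c("complete", "partial", "discordant_mosaic",
                        "aneuploid_by_ngs", "euploid_by_ngs")

#' Aggregate a cohort of dual-platform records
#'
#' Takes one row per embryo and emits the cohort accounting: five-way
#' concordance counts and rates; NGS outcome counts (euploid / aneuploid /
#' mosaic, with the mosaic group split at level 50%); transferable vs
#' untransferable counts; and the stratified complete-concordance
#' comparisons (maternal age < 35 vs >= 35, whole-chromosome vs segmental
#' mosaicism with `"both"` embryos excluded, good vs low embryo quality),
#' each tested with [compare_groups()].
#'
#' @param records A tibble with one row per embryo and columns
#'   `embryo_id`, `category` (a concordance category), `ngs_class`
#'   (`"euploid"`, `"aneuploid"`, `"mosaic"`, `"mosaic_and_aneuploid"`),
#'   `max_level` (highest mosaic level on NGS, `NA` when none),
#'   `transferable` (logical), `maternal_age` (years), `good_quality`
#'   (logical), `mosaic_type_snp` (`"whole"`, `"segmental"`, `"both"`).
#' @return An object of class `cohort_summary`: a list of tibbles
#'   `concordance`, `ngs_outcomes`, `transferability`, `strata`, plus `n`.
#' @export
cohort_summary <- function(records) {
  if (!nrow(records)) stop("no records")
  needed <- c("embryo_id", "category", "ngs_class", "max_level",
              "transferable", "maternal_age", "good_quality",
              "mosaic_type_snp")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- records$embryo_id[!records$category %in% concordance_levels |
                             is.na(records$category)]
  if (length(bad))
    stop("unclassified record(s): ", paste(bad, collapse = ", "))
  n <- nrow(records)

  conc <- tibble::tibble(category = concordance_levels) |>
    dplyr::left_join(dplyr::count(records, .data$category),
                     by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  rate_percent = round(100 * .data$n / !!n, 2))

  mosaic_cls <- c("mosaic", "mosaic_and_aneuploid")
  n_mos <- sum(records$ngs_class %in% mosaic_cls)
  n_low <- sum(records$ngs_class %in% mosaic_cls & records$max_level <= 50)
  ngs_counts <- c(sum(records$ngs_class == "euploid"),
                  sum(records$ngs_class == "aneuploid"),
                  n_mos, n_low, n_mos - n_low)
  ngs_denoms <- c(n, n, n, n_mos, n_mos)
  ngs_out <- tibble::tibble(
    outcome = c("euploid", "aneuploid", "mosaic",
                "mosaic_level_le50", "mosaic_level_gt50"),
    n = ngs_counts,
    denominator = ngs_denoms)
  ngs_out$rate_percent <- round(100 * ngs_out$n / ngs_out$denominator, 2)

  transf_counts <- c(sum(records$transferable), sum(!records$transferable))
  transf_rates <- round(100 * transf_counts / n, 2)
  transf <- tibble::tibble(
    outcome = c("transferable", "untransferable"),
    n = transf_counts,
    rate_percent = transf_rates)

  stratum_row <- function(rec, name, in_g1, g1, g2) {
    complete <- rec$category == "complete"
    a <- sum(complete & in_g1, na.rm = TRUE)
    b <- sum(!complete & in_g1, na.rm = TRUE)
    c_ <- sum(complete & !in_g1, na.rm = TRUE)
    d <- sum(!complete & !in_g1, na.rm = TRUE)
    cmp <- compare_groups(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    tibble::tibble(stratum = name, group1 = g1, group2 = g2,
                   complete1 = a, n1 = a + b, complete2 = c_, n2 = c_ + d,
                   rate1 = round(100 * a / (a + b), 2),
                   rate2 = round(100 * c_ / (c_ + d), 2),
                   method = cmp$method, p_value = cmp$p_value)
  }
  type_rec <- records[records$mosaic_type_snp != "both", ]
  strata <- dplyr::bind_rows(
    stratum_row(records, "maternal_age", records$maternal_age < 35,
                "<35 years", ">=35 years"),
    stratum_row(type_rec, "mosaic_type", type_rec$mosaic_type_snp == "whole",
                "whole", "segmental"),
    stratum_row(records, "embryo_quality", records$good_quality,
                "good", "low"))

  structure(list(n = n, concordance = conc, ngs_outcomes = ngs_out,
                 transferability = transf, strata = strata),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "embryos\n\nConcordance:\n")
  print(as.data.frame(x$concordance), row.names = FALSE)
  cat("\nNGS outcomes:\n")
  print(as.data.frame(x$ngs_outcomes), row.names = FALSE)
  cat("\nTransferability:\n")
  print(as.data.frame(x$transferability), row.names = FALSE)
  cat("\nStratified complete-concordance comparisons:\n")
  print(as.data.frame(x$strata), row.names = FALSE)
  invisible(x)
}
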