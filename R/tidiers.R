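# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a platform diagnosis into its event table
#'
#' @param x A `platform_diagnosis`.
#' @param ... Unused.
#' @return A tibble: one row per event with `embryo_id` and `platform`
#'   prepended (zero rows for a euploid diagnosis).
#' @export
tidy.platform_diagnosis <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(embryo_id = rep(x$embryo_id, nrow(x$events)),
                   platform = rep(x$platform, nrow(x$events))),
    x$events)
}

#' @rdname tidy.platform_diagnosis
#' @return `glance()` returns a one-row tibble: `embryo_id`, `platform`,
#'   `overall_class`, `n_events`, `n_mosaic`, `qc_pass`.
#' @export
glance.platform_diagnosis <- function(x, ...) {
  tibble::tibble(embryo_id = x$embryo_id, platform = x$platform,
                 overall_class = x$overall_class,
                 n_events = nrow(x$events),
                 n_mosaic = sum(x$events$mosaic),
                 qc_pass = if (is.null(x$qc)) NA else x$qc$pass[1])
}

#' Tidy a concordance result into its key table
#'
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @return A tibble with one row per type key and a `membership` column
#'   (`"shared"`, `"snp_only"`, `"ngs_only"`).
#' @export
tidy.concordance_result <- function(x, ...) {
  mk <- function(keys, membership) {
    if (!length(keys)) return(NULL)
    parts <- strsplit(keys, ":", fixed = TRUE)
    tibble::tibble(chrom = vapply(parts, `[`, "", 1),
                   arm_scope = vapply(parts, `[`, "", 2),
                   direction = vapply(parts, `[`, "", 3),
                   membership = membership)
  }
  dplyr::bind_rows(mk(x$shared, "shared"), mk(x$snp_only, "snp_only"),
                   mk(x$ngs_only, "ngs_only"))
}

#' @rdname tidy.concordance_result
#' @return `glance()` returns a one-row tibble with the category and key
#'   counts.
#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(embryo_id = x$embryo_id, category = x$category,
                 n_snp_keys = length(x$snp_keys),
                 n_ngs_keys = length(x$ngs_keys),
                 n_shared = length(x$shared),
                 whole_arm_overlap_flag = x$whole_arm_overlap_flag)
}

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return `tidy()` returns the five-way concordance table; `glance()` a
#'   one-row tibble of the headline rates (percent).
#' @export
tidy.cohort_summary <- function(x, ...) x$concordance

#' @rdname tidy.cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  rate <- function(cat) x$concordance$rate_percent[x$concordance$category == cat]
  tibble::tibble(
    n = x$n,
    complete = rate("complete"), partial = rate("partial"),
    discordant_mosaic = rate("discordant_mosaic"),
    aneuploid_by_ngs = rate("aneuploid_by_ngs"),
    euploid_by_ngs = rate("euploid_by_ngs"),
    transferable = x$transferability$rate_percent[1])
}
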