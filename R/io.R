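# TSV interchange: platform signals, diagnoses, and supplementary-style
# per-embryo cohort tables. All writers emit header comments carrying the
# generating seed/metadata as JSON so a write -> read round trip is lossless.

#' Write / read a platform signal as TSV
#'
#' The signal table is written as tab-separated values preceded by `#`
#' header comments, one of which carries the simulation metadata (including
#' the generating seed) as JSON. `read_signal_tsv()` restores the tibble,
#' its class and its metadata.
#'
#' @param signal A `snp_signal` or `ngs_signal`.
#' @param path File path.
#' @return `write_signal_tsv()` returns `path` invisibly;
#'   `read_signal_tsv()` returns the restored signal.
#' @export
write_signal_tsv <- function(signal, path) {
  meta <- attr(signal, "meta")
  cls <- intersect(class(signal), c("snp_signal", "ngs_signal"))[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# class: ", cls), con)
  writeLines(paste0("# meta: ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                 digits = NA)), con)
  utils::write.table(as.data.frame(signal), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  cls <- sub("^# class: ", "", hdr[startsWith(hdr, "# class: ")][1])
  meta_line <- hdr[startsWith(hdr, "# meta: ")]
  meta <- if (length(meta_line))
    jsonlite::fromJSON(sub("^# meta: ", "", meta_line[1])) else NULL
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  tab$chrom <- as.character(tab$chrom)
  attr(tab, "meta") <- meta
  class(tab) <- c(cls, class(tab))
  tab
}

events_levels <- function(events) {
  if (!nrow(events)) return(NA_character_)
  paste(ifelse(is.na(events$level_percent), "NA", events$level_percent),
        collapse = ";")
}

#' Write / read diagnoses as TSV
#'
#' One row per embryo: `embryo_id`, `platform`, `overall_class`, the call in
#' mosaic notation, and per-event mosaic levels / CNV values (`;`-joined, in
#' event order). Reading reverses the mapping via
#' [parse_mosaic_notation()].
#'
#' @param diagnoses A list of `platform_diagnosis` objects.
#' @param path File path.
#' @param genome,cytobands Genome model and cytoband table for notation.
#' @return `write_diagnosis_tsv()` returns `path` invisibly;
#'   `read_diagnosis_tsv()` returns a list of `platform_diagnosis`.
#' @export
write_diagnosis_tsv <- function(diagnoses, path, genome = genome_model(),
                                cytobands = cytoband_table()) {
  rows <- purrr::map_dfr(diagnoses, function(d) tibble::tibble(
    embryo_id = d$embryo_id, platform = d$platform,
    overall_class = d$overall_class,
    notation = format_diagnosis(d, genome, cytobands),
    levels = events_levels(d$events),
    cnv_values = if (nrow(d$events))
      paste(ifelse(is.na(d$events$cnv_value), "NA",
                   signif(d$events$cnv_value, 6)), collapse = ";")
      else NA_character_))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pgtmosaic diagnosis table", con)
  utils::write.table(as.data.frame(rows), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

split_num <- function(x, n) {
  if (is.na(x) || x == "") return(rep(NA_real_, n))
  out <- suppressWarnings(as.numeric(strsplit(x, ";", fixed = TRUE)[[1]]))
  length(out) <- n
  out
}

#' @rdname write_diagnosis_tsv
#' @export
read_diagnosis_tsv <- function(path, genome = genome_model(),
                               cytobands = cytoband_table()) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  purrr::map(seq_len(nrow(tab)), function(i) {
    ev <- parse_mosaic_notation(tab$notation[i] %||% "euploid",
                                genome, cytobands)
    if (nrow(ev)) {
      ev$level_percent <- split_num(tab$levels[i], nrow(ev))
      ev$cnv_value <- split_num(tab$cnv_values[i], nrow(ev))
    }
    platform_diagnosis(tab$platform[i], ev,
                       embryo_id = tab$embryo_id[i])
  })
}

default_dialect <- function() {
  list(embryo_id = "embryo_id", snp = "snp_result", ngs = "ngs_result",
       level = "ngs_level", age = "maternal_age", quality = "good_quality")
}

#' Ingest a per-embryo supplementary-style diagnosis table
#'
#' Reads a TSV with one row per embryo carrying the SNP and NGS calls in
#' mosaic notation plus covariates. The column layout is configurable
#' through `dialect`, a named list mapping the canonical fields
#' (`embryo_id`, `snp`, `ngs`, `level`, `age`, `quality`) to the file's
#' column names. Rows whose notation fails to parse are collected in the
#' `rejects` attribute, not silently dropped.
#'
#' @param path File path.
#' @param dialect Named list of column mappings; see Details.
#' @param genome,cytobands Genome model and cytoband table.
#' @return A tibble with columns `embryo_id`, `snp` and `ngs`
#'   (list-columns of `platform_diagnosis`), `maternal_age`, `good_quality`,
#'   and attribute `rejects` (tibble of failed rows with the error message).
#' @export
read_diagnosis_table <- function(path, dialect = default_dialect(),
                                 genome = genome_model(),
                                 cytobands = cytoband_table()) {
  dialect <- utils::modifyList(default_dialect(), dialect)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!nrow(tab)) stop("empty diagnosis table: ", path)
  for (fld in c("embryo_id", "snp", "ngs")) {
    if (!dialect[[fld]] %in% names(tab))
      stop("missing mandatory column '", dialect[[fld]], "' (", fld, ")")
  }
  rejects <- list(); rows <- list()
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch({
      snp_ev <- parse_mosaic_notation(tab[[dialect$snp]][i], genome, cytobands)
      ngs_ev <- parse_mosaic_notation(tab[[dialect$ngs]][i], genome, cytobands)
      lv <- if (dialect$level %in% names(tab))
        split_num(tab[[dialect$level]][i], nrow(ngs_ev)) else
          rep(NA_real_, nrow(ngs_ev))
      if (nrow(ngs_ev)) ngs_ev$level_percent <- lv
      tibble::tibble(
        embryo_id = tab[[dialect$embryo_id]][i],
        snp = list(platform_diagnosis("SNP", snp_ev,
                                      embryo_id = tab[[dialect$embryo_id]][i])),
        ngs = list(platform_diagnosis("NGS", ngs_ev,
                                      embryo_id = tab[[dialect$embryo_id]][i])),
        maternal_age = if (dialect$age %in% names(tab))
          suppressWarnings(as.numeric(tab[[dialect$age]][i])) else NA_real_,
        good_quality = if (dialect$quality %in% names(tab))
          tolower(tab[[dialect$quality]][i]) %in% c("true", "yes", "1", "good")
          else NA)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejects[[length(rejects) + 1L]] <- tibble::tibble(
        row = i, embryo_id = tab[[dialect$embryo_id]][i],
        error = conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "rejects") <- dplyr::bind_rows(rejects)
  out
}

snp_mosaic_type <- function(snp) {
  mos <- snp$events[snp$events$mosaic, ]
  if (!nrow(mos)) return(NA_character_)
  whole <- any(mos$scope == "whole"); seg <- any(mos$scope != "whole")
  if (whole && seg) "both" else if (whole) "whole" else "segmental"
}

#' Build summary-ready cohort records from paired diagnoses
#'
#' Runs [classify_concordance()] and [is_transferable()] on each embryo's
#' SNP/NGS diagnosis pair and assembles the flat record table that
#' [cohort_summary()] consumes.
#'
#' @param paired A tibble as returned by [read_diagnosis_table()] (columns
#'   `embryo_id`, list-columns `snp` and `ngs`, `maternal_age`,
#'   `good_quality`).
#' @param genome Genome model tibble.
#' @return A tibble with columns `embryo_id`, `category`, `ngs_class`,
#'   `max_level`, `transferable`, `maternal_age`, `good_quality`,
#'   `mosaic_type_snp`, `whole_arm_overlap_flag`.
#' @export
cohort_records <- function(paired, genome = genome_model()) {
  purrr::map_dfr(seq_len(nrow(paired)), function(i) {
    snp <- paired$snp[[i]]; ngs <- paired$ngs[[i]]
    cc <- classify_concordance(snp, ngs, genome)
    mos <- ngs$events[ngs$events$mosaic, ]
    tibble::tibble(
      embryo_id = paired$embryo_id[i],
      category = cc$category,
      ngs_class = ngs$overall_class,
      max_level = if (nrow(mos)) max(mos$level_percent) else NA_real_,
      transferable = is_transferable(ngs),
      maternal_age = paired$maternal_age[i],
      good_quality = paired$good_quality[i],
      mosaic_type_snp = snp_mosaic_type(snp),
      whole_arm_overlap_flag = cc$whole_arm_overlap_flag)
  })
}
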