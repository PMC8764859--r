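#' @importFrom rlang .data
NULL

# canonical empty copy-number event table (schema definition)
empty_events <- function() {
  tibble::tibble(chrom = character(), scope = character(),
                 start = double(), end = double(),
                 direction = character(), mosaic = logical(),
                 level_percent = double(), cnv_value = double())
}

#' Construct a copy-number event
#'
#' One copy-number abnormality: a chromosome, a scope (whole chromosome, a
#' single arm, or a base-pair segment), a direction (gain/loss), and a mosaic
#' flag. Mosaic events from the NGS platform may carry a mosaic level
#' (percentage of abnormal cells implied by the CNV value) and the CNV value
#' itself; the SNP platform cannot report a level, so it stays `NA` there.
#'
#' @param chrom Chromosome name ("1".."22", "X", "Y").
#' @param scope One of `"whole"`, `"p"`, `"q"`, `"segment"`.
#' @param direction `"gain"` or `"loss"`.
#' @param mosaic Logical; is the event mosaic?
#' @param start,end Segment bounds in bp (1-based inclusive); required iff
#'   `scope == "segment"`.
#' @param level_percent Mosaic level in `[0, 100]` or `NA`.
#' @param cnv_value Estimated copy number (disomy = 2) or `NA`.
#' @param genome Genome model used to validate segment coordinates.
#' @return A one-row events tibble.
#' @examples
#' cn_event("2", "q", "loss", mosaic = TRUE)
#' @export
cn_event <- function(chrom, scope, direction, mosaic = FALSE,
                     start = NA_real_, end = NA_real_,
                     level_percent = NA_real_, cnv_value = NA_real_,
                     genome = genome_model()) {
  scope <- match.arg(scope, c("whole", "p", "q", "segment"))
  direction <- match.arg(direction, c("gain", "loss"))
  if (!chrom %in% genome$chrom) stop("unknown chromosome: ", chrom)
  if (scope == "segment") {
    if (is.na(start) || is.na(end)) stop("segment scope requires start and end")
    if (start > end) stop("segment coordinates out of order")
    len <- genome$length[genome$chrom == chrom]
    if (start < 1 || end > len) stop("segment outside chromosome ", chrom)
  } else {
    start <- NA_real_; end <- NA_real_
  }
  if (!is.na(level_percent) && (level_percent < 0 || level_percent > 100))
    stop("level_percent must be in [0, 100]")
  tibble::tibble(chrom = chrom, scope = scope, start = start, end = end,
                 direction = direction, mosaic = mosaic,
                 level_percent = level_percent, cnv_value = cnv_value)
}

# ---- notation ----------------------------------------------------------

parse_locus <- function(locus, token, genome, cytobands) {
  m <- regexec("^(1[0-9]|2[0-2]|[1-9]|X|Y)(.*)$", locus)
  parts <- regmatches(locus, m)[[1]]
  if (!length(parts)) stop("malformed locus in token '", token, "'")
  chrom <- parts[2]; rest <- parts[3]
  if (!chrom %in% genome$chrom) stop("unknown chromosome '", chrom,
                                     "' in token '", token, "'")
  if (rest == "") return(list(chrom = chrom, scope = "whole",
                              start = NA_real_, end = NA_real_))
  if (rest %in% c("p", "q")) return(list(chrom = chrom, scope = rest,
                                         start = NA_real_, end = NA_real_))
  # band or band range, e.g. "p12.2" or "p12.2-q21"
  bands <- strsplit(rest, "-", fixed = TRUE)[[1]]
  if (!length(bands) %in% 1:2 ||
      !all(grepl("^[pq][0-9]+(\\.[0-9]+)?$", bands)))
    stop("malformed band locus '", rest, "' in token '", token, "'")
  ranges <- lapply(bands, function(b) band_range(cytobands, chrom, b))
  list(chrom = chrom, scope = "segment",
       start = min(vapply(ranges, `[[`, 0, "start")),
       end = max(vapply(ranges, `[[`, 0, "end")))
}

#' Parse mosaic-call notation into copy-number events
#'
#' Parses the compact karyotype notation used for PGT-A calls: a sign
#' (`+` gain, `-` loss) followed by `mos(<locus>)` for mosaic events or a
#' bare locus for non-mosaic events, with multiple events comma-separated.
#' A locus is a chromosome (`"4"`), a chromosome arm (`"2q"`), or a band
#' range (`"16p12.2-q21"`) resolved to base-pair coordinates via the bundled
#' cytoband table; a range spanning the centromere yields a single segment
#' overlapping both arms. The string `"euploid"` (or an empty string) means
#' no events.
#'
#' @param text Notation string, e.g. `"-mos(2q)"`, `"+mos(4)"`, `"+21,-16q"`.
#' @param genome Genome model tibble (see [genome_model()]).
#' @param cytobands Cytoband tibble (see [cytoband_table()]).
#' @return An events tibble (possibly zero rows), one row per event.
#' @examples
#' g <- genome_model()
#' parse_mosaic_notation("-mos(2q)", g)
#' parse_mosaic_notation("+mos(4),-16q", g)
#' @export
parse_mosaic_notation <- function(text, genome = genome_model(),
                                  cytobands = cytoband_table()) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (text == "" || tolower(text) == "euploid") return(empty_events())
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  rows <- lapply(tokens, function(tok) {
    m <- regexec("^([+-])(mos\\(([^)]+)\\)|[^()]+)$", tok)
    parts <- regmatches(tok, m)[[1]]
    if (!length(parts)) stop("malformed token '", tok, "'")
    sign <- parts[2]
    mosaic <- startsWith(parts[3], "mos(")
    locus <- if (mosaic) parts[4] else parts[3]
    loc <- parse_locus(locus, tok, genome, cytobands)
    cn_event(loc$chrom, loc$scope,
             direction = if (sign == "+") "gain" else "loss",
             mosaic = mosaic, start = loc$start, end = loc$end,
             genome = genome)
  })
  dplyr::bind_rows(rows)
}

# band name containing position x (for formatting segments)
band_at <- function(cytobands, chrom, x) {
  hit <- cytobands[cytobands$chrom == chrom &
                     cytobands$start <= x & cytobands$end >= x, ]
  if (!nrow(hit)) stop("position ", x, " not covered by cytoband table on ",
                       chrom)
  hit$band[1]
}

format_one_event <- function(ev, genome, cytobands) {
  sign <- if (ev$direction == "gain") "+" else "-"
  locus <- switch(ev$scope,
    whole = ev$chrom,
    p = paste0(ev$chrom, "p"),
    q = paste0(ev$chrom, "q"),
    segment = {
      b1 <- band_at(cytobands, ev$chrom, ev$start)
      b2 <- band_at(cytobands, ev$chrom, ev$end)
      if (b1 == b2) paste0(ev$chrom, b1)
      else paste0(ev$chrom, b1, "-", b2)
    })
  if (ev$mosaic) paste0(sign, "mos(", locus, ")") else paste0(sign, locus)
}

#' Format a diagnosis (or events table) as mosaic-call notation
#'
#' Inverse of [parse_mosaic_notation()]. Segments are named by the bands
#' containing their endpoints, so the round trip reproduces events up to the
#' coordinate resolution of the cytoband table. An event-free diagnosis
#' formats as `"euploid"`.
#'
#' @param d A `platform_diagnosis` or an events tibble.
#' @inheritParams parse_mosaic_notation
#' @return A single notation string.
#' @export
format_diagnosis <- function(d, genome = genome_model(),
                             cytobands = cytoband_table()) {
  events <- if (inherits(d, "platform_diagnosis")) d$events else d
  if (!nrow(events)) return("euploid")
  paste(vapply(seq_len(nrow(events)), function(i)
    format_one_event(events[i, ], genome, cytobands), ""), collapse = ",")
}

#' Arm-level type keys of a copy-number event
#'
#' Reduces an event to the keys used for between-platform concordance:
#' `(chrom, arm_scope, direction)` where `arm_scope` is `"whole"`, `"p"` or
#' `"q"`. A whole-chromosome event keeps a distinct `"whole"` key (whole vs
#' arm mosaicism are different types); a segment contributes one key per arm
#' it overlaps; segment coordinates never leak into keys.
#'
#' @param events Events tibble (any number of rows).
#' @param genome Genome model tibble.
#' @return A tibble with columns `chrom`, `arm_scope`, `direction`, distinct
#'   rows.
#' @examples
#' g <- genome_model()
#' event_keys(parse_mosaic_notation("+mos(16p12.2-q21)", g), g)
#' @export
event_keys <- function(events, genome = genome_model()) {
  if (inherits(events, "platform_diagnosis")) events <- events$events
  if (!nrow(events))
    return(tibble::tibble(chrom = character(), arm_scope = character(),
                          direction = character()))
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    arms <- switch(ev$scope,
      whole = "whole",
      p = "p", q = "q",
      segment = arms_overlapped(genome, ev$chrom, ev$start, ev$end))
    tibble::tibble(chrom = ev$chrom, arm_scope = arms,
                   direction = ev$direction)
  })
  dplyr::distinct(dplyr::bind_rows(rows))
}

# ---- platform diagnosis ------------------------------------------------

#' One platform's call set for one embryo
#'
#' Bundles the event list, QC report and overall class for a single embryo on
#' a single platform. The overall class is derived from the events: euploid
#' when there are none, mosaic when all are mosaic, aneuploid when none are,
#' and `mosaic_and_aneuploid` for a mixed list.
#'
#' @param platform `"SNP"` or `"NGS"`.
#' @param events Events tibble (see [cn_event()]).
#' @param qc QC report (a one-row tibble from [snp_qc()] / [ngs_qc()]), or
#'   `NULL`.
#' @param embryo_id Optional identifier carried through tidiers.
#' @return An object of class `platform_diagnosis`.
#' @export
platform_diagnosis <- function(platform, events = empty_events(), qc = NULL,
                               embryo_id = NA_character_) {
  platform <- match.arg(platform, c("SNP", "NGS"))
  if (platform == "SNP" && any(!is.na(events$level_percent)))
    stop("the SNP platform cannot report a mosaic level")
  overall <- if (!nrow(events)) "euploid"
    else if (all(events$mosaic)) "mosaic"
    else if (!any(events$mosaic)) "aneuploid"
    else "mosaic_and_aneuploid"
  structure(list(platform = platform, events = events, qc = qc,
                 overall_class = overall, embryo_id = embryo_id),
            class = "platform_diagnosis")
}

#' @export
print.platform_diagnosis <- function(x, ...) {
  cat("<platform_diagnosis> ", x$platform,
      if (!is.na(x$embryo_id)) paste0(" embryo ", x$embryo_id), "\n",
      "  call: ", format_diagnosis(x$events), "  [", x$overall_class, "]\n",
      sep = "")
  if (!is.null(x$qc) && "pass" %in% names(x$qc))
    cat("  qc: ", if (isTRUE(x$qc$pass[1])) "pass" else "FAIL", "\n", sep = "")
  invisible(x)
}
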