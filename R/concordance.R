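# Arm-level between-platform concordance classification and the
# transferability rule.

key_strings <- function(keys) {
  if (!nrow(keys)) character() else
    sort(paste(keys$chrom, keys$arm_scope, keys$direction, sep = ":"))
}

#' Classify between-platform concordance for one embryo
#'
#' Compares the chromosome-arm type keys `(chrom, whole|p|q, direction)` of
#' the mosaic events called by each platform. Deletion vs duplication on the
#' same arm, and whole-chromosome vs single-arm mosaicism of the same
#' chromosome, are different types and never match; segmental coordinate
#' differences within the same arm are ignored. Categories:
#' \describe{
#'   \item{complete}{identical mosaic key sets;}
#'   \item{partial}{overlapping but not identical key sets (including NGS
#'     detecting a superset of the SNP arms);}
#'   \item{discordant_mosaic}{both platforms mosaic but with disjoint keys;}
#'   \item{aneuploid_by_ngs}{NGS reports no mosaic event but pure
#'     aneuploidy;}
#'   \item{euploid_by_ngs}{NGS reports no event at all.}
#' }
#' Every enrolled embryo is SNP-mosaic, so the SNP diagnosis must contain at
#' least one mosaic event.
#'
#' @param snp,ngs `platform_diagnosis` objects (platforms `"SNP"`, `"NGS"`).
#' @param genome Genome model tibble.
#' @return An object of class `concordance_result`: `category`, key sets
#'   (`snp_keys`, `ngs_keys`, `shared`, `snp_only`, `ngs_only`) and a
#'   `whole_arm_overlap_flag` marking the audit edge case where a whole-
#'   chromosome and a same-direction arm call physically overlap yet count
#'   as different types.
#' @examples
#' g <- genome_model()
#' snp <- platform_diagnosis("SNP", parse_mosaic_notation("-mos(2q)", g))
#' ngs <- platform_diagnosis("NGS", parse_mosaic_notation("-mos(2q)", g))
#' classify_concordance(snp, ngs)$category
#' @export
classify_concordance <- function(snp, ngs, genome = genome_model()) {
  stopifnot(inherits(snp, "platform_diagnosis"),
            inherits(ngs, "platform_diagnosis"))
  if (!snp$overall_class %in% c("mosaic", "mosaic_and_aneuploid"))
    stop("the SNP diagnosis must contain at least one mosaic event")
  snp_mos <- snp$events[snp$events$mosaic, ]
  ngs_mos <- ngs$events[ngs$events$mosaic, ]
  S <- key_strings(event_keys(snp_mos, genome))
  N <- key_strings(event_keys(ngs_mos, genome))
  category <- if (!length(N)) {
    if (nrow(ngs$events)) "aneuploid_by_ngs" else "euploid_by_ngs"
  } else if (setequal(S, N)) "complete"
  else if (length(intersect(S, N))) "partial"
  else "discordant_mosaic"

  # audit flag: whole-chromosome vs same-direction arm call on one chromosome
  flag <- FALSE
  if (length(S) && length(N)) {
    parse_keys <- function(k) {
      parts <- strsplit(k, ":", fixed = TRUE)
      tibble::tibble(chrom = vapply(parts, `[`, "", 1),
                     arm_scope = vapply(parts, `[`, "", 2),
                     direction = vapply(parts, `[`, "", 3))
    }
    a <- parse_keys(S); b <- parse_keys(N)
    for (i in seq_len(nrow(a))) {
      m <- b$chrom == a$chrom[i] & b$direction == a$direction[i] &
        ((a$arm_scope[i] == "whole" & b$arm_scope != "whole") |
           (a$arm_scope[i] != "whole" & b$arm_scope == "whole"))
      if (any(m)) flag <- TRUE
    }
  }
  structure(list(category = category, snp_keys = S, ngs_keys = N,
                 shared = intersect(S, N), snp_only = setdiff(S, N),
                 ngs_only = setdiff(N, S),
                 whole_arm_overlap_flag = flag,
                 embryo_id = snp$embryo_id),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> ", x$category, "\n",
      "  SNP keys: ", paste(x$snp_keys, collapse = ", "), "\n",
      "  NGS keys: ", paste(x$ngs_keys, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Is an embryo transferable under its NGS diagnosis?
#'
#' Transferable means euploid, or mosaic with every event's level at or
#' below 50% and no pure (non-mosaic) aneuploid event.
#'
#' @param ngs A `platform_diagnosis` from the NGS platform.
#' @return `TRUE` or `FALSE`.
#' @export
is_transferable <- function(ngs) {
  stopifnot(inherits(ngs, "platform_diagnosis"))
  ev <- ngs$events
  if (!nrow(ev)) return(TRUE)
  if (any(!ev$mosaic)) return(FALSE)
  if (any(is.na(ev$level_percent)))
    stop("mosaic event without a level_percent")
  all(ev$level_percent <= 50)
}
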