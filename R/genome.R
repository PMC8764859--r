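#' Genome model: chromosome lengths, centromeres and arm boundaries
#'
#' Returns the bundled genome model as a tibble with one row per chromosome
#' (1-22, X, Y). Chromosome lengths and centromere positions are hg19 values;
#' coordinates are 1-based inclusive. The p arm spans `[1, centromere]` and
#' the q arm spans `(centromere, length]`.
#'
#' @param chroms Optional character vector restricting the model to a subset
#'   of chromosomes (in the given order).
#' @return A tibble with columns `chrom`, `length`, `centromere`.
#' @examples
#' genome_model()
#' genome_model(c("16", "21"))
#' @export
genome_model <- function(chroms = NULL) {
  g <- tibble::tibble(
    chrom = c(as.character(1:22), "X", "Y"),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560, 59373566),
    centromere = c(125000000, 93300000, 91000000, 50400000, 48400000,
                   61000000, 59900000, 45600000, 49000000, 40200000,
                   53700000, 35800000, 17900000, 17600000, 19000000,
                   36600000, 24000000, 17200000, 26500000, 27500000,
                   13200000, 14700000, 60600000, 12500000)
  )
  stopifnot(all(g$centromere > 0), all(g$centromere < g$length))
  if (!is.null(chroms)) {
    bad <- setdiff(chroms, g$chrom)
    if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    g <- g[match(chroms, g$chrom), ]
  }
  g
}

#' Bundled cytoband table
#'
#' Reads the packaged cytoband table (synthetic ISCN-style banding laid over
#' real hg19 arm lengths; see the file header) used to resolve band-range
#' loci such as `"16p12.2-q21"` to base-pair segments.
#'
#' @return A tibble with columns `chrom`, `band`, `start`, `end`
#'   (1-based inclusive).
#' @export
cytoband_table <- function() {
  path <- system.file("extdata", "cytobands_synthetic.tsv",
                      package = "pgtmosaic", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    band = readr::col_character(),
                    start = readr::col_double(),
                    end = readr::col_double()))
}

# arm boundaries for one chromosome; arm is "p" or "q"
arm_bounds <- function(genome, chrom, arm) {
  row <- genome[genome$chrom == chrom, ]
  if (nrow(row) != 1) stop("unknown chromosome: ", chrom)
  if (arm == "p") c(start = 1, end = row$centromere)
  else if (arm == "q") c(start = row$centromere + 1, end = row$length)
  else stop("arm must be 'p' or 'q'")
}

# which arms does [start, end] overlap on chrom -> subset of c("p","q")
arms_overlapped <- function(genome, chrom, start, end) {
  row <- genome[genome$chrom == chrom, ]
  if (nrow(row) != 1) stop("unknown chromosome: ", chrom)
  if (start < 1 || end > row$length || start > end)
    stop("segment ", start, "-", end, " outside chromosome ", chrom)
  out <- character()
  if (start <= row$centromere) out <- c(out, "p")
  if (end > row$centromere) out <- c(out, "q")
  out
}

# resolve a band query like "p12.2" or "q21" (prefix over sub-bands) to bp range
band_range <- function(cytobands, chrom, band) {
  hits <- cytobands[cytobands$chrom == chrom &
                      (cytobands$band == band |
                         startsWith(cytobands$band, paste0(band, "."))), ]
  if (!nrow(hits)) stop("unknown band '", band, "' on chromosome ", chrom)
  c(start = min(hits$start), end = max(hits$end))
}
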