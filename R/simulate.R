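# Biopsy simulator: cell mixtures, shared MDA amplification bias, and the
# two platform renderers fed from the same amplified product.

#' Construct a cell karyotype
#'
#' A single cell line: non-mosaic copy-number events on a disomic baseline
#' (copy number 2 everywhere else), with an integer copy number per event
#' (1 for loss, 3 for gain by default).
#'
#' @param events Events tibble (see [cn_event()]); must be non-mosaic and
#'   non-overlapping within a chromosome.
#' @param copy_number Optional integer vector of per-event copy numbers;
#'   defaults to 1 for losses and 3 for gains.
#' @param genome Genome model tibble.
#' @return A tibble with columns `chrom`, `scope`, `start`, `end`, `cn`.
#' @export
cell_karyotype <- function(events = empty_events(), copy_number = NULL,
                           genome = genome_model()) {
  if (nrow(events) && any(events$mosaic))
    stop("a single cell line cannot carry mosaic events")
  cn <- if (is.null(copy_number)) {
    ifelse(events$direction == "gain", 3L, 1L)
  } else {
    if (length(copy_number) != nrow(events))
      stop("copy_number must match the number of events")
    copy_number
  }
  if (any(cn < 0)) stop("copy numbers must be >= 0")
  k <- tibble::tibble(chrom = events$chrom, scope = events$scope,
                      start = events$start, end = events$end, cn = cn)
  # resolve arm scopes to bp so overlap checks and rendering are uniform
  if (nrow(k)) {
    for (i in seq_len(nrow(k))) {
      if (k$scope[i] %in% c("p", "q")) {
        b <- arm_bounds(genome, k$chrom[i], k$scope[i])
        k$start[i] <- b[["start"]]; k$end[i] <- b[["end"]]
      } else if (k$scope[i] == "whole") {
        k$start[i] <- 1
        k$end[i] <- genome$length[genome$chrom == k$chrom[i]]
      }
    }
    by_chr <- split(k, k$chrom)
    for (part in by_chr) {
      part <- part[order(part$start), ]
      if (nrow(part) > 1 && any(part$start[-1] <= part$end[-nrow(part)]))
        stop("overlapping events on chromosome ", part$chrom[1])
    }
  }
  k
}

#' Assemble a biopsy ground truth from components and exact fractions
#'
#' The analytic mixture: a list of cell lines with population fractions that
#' sum to 1, plus the biopsy cell count. Use [make_biopsy()] for the
#' sampled (binomially quantized) version.
#'
#' @param karyotypes List of [cell_karyotype()] tibbles.
#' @param fractions Numeric vector of the same length, summing to 1.
#' @param n_cells Number of trophectoderm cells in the biopsy (5-10).
#' @return An object of class `biopsy_truth`.
#' @export
biopsy_truth <- function(karyotypes, fractions, n_cells = 5L) {
  if (length(karyotypes) != length(fractions))
    stop("karyotypes and fractions must have equal length")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1")
  if (n_cells < 1) stop("n_cells must be positive")
  structure(list(components = tibble::tibble(karyotype = karyotypes,
                                             fraction = fractions),
                 n_cells = as.integer(n_cells)),
            class = "biopsy_truth")
}

#' @export
print.biopsy_truth <- function(x, ...) {
  cat("<biopsy_truth> ", nrow(x$components), " cell line(s), ",
      x$n_cells, " cells\n", sep = "")
  for (i in seq_len(nrow(x$components))) {
    k <- x$components$karyotype[[i]]
    lab <- if (!nrow(k)) "disomic" else
      paste(paste0(k$chrom, ifelse(k$scope %in% c("p", "q"), k$scope, ""),
                   " CN", k$cn), collapse = ", ")
    cat(sprintf("  %5.1f%%  %s\n", 100 * x$components$fraction[i], lab))
  }
  invisible(x)
}

#' Draw a biopsy: binomial quantization of the mosaic fraction
#'
#' Samples the realized cell composition of a 5-10-cell trophectoderm biopsy
#' from a two-line mixture: the number of abnormal cells is
#' `Binomial(n_cells, fraction)`, so small biopsies quantize the mosaic
#' fraction (with 5 cells, realized fractions are multiples of 0.2).
#'
#' @param event One-row events tibble (or notation string) describing the
#'   abnormal line's event.
#' @param fraction Population fraction of the abnormal line, in `[0, 1]`.
#' @param n_cells Biopsy cell count (default 5).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param genome Genome model tibble.
#' @return A `biopsy_truth` whose component fractions are the realized
#'   cell proportions.
#' @examples
#' make_biopsy("+21", fraction = 0.4, n_cells = 10, seed = 1)
#' @export
make_biopsy <- function(event, fraction, n_cells = 5L, seed,
                        genome = genome_model()) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (is.character(event)) event <- parse_mosaic_notation(event, genome)
  abn <- cell_karyotype(event, genome = genome)
  k_abn <- local_rng(seed, stats::rbinom(1, n_cells, fraction))
  dis <- cell_karyotype(genome = genome)
  if (k_abn == 0) biopsy_truth(list(dis), 1, n_cells)
  else if (k_abn == n_cells) biopsy_truth(list(abn), 1, n_cells)
  else biopsy_truth(list(dis, abn),
                    c(1 - k_abn / n_cells, k_abn / n_cells), n_cells)
}

# copy number of one karyotype averaged over [start, end] on chrom
karyotype_cn_region <- function(k, chrom, start, end) {
  cn <- 2
  rows <- k[k$chrom == chrom, , drop = FALSE]
  if (!nrow(rows)) return(cn)
  len <- end - start + 1
  for (i in seq_len(nrow(rows))) {
    ov <- min(end, rows$end[i]) - max(start, rows$start[i]) + 1
    if (ov > 0) cn <- cn + (rows$cn[i] - 2) * ov / len
  }
  cn
}

#' Mixture-expected copy number over a region
#'
#' The analytic oracle for intermediate copy number: the fraction-weighted
#' mean copy number of the mixture over a region,
#' `sum(fraction_i * cn_i)`. This is what depth-based platforms measure, and
#' why complementary mixtures (40% monosomy + 60% trisomy vs 80% disomy +
#' 20% trisomy, both mean 2.2) are indistinguishable.
#'
#' @param truth A `biopsy_truth`.
#' @param chrom Chromosome name.
#' @param scope `"whole"`, `"p"`, `"q"`, or `"segment"`.
#' @param start,end Segment bounds when `scope == "segment"`.
#' @param genome Genome model tibble.
#' @return A single numeric copy number (disomy = 2).
#' @examples
#' tri21 <- cell_karyotype(parse_mosaic_notation("+21"))
#' mono21 <- cell_karyotype(parse_mosaic_notation("-21"))
#' dis <- cell_karyotype()
#' expected_copy_number(biopsy_truth(list(mono21, tri21), c(0.4, 0.6)), "21")
#' @export
expected_copy_number <- function(truth, chrom, scope = "whole",
                                 start = NULL, end = NULL,
                                 genome = genome_model()) {
  stopifnot(inherits(truth, "biopsy_truth"))
  if (scope == "whole") {
    start <- 1; end <- genome$length[genome$chrom == chrom]
  } else if (scope %in% c("p", "q")) {
    b <- arm_bounds(genome, chrom, scope); start <- b[["start"]]; end <- b[["end"]]
  } else if (is.null(start) || is.null(end)) {
    stop("segment scope requires start and end")
  }
  sum(truth$components$fraction *
        vapply(truth$components$karyotype, karyotype_cn_region, 0,
               chrom = chrom, start = start, end = end))
}

# run expr with a local, seeded RNG without touching the global stream
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a shared MDA amplification-bias layer
#'
#' Multiple displacement amplification (MDA) over- and under-amplifies loci;
#' because both assays consume aliquots of the same MDA product, one weight
#' layer feeds both renderers. Weights are log-normal per genomic tile and
#' mean-normalized to 1.
#'
#' @param genome Genome model tibble.
#' @param tile_kb Tile size in kb (default 100, the MDA amplicon scale).
#' @param sigma_log Standard deviation of log2 weights (0 gives weights
#'   identically 1), so a tile's LogR contribution has SD `sigma_log`
#'   directly.
#' @param seed Integer seed.
#' @return A tibble (`chrom`, `start`, `end`, `weight`) with attribute
#'   `tile_bp`.
#' @export
simulate_mda <- function(genome = genome_model(), tile_kb = 100,
                         sigma_log = 0.2, seed = 1L) {
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  tile_bp <- tile_kb * 1000
  tiles <- dplyr::bind_rows(purrr::map(seq_len(nrow(genome)), function(i) {
    n <- ceiling(genome$length[i] / tile_bp)
    s <- (seq_len(n) - 1) * tile_bp + 1
    tibble::tibble(chrom = genome$chrom[i], start = s,
                   end = pmin(s + tile_bp - 1, genome$length[i]))
  }))
  w <- local_rng(seed, 2^(stats::rnorm(nrow(tiles), 0, sigma_log)))
  tiles$weight <- w / mean(w)
  attr(tiles, "tile_bp") <- tile_bp
  tiles
}

# weight lookup for positions on one chromosome (weights from simulate_mda)
weights_at <- function(weights, chrom, pos) {
  tile_bp <- attr(weights, "tile_bp")
  wc <- weights$weight[weights$chrom == chrom]
  idx <- pmin(((pos - 1) %/% tile_bp) + 1, length(wc))
  wc[idx]
}

#' Render the SNP-array signal of a biopsy
#'
#' Produces the per-marker LogR / BAF table an SNP array reports for the
#' amplified biopsy. Markers are laid evenly across the genome; per marker
#' the mixture-average total copies `c` and B-allele copies `b` follow the
#' allele-copy arithmetic of the mixture (a gained/lost homologue is chosen
#' at random per marker), then `LogR = log2((c/2) * weight) + N(0,
#' sigma_lrr)` and `BAF = b/c + N(0, sigma_baf)` truncated to `[0, 1]`.
#'
#' @param truth A `biopsy_truth`.
#' @param weights MDA weight layer from [simulate_mda()].
#' @param n_markers Total marker count (default 300000, a ~300k SNP chip).
#' @param sigma_lrr,sigma_baf Gaussian noise SDs for LogR and BAF.
#' @param het_prob Probability a marker is heterozygous in the embryo.
#' @param nocall_prob Probability a marker fails to genotype.
#' @param genome Genome model tibble.
#' @param seed Integer seed.
#' @return A `snp_signal`: tibble (`chrom`, `pos`, `logr`, `baf`, `called`)
#'   with simulation parameters in `attr(, "meta")`.
#' @export
render_snp <- function(truth, weights, n_markers = 300000,
                       sigma_lrr = 0.15, sigma_baf = 0.03,
                       het_prob = 0.3, nocall_prob = 0.01,
                       genome = genome_model(), seed = 1L) {
  stopifnot(inherits(truth, "biopsy_truth"))
  per_chr <- pmax(1, round(n_markers * genome$length / sum(genome$length)))
  sig <- local_rng(seed, {
    dplyr::bind_rows(purrr::map(seq_len(nrow(genome)), function(i) {
      chrom <- genome$chrom[i]; n <- per_chr[i]
      pos <- round(seq(1, genome$length[i], length.out = n))
      w <- weights_at(weights, chrom, pos)
      geno <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
                     prob = c((1 - het_prob) / 2, het_prob, (1 - het_prob) / 2))
      b_base <- c(AA = 0, AB = 1, BB = 2)[geno]  # B copies per disomic cell
      # which homologue the abnormal copy-number change hits, per marker
      hit_b <- stats::runif(n) < b_base / 2
      cmean <- numeric(n); bmean <- numeric(n)
      for (j in seq_len(nrow(truth$components))) {
        f <- truth$components$fraction[j]
        k <- truth$components$karyotype[[j]]
        cn <- rep(2, n)
        rows <- k[k$chrom == chrom, , drop = FALSE]
        if (nrow(rows)) for (r in seq_len(nrow(rows)))
          cn[pos >= rows$start[r] & pos <= rows$end[r]] <- rows$cn[r]
        # B copies in this line: changed homologue carries the dosage change
        bcn <- ifelse(cn == 2, b_base,
                      ifelse(hit_b, pmax(b_base + (cn - 2), 0),
                             pmin(b_base, cn)))
        bcn <- pmin(bcn, cn)
        cmean <- cmean + f * cn
        bmean <- bmean + f * bcn
      }
      logr <- log2(pmax(cmean, 0.05) / 2 * w) +
        stats::rnorm(n, 0, sigma_lrr)
      baf0 <- ifelse(cmean > 0, bmean / pmax(cmean, 1e-12), stats::runif(n))
      baf <- pmin(pmax(baf0 + stats::rnorm(n, 0, sigma_baf), 0), 1)
      tibble::tibble(chrom = chrom, pos = pos, logr = logr, baf = baf,
                     called = stats::runif(n) >= nocall_prob)
    }))
  })
  attr(sig, "meta") <- list(platform = "SNP", n_markers = n_markers,
                            sigma_lrr = sigma_lrr, sigma_baf = sigma_baf,
                            het_prob = het_prob, nocall_prob = nocall_prob,
                            seed = seed)
  class(sig) <- c("snp_signal", class(sig))
  sig
}

#' Render the low-pass NGS signal of a biopsy
#'
#' Produces the per-bin GC and read-count table of a low-pass sequencing run
#' on the amplified biopsy. The expected count of a bin is proportional to
#' `bin_width * (cn/2) * mda_weight * gc_curve(gc)`, normalized so expected
#' counts sum to `total_reads`; counts are negative-binomial with
#' `var = mu * (1 + overdispersion)` (Poisson at 0; `exact = TRUE` returns
#' the expectations themselves, the noiseless limit).
#'
#' @param truth A `biopsy_truth`.
#' @param weights MDA weight layer from [simulate_mda()].
#' @param bin_kb Bin width in kb (default 1000, so the 4 Mb segmental floor
#'   spans at least 4 bins).
#' @param total_reads Expected total mapped reads (default 750000; runs
#'   must deliver at least the 700000-read QC floor, so the simulator
#'   targets a realistic margin above it).
#' @param gc_coeffs Length-2 coefficients of the log-linear/quadratic GC
#'   bias curve around GC = 0.42.
#' @param overdispersion Negative-binomial overdispersion; 0 means Poisson.
#' @param exact If `TRUE`, counts equal their expectations (no sampling).
#' @param genome Genome model tibble.
#' @param seed Integer seed.
#' @return An `ngs_signal`: tibble (`chrom`, `start`, `end`, `gc_fraction`,
#'   `read_count`) with run metadata (`total_reads`, `read_length`,
#'   `map_ratio`, `duplicate_rate`, `gc_content`) in `attr(, "meta")`.
#' @export
render_ngs <- function(truth, weights, bin_kb = 1000, total_reads = 750000,
                       gc_coeffs = c(1, -10), overdispersion = 0.1,
                       exact = FALSE, genome = genome_model(), seed = 1L) {
  stopifnot(inherits(truth, "biopsy_truth"))
  if (total_reads <= 0) stop("total_reads must be positive")
  bin_bp <- bin_kb * 1000
  bins <- dplyr::bind_rows(purrr::map(seq_len(nrow(genome)), function(i) {
    n <- ceiling(genome$length[i] / bin_bp)
    s <- (seq_len(n) - 1) * bin_bp + 1
    tibble::tibble(chrom = genome$chrom[i], start = s,
                   end = pmin(s + bin_bp - 1, genome$length[i]))
  }))
  sig <- local_rng(seed, {
    gc <- pmin(pmax(stats::rnorm(nrow(bins), 0.42, 0.03), 0.30), 0.60)
    tile_bp <- attr(weights, "tile_bp")
    w <- numeric(nrow(bins))
    cn <- rep(2, nrow(bins))
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      # average MDA tile weights across each bin (tiles may be larger or
      # smaller than bins)
      wt <- weights$weight[weights$chrom == ch]
      t1 <- pmin((bins$start[idx] - 1) %/% tile_bp + 1, length(wt))
      t2 <- pmin((bins$end[idx] - 1) %/% tile_bp + 1, length(wt))
      cw <- c(0, cumsum(wt))
      w[idx] <- (cw[t2 + 1] - cw[t1]) / (t2 - t1 + 1)
      # mixture-mean copy number per bin, by event-overlap arithmetic
      cnb <- rep(0, length(idx))
      for (j in seq_len(nrow(truth$components))) {
        f <- truth$components$fraction[j]
        k <- truth$components$karyotype[[j]]
        cnj <- rep(2, length(idx))
        rows <- k[k$chrom == ch, , drop = FALSE]
        if (nrow(rows)) for (r in seq_len(nrow(rows))) {
          ov <- pmax(0, pmin(bins$end[idx], rows$end[r]) -
                       pmax(bins$start[idx], rows$start[r]) + 1)
          cnj <- cnj + (rows$cn[r] - 2) * ov / (bins$end[idx] - bins$start[idx] + 1)
        }
        cnb <- cnb + f * cnj
      }
      cn[idx] <- cnb
    }
    gc_curve <- exp(gc_coeffs[1] * (gc - 0.42) + gc_coeffs[2] * (gc - 0.42)^2)
    lambda <- (bins$end - bins$start + 1) * (cn / 2) * w * gc_curve
    lambda <- lambda / sum(lambda) * total_reads
    counts <- if (exact) lambda
      else if (overdispersion <= 0) stats::rpois(nrow(bins), lambda)
      else stats::rnbinom(nrow(bins), mu = lambda,
                          size = pmax(lambda, 1e-9) / overdispersion)
    out <- bins
    out$gc_fraction <- gc
    out$read_count <- counts
    attr(out, "meta") <- list(
      platform = "NGS",
      total_reads = if (exact) total_reads else sum(counts),
      read_length = 36,
      map_ratio = min(max(stats::rnorm(1, 95, 1.5), 50), 100),
      duplicate_rate = min(max(stats::rnorm(1, 12, 2), 0), 100),
      gc_content = 100 * stats::weighted.mean(gc, counts + 1e-9),
      bin_kb = bin_kb, overdispersion = overdispersion, seed = seed)
    out
  })
  class(sig) <- c("ngs_signal", class(sig))
  sig
}
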