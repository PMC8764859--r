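# NGS platform: QC, GC normalization, CNV segmentation and the interval
# classification of CNV values with mosaic levels.

#' NGS run quality control
#'
#' Gathers the run metrics (total reads, Map_Ratio, Duplicate, GC_Content)
#' and computes SD, the bin-level noise statistic: the standard deviation of
#' the per-bin copy-number estimates (2 x GC-normalized ratio) over autosomal
#' bins. The run passes when total reads >= 700,000, Map_Ratio >= 80%,
#' GC_Content within 39-45%, and SD < 3.5 (the resolution gate for 4 Mb
#' segmental and whole-chromosome detection).
#'
#' @param signal An `ngs_signal` tibble (see [render_ngs()]).
#' @param sd_threshold SD gate (default 3.5; the vendor scale is opaque, so
#'   the gate is configurable).
#' @return A one-row tibble: `total_reads`, `map_ratio`, `duplicate_rate`,
#'   `gc_content`, `sd`, `pass`.
#' @export
ngs_qc <- function(signal, sd_threshold = 3.5) {
  if (!nrow(signal)) stop("empty NGS signal")
  meta <- attr(signal, "meta")
  if (is.null(meta)) meta <- list()
  norm <- gc_normalize(signal)
  auto <- norm$ratio[norm$chrom %in% as.character(1:22)]
  sdv <- stats::sd(2 * auto)
  total <- meta$total_reads %||% sum(signal$read_count)
  mr <- meta$map_ratio %||% NA_real_
  dup <- meta$duplicate_rate %||% NA_real_
  gc <- meta$gc_content %||% (100 * mean(signal$gc_fraction))
  tibble::tibble(
    total_reads = total, map_ratio = mr, duplicate_rate = dup,
    gc_content = gc, sd = sdv,
    pass = total >= 700000 & (is.na(mr) | mr >= 80) &
      gc >= 39 & gc <= 45 & sdv < sd_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GC-bias normalization of binned counts
#'
#' Works on per-bp coverage rates (count / bin width, so partial bins at
#' chromosome ends are comparable): each bin's rate is divided by the
#' median rate of its GC decile (deciles over autosomal bins), then
#' rescaled so the autosomal median ratio is 1. A decile with no bins falls
#' back to the global autosomal median. Deterministic.
#'
#' @param signal An `ngs_signal` with at least 20 autosomal bins.
#' @return The input tibble with a `ratio` column appended (disomy ~ 1).
#' @export
gc_normalize <- function(signal) {
  auto <- signal$chrom %in% as.character(1:22)
  if (sum(auto) < 20) stop("need at least 20 autosomal bins")
  rate <- signal$read_count / (signal$end - signal$start + 1)
  br <- stats::quantile(signal$gc_fraction[auto], probs = seq(0, 1, 0.1),
                        names = FALSE)
  br[1] <- -Inf; br[length(br)] <- Inf
  dec <- cut(signal$gc_fraction, breaks = unique(br), include.lowest = TRUE)
  glob <- stats::median(rate[auto])
  med <- tapply(rate[auto], dec[auto], stats::median)
  med[is.na(med) | med == 0] <- glob
  denom <- med[as.character(dec)]
  denom[is.na(denom)] <- glob
  out <- signal
  out$ratio <- rate / as.numeric(denom)
  out$ratio <- out$ratio / stats::median(out$ratio[auto])
  out
}

#' Segment GC-normalized bins into copy-number segments
#'
#' Per-arm binary segmentation of the per-bin copy-number estimates
#' (2 x ratio); segments shorter than the resolution floor (4 Mb) are merged
#' into their nearest neighbor. An arm covered by one segment is promoted to
#' arm scope; when the two arms of a chromosome carry similar CNV values
#' they promote to a single whole-chromosome segment. The CNV value of a
#' segment is twice the median ratio of its bins.
#'
#' @param norm Output of [gc_normalize()].
#' @param genome Genome model tibble.
#' @param min_seg_mb Segmental resolution floor in Mb (default 4).
#' @param merge_cnv Maximum CNV difference between arms for whole-chromosome
#'   promotion (default 0.3).
#' @param penalty Changepoint acceptance penalty (multiplies the BIC term;
#'   larger is more conservative).
#' @return A tibble of segments: `chrom`, `start`, `end`, `scope`,
#'   `cnv_value`, `n_bins`.
#' @export
segment_cnv <- function(norm, genome = genome_model(), min_seg_mb = 4,
                        merge_cnv = 0.3, penalty = 4) {
  bin_bp <- stats::median(norm$end - norm$start + 1)
  min_bins <- max(2L, ceiling(min_seg_mb * 1e6 / bin_bp))
  arm_segs <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    for (arm in c("p", "q")) {
      b <- arm_bounds(genome, chrom, arm)
      sub <- norm[norm$chrom == chrom & norm$start >= b[["start"]] &
                    norm$start <= b[["end"]], ]
      if (!nrow(sub)) next
      sub <- sub[order(sub$start), ]
      y <- 2 * sub$ratio
      brk <- binseg(y, min_width = min_bins, penalty = penalty)
      segs <- seg_table(nrow(sub), brk)
      # refine boundaries: hand edge bins to the neighbor whose mean they
      # are strictly closer to, so sub-floor events cannot borrow a
      # neighbor's bin to reach the 4 Mb resolution floor
      if (nrow(segs) > 1) {
        smean <- function(j) mean(y[segs$from[j]:segs$to[j]])
        for (j in seq_len(nrow(segs) - 1L)) {
          repeat {
            if (segs$to[j] <= segs$from[j]) break
            edge <- y[segs$to[j]]
            if (abs(edge - smean(j + 1L)) < abs(edge - smean(j))) {
              segs$to[j] <- segs$to[j] - 1L
              segs$from[j + 1L] <- segs$from[j + 1L] - 1L
            } else break
          }
          repeat {
            if (segs$from[j + 1L] >= segs$to[j + 1L]) break
            edge <- y[segs$from[j + 1L]]
            if (abs(edge - smean(j)) < abs(edge - smean(j + 1L))) {
              segs$from[j + 1L] <- segs$from[j + 1L] + 1L
              segs$to[j] <- segs$to[j] + 1L
            } else break
          }
        }
      }
      # merge short segments into the neighbor with the closer mean
      repeat {
        lens <- segs$to - segs$from + 1L
        if (nrow(segs) <= 1 || all(lens >= min_bins)) break
        j <- which.min(lens)
        target <- if (j == 1) 2L
          else if (j == nrow(segs)) j - 1L
          else {
            mj <- mean(y[segs$from[j]:segs$to[j]])
            ml <- mean(y[segs$from[j - 1]:segs$to[j - 1]])
            mr <- mean(y[segs$from[j + 1]:segs$to[j + 1]])
            if (abs(mj - ml) <= abs(mj - mr)) j - 1L else j + 1L
          }
        lo <- min(j, target); hi <- max(j, target)
        segs$to[lo] <- segs$to[hi]
        segs <- segs[-hi, ]
      }
      for (s in seq_len(nrow(segs))) {
        rows <- sub[segs$from[s]:segs$to[s], ]
        arm_segs[[length(arm_segs) + 1L]] <- tibble::tibble(
          chrom = chrom, arm = arm,
          start = min(rows$start), end = max(rows$end),
          scope = if (nrow(segs) == 1) arm else "segment",
          cnv_value = 2 * stats::median(rows$ratio), n_bins = nrow(rows))
      }
    }
  }
  segs <- dplyr::bind_rows(arm_segs)
  if (!nrow(segs))
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), scope = character(),
                          cnv_value = double(), n_bins = integer()))
  # whole-chromosome promotion
  out <- list()
  for (chrom in unique(segs$chrom)) {
    sc <- segs[segs$chrom == chrom, ]
    p1 <- sc[sc$scope == "p", ]; q1 <- sc[sc$scope == "q", ]
    if (nrow(p1) == 1 && nrow(q1) == 1 &&
        abs(p1$cnv_value - q1$cnv_value) <= merge_cnv) {
      w <- c(p1$n_bins, q1$n_bins)
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = p1$start, end = q1$end, scope = "whole",
        cnv_value = stats::weighted.mean(c(p1$cnv_value, q1$cnv_value), w),
        n_bins = sum(w))
      sc <- sc[sc$scope == "segment", ]
    }
    if (nrow(sc)) out[[length(out) + 1L]] <- sc
  }
  res <- dplyr::bind_rows(out)
  res$arm <- NULL
  res[order(match(res$chrom, genome$chrom), res$start),
      c("chrom", "start", "end", "scope", "cnv_value", "n_bins")]
}

#' Classify a CNV value into a ploidy class
#'
#' The interval rule on the copy-number scale (disomy = 2): CNV in
#' `[1.20, 1.80]` is mosaic loss, `(1.80, 2.20)` euploid, `[2.20, 2.80]`
#' mosaic gain, below 1.20 pure aneuploid loss, above 2.80 pure aneuploid
#' gain. The shared endpoints 1.80/2.20 belong to the mosaic classes: a mean
#' copy number of 2.2 is 20% mosaicism, not euploidy. Mosaic calls carry
#' `level_percent = round(|CNV - 2| * 100)`.
#'
#' @param cnv_value Non-negative CNV value.
#' @return A one-row tibble: `class` (`"euploid"`, `"mosaic"`,
#'   `"aneuploid"`), `direction` (`"gain"`, `"loss"` or `NA`),
#'   `level_percent` (`NA` unless mosaic).
#' @examples
#' classify_cnv(2.2)  # mosaic gain, level 20
#' classify_cnv(1.5)  # mosaic loss, level 50
#' @export
classify_cnv <- function(cnv_value) {
  if (is.na(cnv_value) || cnv_value < 0) stop("cnv_value must be >= 0")
  # interval endpoints are decision values; guard against float jitter
  cnv_value <- round(cnv_value, 9)
  if (cnv_value < 1.20)
    tibble::tibble(class = "aneuploid", direction = "loss",
                   level_percent = NA_real_)
  else if (cnv_value <= 1.80)
    tibble::tibble(class = "mosaic", direction = "loss",
                   level_percent = round(abs(cnv_value - 2) * 100))
  else if (cnv_value < 2.20)
    tibble::tibble(class = "euploid", direction = NA_character_,
                   level_percent = NA_real_)
  else if (cnv_value <= 2.80)
    tibble::tibble(class = "mosaic", direction = "gain",
                   level_percent = round(abs(cnv_value - 2) * 100))
  else
    tibble::tibble(class = "aneuploid", direction = "gain",
                   level_percent = NA_real_)
}

#' Call ploidy from a low-pass NGS signal
#'
#' The full NGS route: QC, GC normalization, per-arm segmentation with the
#' 4 Mb resolution floor, and interval classification of segment CNV values.
#' Mosaic events carry their level percentage and CNV value.
#'
#' @param signal An `ngs_signal`.
#' @param genome Genome model tibble.
#' @param min_seg_mb Segmental resolution floor in Mb (default 4).
#' @param sd_threshold QC SD gate (default 3.5).
#' @param penalty Changepoint acceptance penalty (see [segment_cnv()]).
#' @param embryo_id Optional identifier.
#' @return A `platform_diagnosis` (platform `"NGS"`) with the segment table
#'   in `$segments`; QC failure flags the diagnosis with a warning.
#' @export
call_ngs <- function(signal, genome = genome_model(), min_seg_mb = 4,
                     sd_threshold = 3.5, penalty = 4,
                     embryo_id = NA_character_) {
  qc <- ngs_qc(signal, sd_threshold = sd_threshold)
  if (!qc$pass)
    warning("NGS QC failed; diagnosis is unreliable")
  norm <- gc_normalize(signal)
  segs <- segment_cnv(norm, genome, min_seg_mb = min_seg_mb,
                      penalty = penalty)
  events <- empty_events()
  for (i in seq_len(nrow(segs))) {
    cls <- classify_cnv(segs$cnv_value[i])
    if (cls$class == "euploid") next
    ev <- cn_event(segs$chrom[i], segs$scope[i], cls$direction,
                   mosaic = cls$class == "mosaic",
                   start = if (segs$scope[i] == "segment") segs$start[i] else NA_real_,
                   end = if (segs$scope[i] == "segment") segs$end[i] else NA_real_,
                   level_percent = cls$level_percent,
                   cnv_value = segs$cnv_value[i], genome = genome)
    events <- dplyr::bind_rows(events, ev)
  }
  d <- platform_diagnosis("NGS", events, qc = qc, embryo_id = embryo_id)
  d$segments <- segs
  d
}
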