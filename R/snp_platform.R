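# SNP-array platform: QC and per-arm ploidy calling from LogR/BAF.

#' SNP-array data quality control
#'
#' Computes the chip-level QC metrics: the median LogR deviation (median over
#' autosomal markers of the absolute deviation from the autosomal median
#' LogR) and the median call rate (fraction of markers genotyped). Good data
#' requires median LogR deviation < 0.2 and call rate > 0.98.
#'
#' @param signal A `snp_signal` tibble (see [render_snp()]).
#' @return A one-row tibble: `median_logr_deviation`, `median_call_rate`,
#'   `pass`.
#' @export
snp_qc <- function(signal) {
  if (!nrow(signal)) stop("empty SNP signal")
  auto <- signal[signal$chrom %in% as.character(1:22), ]
  med <- stats::median(auto$logr)
  dev <- stats::median(abs(auto$logr - med))
  rate <- mean(signal$called)
  tibble::tibble(median_logr_deviation = dev, median_call_rate = rate,
                 pass = dev < 0.2 & rate > 0.98)
}

# scatter statistic: fraction of het-pattern markers (called, BAF in
# [0.15, 0.85]) deviating from 0.5 by more than tau_baf; 1 when the 0.5
# band has vanished entirely (no het-pattern markers at all).
baf_scatter_stat <- function(baf, called, tau_baf) {
  hp <- called & baf >= 0.15 & baf <= 0.85
  if (!sum(hp)) return(1)
  mean(abs(baf[hp] - 0.5) > tau_baf)
}

#' Per-arm summaries of an SNP signal
#'
#' One row per chromosome arm with at least `min_markers` markers: the
#' median LogR and the BAF scatter statistic (fraction of heterozygous-
#' pattern markers with `|BAF - 0.5| > tau_baf`; "not concentrated at 0.5"
#' when this exceeds the caller's scatter threshold).
#'
#' @param signal A `snp_signal`.
#' @param genome Genome model tibble.
#' @param tau_baf BAF deviation tolerance (default 0.1).
#' @param min_markers Minimum markers per reported arm (default 20).
#' @return A tibble: `chrom`, `arm`, `median_logr`, `baf_scatter`,
#'   `n_markers`.
#' @export
summarize_arms <- function(signal, genome = genome_model(), tau_baf = 0.1,
                           min_markers = 20L) {
  dplyr::bind_rows(purrr::map(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    purrr::map_dfr(c("p", "q"), function(arm) {
      b <- arm_bounds(genome, chrom, arm)
      sub <- signal[signal$chrom == chrom & signal$pos >= b[["start"]] &
                      signal$pos <= b[["end"]] & signal$called, ]
      if (nrow(sub) < min_markers) return(NULL)
      tibble::tibble(chrom = chrom, arm = arm,
                     median_logr = stats::median(sub$logr),
                     baf_scatter = baf_scatter_stat(sub$baf, sub$called,
                                                    tau_baf),
                     n_markers = nrow(sub))
    })
  }))
}

# classify one (median_logr, scatter) pair under the SNP criteria;
# returns NULL (no event), or list(direction, mosaic)
snp_classify <- function(median_logr, scatter, theta_scatter, logr_full_gain,
                         logr_full_loss) {
  if (scatter <= theta_scatter) return(NULL)
  if (median_logr >= logr_full_gain) list(direction = "gain", mosaic = FALSE)
  else if (median_logr <= logr_full_loss) list(direction = "loss", mosaic = FALSE)
  else if (median_logr > 0.2) list(direction = "gain", mosaic = TRUE)
  else if (median_logr < -0.2) list(direction = "loss", mosaic = TRUE)
  else NULL
}

#' Call ploidy from an SNP-array signal
#'
#' Applies the SNP-array criteria per chromosome arm: mosaicism is called
#' when the BAF scatter of heterozygous loci is not concentrated at 0.5 and
#' the arm's median LogR exceeds 0.2 in magnitude; dosage beyond the
#' full-aneuploidy bounds (copy number within 10% of 1 or 3 by default)
#' is called non-mosaic aneuploidy. Within-arm segmental events are found by
#' a changepoint scan on marker LogR with a minimum span of `min_seg_mb`.
#' Both arms mosaic in the same direction with similar dosage merge into one
#' whole-chromosome event. The mosaic level is never reported: an SNP array
#' cannot measure it.
#'
#' @param signal A `snp_signal`.
#' @param genome Genome model tibble.
#' @param tau_baf,theta_scatter BAF scatter statistic tolerance and
#'   threshold (defaults 0.1 and 0.5).
#' @param logr_mosaic Mosaic LogR threshold (default 0.2).
#' @param cn_full_lo,cn_full_hi Copy-number bounds for non-mosaic calls
#'   (defaults 0.55 and 1.45 on the CN/2 ratio scale, i.e. LogR
#'   `log2(0.55)` / `log2(1.45)`).
#' @param min_seg_mb Minimum segmental span in Mb (default 10; arrays
#'   resolve coarser segments than sequencing).
#' @param min_markers Minimum markers per analyzed arm.
#' @param merge_logr Maximum arm-median LogR difference for whole-chromosome
#'   merging (default 0.15).
#' @param embryo_id Optional identifier.
#' @return A `platform_diagnosis` (platform `"SNP"`); if QC fails, the
#'   diagnosis carries `qc$pass = FALSE` and a warning is emitted.
#' @export
call_snp <- function(signal, genome = genome_model(), tau_baf = 0.1,
                     theta_scatter = 0.5, logr_mosaic = 0.2,
                     cn_full_lo = 0.55, cn_full_hi = 1.45,
                     min_seg_mb = 10, min_markers = 20L,
                     merge_logr = 0.15, embryo_id = NA_character_) {
  qc <- snp_qc(signal)
  if (!qc$pass)
    warning("SNP QC failed; diagnosis is unreliable")
  lg_gain <- log2(cn_full_hi); lg_loss <- log2(cn_full_lo)

  arm_events <- list(); seg_events <- list()
  arm_calls <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    for (arm in c("p", "q")) {
      b <- arm_bounds(genome, chrom, arm)
      sub <- signal[signal$chrom == chrom & signal$pos >= b[["start"]] &
                      signal$pos <= b[["end"]] & signal$called, ]
      if (nrow(sub) < min_markers) next
      sub <- sub[order(sub$pos), ]
      # changepoint scan: minimum width in markers from the arm's density;
      # marker noise is correlated within WGA tiles, so a stiff penalty
      mb_per_marker <- (b[["end"]] - b[["start"]] + 1) / 1e6 / nrow(sub)
      min_w <- max(10L, ceiling(min_seg_mb / mb_per_marker))
      brk <- binseg(sub$logr, min_width = min_w, penalty = 6)
      segs <- seg_table(nrow(sub), brk)
      seg_cls <- lapply(seq_len(nrow(segs)), function(s) {
        rows <- sub[segs$from[s]:segs$to[s], ]
        snp_classify(stats::median(rows$logr),
                     baf_scatter_stat(rows$baf, rows$called, tau_baf),
                     theta_scatter, lg_gain, lg_loss)
      })
      # heal adjacent segments with the same classification
      s <- 1L
      while (s < nrow(segs)) {
        if (identical(seg_cls[[s]], seg_cls[[s + 1L]])) {
          segs$to[s] <- segs$to[s + 1L]
          segs <- segs[-(s + 1L), ]
          seg_cls[[s + 1L]] <- NULL
        } else s <- s + 1L
      }
      for (s in seq_len(nrow(segs))) {
        rows <- sub[segs$from[s]:segs$to[s], ]
        cls <- seg_cls[[s]]
        covers_arm <- nrow(rows) >= 0.95 * nrow(sub)
        if (covers_arm) {
          arm_calls[[paste0(chrom, arm)]] <-
            list(chrom = chrom, arm = arm,
                 median_logr = stats::median(rows$logr), cls = cls)
        } else if (!is.null(cls)) {
          seg_events[[length(seg_events) + 1L]] <-
            cn_event(chrom, "segment", cls$direction, mosaic = cls$mosaic,
                     start = min(rows$pos), end = max(rows$pos),
                     genome = genome)
        }
      }
    }
  }
  # arm-level events, merging both arms into a whole-chromosome call when
  # direction/mosaic agree and dosage is similar
  done <- character()
  for (key in names(arm_calls)) {
    ac <- arm_calls[[key]]
    if (is.null(ac$cls) || key %in% done) next
    other_key <- paste0(ac$chrom, setdiff(c("p", "q"), ac$arm))
    other <- arm_calls[[other_key]]
    if (!is.null(other) && !is.null(other$cls) &&
        identical(other$cls, ac$cls) &&
        abs(other$median_logr - ac$median_logr) <= merge_logr) {
      arm_events[[length(arm_events) + 1L]] <-
        cn_event(ac$chrom, "whole", ac$cls$direction, mosaic = ac$cls$mosaic,
                 genome = genome)
      done <- c(done, key, other_key)
    } else {
      arm_events[[length(arm_events) + 1L]] <-
        cn_event(ac$chrom, ac$arm, ac$cls$direction, mosaic = ac$cls$mosaic,
                 genome = genome)
      done <- c(done, key)
    }
  }
  events <- dplyr::bind_rows(c(arm_events, seg_events))
  if (!nrow(events)) events <- empty_events()
  platform_diagnosis("SNP", events, qc = qc, embryo_id = embryo_id)
}
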