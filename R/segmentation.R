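# Binary segmentation on a numeric series with BIC-style stopping.
# Used by both callers (marker LogR for the SNP arm scan, 2x normalized
# ratio for the NGS bins). Returns integer breakpoints: last index of each
# segment except the final one.

binseg <- function(x, min_width = 4L, penalty = 3, max_depth = 8L,
                   sigma2 = NULL) {
  n <- length(x)
  if (n < 2 * min_width) return(integer())
  if (is.null(sigma2)) {
    # robust local noise estimate from first differences
    d <- diff(x)
    sigma2 <- (stats::mad(d, na.rm = TRUE) / sqrt(2))^2
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- stats::var(x)
    # effectively constant input (float jitter only): nothing to split
    eps2 <- (1e-8 * (1 + abs(mean(x))))^2
    if (!is.finite(sigma2) || sigma2 <= eps2) return(integer())
  }
  thresh <- penalty * sigma2 * log(n)

  best_split <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2 * min_width) return(NULL)
    xs <- x[lo:hi]
    cs <- cumsum(xs); tot <- cs[m]
    k <- min_width:(m - min_width)
    # RSS reduction of splitting after position k (within-window index)
    gain <- cs[k]^2 / k + (tot - cs[k])^2 / (m - k) - tot^2 / m
    i <- which.max(gain)
    list(pos = lo + k[i] - 1L, gain = gain[i])
  }

  breaks <- integer()
  recurse <- function(lo, hi, depth) {
    if (depth > max_depth) return()
    sp <- best_split(lo, hi)
    if (is.null(sp) || sp$gain < thresh) return()
    breaks <<- c(breaks, sp$pos)
    recurse(lo, sp$pos, depth + 1L)
    recurse(sp$pos + 1L, hi, depth + 1L)
  }
  recurse(1L, n, 1L)
  sort(breaks)
}

# convert breakpoints to a (from, to) index table
seg_table <- function(n, breaks) {
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  tibble::tibble(from = starts, to = ends)
}
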