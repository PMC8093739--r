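# Tidal-phase extraction from a high-rate depth record: smoothing, peak
# picking with a minimum spacing, alternation repair, and the signed
# time-to-high-tide predictor.

#' Extract high and low tides from a depth record
#'
#' The depth series is cleaned with a running median and then a running mean
#' (both `median_window` / `mean_window` samples), after which local maxima
#' separated by at least `min_spacing` hours are taken as high tides; the
#' procedure is repeated on the negated series for low tides. Where two
#' highs (or two lows) occur without the other type between them, the less
#' prominent (lower high / shallower low) peak is dropped so that highs and
#' lows strictly alternate.
#'
#' @param times POSIXct sample instants (fixed cadence).
#' @param depth Depth series in metres (larger = deeper water = higher
#'   tide).
#' @param median_window,mean_window Odd window lengths in samples
#'   (default 501).
#' @param min_spacing Minimum peak separation in hours (default 5.5).
#' @return Object of class `tidaltag_tide`: list with POSIXct vectors
#'   `high_tide_times`, `low_tide_times`, the smoothed series, and a count
#'   `n_alternation_dropped`.
#' @export
extract_tide <- function(times, depth, median_window = 501,
                         mean_window = 501, min_spacing = 5.5) {
  dt <- as.numeric(difftime(times[2], times[1], units = "secs"))
  span_h <- as.numeric(difftime(times[length(times)], times[1], units = "hours"))
  if (span_h <= 2 * min_spacing) {
    stop("depth record span must exceed twice the minimum peak spacing")
  }
  if (median_window %% 2 == 0) median_window <- median_window + 1
  sm <- stats::runmed(depth, k = min(median_window, length(depth)), endrule = "median")
  sm <- running_mean(sm, mean_window)
  spacing_samples <- ceiling(min_spacing * 3600 / dt)

  highs <- find_peaks(sm, spacing_samples)
  lows <- find_peaks(-sm, spacing_samples)

  # merge and repair alternation: consecutive same-type peaks keep the more
  # prominent one (higher high, lower low)
  pk <- rbind(
    data.frame(i = highs, type = rep("H", length(highs)), h = sm[highs]),
    data.frame(i = lows, type = rep("L", length(lows)), h = sm[lows]))
  pk <- pk[order(pk$i), , drop = FALSE]
  dropped <- 0L
  repeat {
    same <- which(pk$type[-1] == pk$type[-nrow(pk)])
    if (!length(same) || nrow(pk) < 2) break
    j <- same[1]
    pair <- pk[c(j, j + 1), ]
    worse <- if (pair$type[1] == "H") which.min(pair$h) else which.max(pair$h)
    pk <- pk[-(j + worse - 1), , drop = FALSE]
    dropped <- dropped + 1L
  }
  if (dropped > 0) {
    message(dropped, " peak(s) dropped to restore high/low alternation")
  }
  structure(list(
    high_tide_times = times[pk$i[pk$type == "H"]],
    low_tide_times = times[pk$i[pk$type == "L"]],
    times = times, smoothed = sm,
    n_alternation_dropped = dropped), class = "tidaltag_tide")
}

#' @export
print.tidaltag_tide <- function(x, ...) {
  cat("Tidal phase extraction:", length(x$high_tide_times), "high tides,",
      length(x$low_tide_times), "low tides\n")
  if (length(x$high_tide_times) > 1) {
    cat(sprintf("  median high-tide spacing %.2f h\n",
                median(as.numeric(diff(x$high_tide_times), units = "hours"))))
  }
  invisible(x)
}

# Centered running mean with shrunken windows at the edges.
running_mean <- function(x, window) {
  if (window %% 2 == 0) window <- window + 1
  n <- length(x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Local maxima (strictly above the previous sample, at least as high as the
# next, plateau-tolerant) thinned to a minimum spacing: candidates are
# accepted tallest-first, discarding any within min_dist samples of an
# accepted peak. Interior peaks only.
find_peaks <- function(x, min_dist) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer())
  cand <- cand[order(-x[cand])]
  keep <- integer()
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Signed time to the nearest high tide
#'
#' For each grid bin, the signed offset in hours to the nearest extracted
#' high tide: zero at high tide, negative before (flood), positive after
#' (ebb), quantized to 5-min (0.083 h) steps. Bins farther than half a
#' tidal cycle from any detected high tide are missing.
#'
#' @param grid Bin start instants.
#' @param high_tide_times POSIXct high-tide instants (or a `tidaltag_tide`).
#' @param step Quantization step in seconds (default 300).
#' @return Numeric vector of signed hours on the grid.
#' @export
time_to_high_tide <- function(grid, high_tide_times, step = 300) {
  if (inherits(high_tide_times, "tidaltag_tide")) {
    high_tide_times <- high_tide_times$high_tide_times
  }
  if (!length(high_tide_times)) stop("need at least one high tide")
  ht <- sort(as.numeric(high_tide_times))
  g <- as.numeric(grid)
  nearest <- vapply(g, function(t) ht[which.min(abs(ht - t))], 0)
  offset_h <- round((g - nearest) / step) * step / 3600
  half_cycle_h <- if (length(ht) > 1) median(diff(ht)) / 3600 / 2 else 6.21
  offset_h[abs(offset_h) > half_cycle_h] <- NA_real_
  offset_h
}
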