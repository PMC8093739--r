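# Five-minute environmental feature engineering: regular-grid binning,
# profile despiking and depth means, current rotation, velocity bin
# selection, design-matrix assembly and collinearity screening.

#' Make a left-closed regular time grid
#'
#' Bins are `[t, t + step)`, labelled by their start instant.
#'
#' @param start,end POSIXct (UTC) span; `start < end`.
#' @param step Bin width in seconds (default 300 = 5 min).
#' @return POSIXct vector of bin start times.
#' @export
make_grid <- function(start, end, step = 300) {
  if (step <= 0) stop("step must be positive")
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(start < end)) stop("start must precede end")
  g <- seq(from = start, to = end, by = step)
  g[g < end]
}

#' Mean of a high-rate series within each grid bin
#'
#' Arithmetic mean of the samples falling in each left-closed bin; bins with
#' no samples are missing.
#'
#' @param times POSIXct sample instants.
#' @param values Numeric samples (NA allowed; NAs are skipped).
#' @param grid Bin start instants from [make_grid()].
#' @param step Bin width in seconds.
#' @return Numeric vector on the grid (NA where a bin is empty).
#' @export
bin_mean <- function(times, values, grid, step = 300) {
  idx <- floor(as.numeric(difftime(times, grid[1], units = "secs")) / step) + 1
  ok <- !is.na(values) & idx >= 1 & idx <= length(grid)
  sums <- rowsum(values[ok], idx[ok])
  counts <- rowsum(rep(1, sum(ok)), idx[ok])
  out <- rep(NA_real_, length(grid))
  out[as.integer(rownames(sums))] <- sums / counts
  out
}

#' Despike a profile series with a vertical running median
#'
#' At each time step, values along the vertical whose absolute deviation
#' from the centred running median exceeds `max_dev` are replaced by that
#' median. Near the edges the window shrinks to the largest odd centred
#' window that fits (so the outermost bin is never altered), which keeps
#' the operation idempotent. Targets single-bin amplified returns (large
#' non-zooplankton scatterers) in backscatter profiles; values within
#' `max_dev` of their local median are never touched.
#'
#' @param values Numeric matrix, time steps in rows, vertical bins in
#'   columns.
#' @param window Odd window length along the vertical (default 3).
#' @param max_dev Maximum tolerated deviation, in the units of the series.
#' @return Matrix of the same shape with spikes replaced.
#' @export
despike_profile <- function(values, window = 3, max_dev = 1) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  h <- (window - 1) / 2
  nb <- ncol(values)
  med <- matrix(NA_real_, nrow(values), nb)
  for (j in seq_len(nb)) {
    hj <- min(h, j - 1, nb - j) # largest odd centred window that fits
    block <- values[, (j - hj):(j + hj), drop = FALSE]
    med[, j] <- apply(block, 1, median, na.rm = TRUE)
  }
  spike <- !is.na(values) & !is.na(med) & abs(values - med) > max_dev
  out <- values
  out[spike] <- med[spike]
  attr(out, "n_replaced") <- sum(spike)
  out
}

#' Depth-mean of a profile series
#'
#' Mean over the vertical bins at each time step, skipping missing bins;
#' all-missing time steps are missing.
#'
#' @param values Numeric matrix, time x bins.
#' @return Numeric vector, one value per time step.
#' @export
depth_mean <- function(values) {
  out <- rowMeans(values, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Linear interpolation of a coarse series onto the analysis grid
#'
#' No extrapolation: grid instants outside the span of the non-missing
#' samples are missing (and will be dropped from the design matrix).
#'
#' @param times POSIXct sample instants.
#' @param values Numeric samples.
#' @param grid Target instants.
#' @return Numeric vector on the grid.
#' @export
interp_to_grid <- function(times, values, grid) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing points to interpolate")
  approx(x = as.numeric(times)[ok], y = values[ok],
         xout = as.numeric(grid), method = "linear", rule = 1)$y
}

#' Rotate current components into longshore / cross-shore coordinates
#'
#' Orthonormal (speed-preserving) rotation of eastward (u) / northward (v)
#' velocity, clockwise by `angle` degrees relative to north, aligning axes
#' with the local slope. With the default 117 degrees: flow toward compass
#' bearing 297 is positive longshore, toward 117 negative longshore; toward
#' 207 positive cross-shore, toward 27 negative cross-shore.
#'
#' @param u,v Eastward and northward velocity (m/s).
#' @param angle Rotation angle, degrees clockwise from north (default 117).
#' @return List with numeric vectors `longshore` and `cross_shore`.
#' @export
rotate_currents <- function(u, v, angle = 117) {
  b_long <- (angle + 180) %% 360   # +ve longshore bearing (297 for 117)
  b_cross <- (angle + 90) %% 360   # +ve cross-shore bearing (207 for 117)
  rad <- pi / 180
  list(
    longshore = u * sin(b_long * rad) + v * cos(b_long * rad),
    cross_shore = u * sin(b_cross * rad) + v * cos(b_cross * rad))
}

# Inverse of rotate_currents (used by the synthetic generator to emit u/v
# whose rotation reproduces a specified longshore/cross-shore truth).
unrotate_currents <- function(longshore, cross_shore, angle = 117) {
  b_long <- (angle + 180) %% 360
  b_cross <- (angle + 90) %% 360
  rad <- pi / 180
  list(
    u = longshore * sin(b_long * rad) + cross_shore * sin(b_cross * rad),
    v = longshore * cos(b_long * rad) + cross_shore * cos(b_cross * rad))
}

#' Select single-bin velocity series at reference heights
#'
#' Picks the 2-m profiler bin whose centre corresponds to the requested
#' height above the seabed, given the transducer height. With 25 bins
#' spanning 0.5-50.5 m range and a transducer 3 m above the bed, heights
#' 8.5 m and 48.5 m map to the bins centred 5.5 m and 45.5 m from the
#' transducer.
#'
#' @param values Profile matrix, time x 25 bins.
#' @param height_above_bed Requested height (m above seabed).
#' @param transducer_height Transducer height above the seabed (m).
#' @param bin_edges Range edges of the profile bins (m from transducer);
#'   default `seq(0.5, 50.5, by = 2)`.
#' @return Numeric vector: the single-bin time series.
#' @export
select_velocity_bin <- function(values, height_above_bed,
                                transducer_height = 3,
                                bin_edges = seq(0.5, 50.5, by = 2)) {
  range_from_transducer <- height_above_bed - transducer_height
  centers <- head(bin_edges, -1) + diff(bin_edges) / 2
  if (range_from_transducer < bin_edges[1] ||
      range_from_transducer > tail(bin_edges, 1)) {
    stop(sprintf("requested height %.1f m (range %.1f m) outside profiled bins",
                 height_above_bed, range_from_transducer))
  }
  j <- which.min(abs(centers - range_from_transducer))
  values[, j]
}

#' Depth-mean vertical velocity on the analysis grid
#'
#' Depth-mean over the profiled bins with no despiking (averaged velocity
#' data are low-noise), then linear interpolation onto the grid.
#'
#' @param times Profile time steps.
#' @param values Vertical-velocity matrix, time x bins (m/s).
#' @param grid Analysis grid.
#' @return Numeric vector on the grid.
#' @export
vertical_velocity_mean <- function(times, values, grid) {
  interp_to_grid(times, depth_mean(values), grid)
}

#' Convert sea pressure to depth
#'
#' Fixed-density hydrostatic conversion, `depth = 0.9928 * (p - atmospheric)`
#' metres per dbar (rho = 1025 kg/m^3, g = 9.81 m/s^2). Tidal-phase
#' extraction depends only on relative elevation, so the constant factor is
#' immaterial there.
#'
#' @param pressure Sea pressure in dbar.
#' @param atmospheric Constant offset (dbar) already removed if 0 (default).
#' @return Depth in metres.
#' @export
pressure_to_depth <- function(pressure, atmospheric = 0) {
  p <- pressure - atmospheric
  if (any(p < 0, na.rm = TRUE)) stop("negative sea pressure after offset")
  0.9928 * p
}

#' Assemble the presence/absence design matrix
#'
#' Joins the binary response (1 if any kept detection of any tag occurred at
#' the focal receiver within a 5-min bin) with the nine predictor series on
#' the grid. Rows with any missing predictor are dropped (listwise) and
#' counted.
#'
#' @param dets Kept detection data.frame.
#' @param grid Bin start instants.
#' @param predictors Named list or data.frame of the nine predictor series
#'   on the grid; names must be exactly [predictor_names()].
#' @param focal_receiver Receiver id whose detections define the response.
#' @param step Bin width in seconds.
#' @return data.frame with `time`, `response` and the nine predictors;
#'   attributes `n_dropped` (rows removed for missingness) and `prevalence`.
#' @export
assemble_design_matrix <- function(dets, grid, predictors, focal_receiver,
                                   step = 300) {
  predictors <- as.data.frame(predictors)
  if (!identical(sort(names(predictors)), sort(PREDICTOR_NAMES))) {
    stop("predictor names must be exactly: ",
         paste(PREDICTOR_NAMES, collapse = ", "))
  }
  predictors <- predictors[PREDICTOR_NAMES]
  stopifnot(nrow(predictors) == length(grid))
  d <- dets[dets$receiver_id == focal_receiver, , drop = FALSE]
  idx <- floor(as.numeric(difftime(d$timestamp, grid[1], units = "secs")) / step) + 1
  idx <- idx[idx >= 1 & idx <= length(grid)]
  response <- integer(length(grid))
  response[unique(idx)] <- 1L
  X <- cbind(data.frame(time = grid, response = response), predictors)
  keep <- complete.cases(predictors)
  out <- X[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "prevalence") <- mean(out$response)
  out
}

#' Pairwise correlation and VIF collinearity screen
#'
#' Pearson correlations between predictors and variance inflation factors
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the others.
#' Flags `|r| >= 0.6` or `VIF >= 3.5` (constant predictors report infinite
#' VIF).
#'
#' @param X data.frame or matrix of predictors.
#' @param r_threshold,vif_threshold Flag thresholds.
#' @return List with `correlation` (matrix), `vif` (named vector),
#'   `flagged` (character vector of predictor names).
#' @export
collinearity_screen <- function(X, r_threshold = 0.6, vif_threshold = 3.5) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  cm <- cor(X)
  vif <- vapply(names(X), function(nm) {
    if (sd(X[[nm]]) == 0) return(Inf)
    fit <- lm(reformulate(setdiff(names(X), nm), response = nm), data = X)
    # perfectly collinear predictors trip lm's perfect-fit warning; the
    # infinite VIF flag below is the intended report
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  off <- abs(cm) >= r_threshold & row(cm) != col(cm)
  flagged <- union(names(X)[apply(off, 1, any)], names(vif)[vif >= vif_threshold])
  list(correlation = cm, vif = vif, flagged = flagged)
}
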