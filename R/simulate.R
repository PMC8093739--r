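# Synthetic tidally forced world with known truth: semidiurnal tides,
# flood-phase cold-water bores near the bed, diel near-surface warming,
# bore-coupled backscatter pulses with single-bin spikes, tidally
# oscillating longshore currents, and bin-level presence of tagged animals
# governed by a logistic model on the nine predictors plus one product
# term. Signals are phenomenological templates, not hydrodynamics.

# Evaluate expr under a deterministic RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification of the synthetic world
#'
#' Defaults state the simulated conditions once: M2 + S2 tides; cold-water
#' bores on 80% of flood phases with random strength and a ~60-min decay; a
#' 0.5 degC diel cycle in near-surface temperature; backscatter pulses
#' co-occurring with bores plus single-bin spikes; longshore currents mixing
#' a tidal oscillation with a slowly varying wind-driven background; and 19
#' tags whose bin-level presence follows a logistic model on the nine
#' standardized predictors with the time-to-high-tide coefficient dominant
#' and one interacting pair (near-surface temperature x vertical velocity),
#' calibrated to ~4% prevalence. Pings are emitted at random 30-90 s
#' intervals while present.
#'
#' @param ... Overrides for any default field.
#' @return List of class `tidaltag_truth_spec`.
#' @export
truth_spec <- function(...) {
  spec <- list(
    constituents = data.frame(
      name = c("M2", "S2"), amplitude = c(0.5, 0.2),
      period_h = c(12.4206012, 12.0), phase = c(0, 0.8)),
    mean_depth = 64.1,          # m, lower CTD
    temp2_base = 27.9,          # degC near-bed baseline
    bore_amp = 2.0,             # degC drop at full flood forcing
    bore_decay_min = 60,        # exponential memory of the bore signal
    bore_prob = 0.8,            # fraction of tidal cycles producing a bore
    bore_scale_range = c(0.7, 1.3), # per-cycle random bore amplitude factor
    temp50_base = 29.1,         # degC near-surface baseline
    diel_amp = 0.5,             # degC, peak mid-afternoon
    temp_noise_sd = 0.05,
    backscatter_base = 46,      # dB
    backscatter_pulse = 6,      # dB added at full flood forcing
    backscatter_noise_sd = 1,
    spike_rate = 0.01,          # fraction of profile cells hit by +15 dB
    spike_amp = 15,
    ls_amp = 0.12,              # m/s longshore tidal oscillation (near-surface)
    ls_shear = 0.8,             # near-bed fraction of near-surface amplitude
    cs_amp = 0.1,               # m/s cross-shore flood/ebb asymmetry
    current_bg_sd = 0.12,       # m/s slowly varying (wind-driven) background
    current_bg_phi = 0.98,      # AR(1) memory of the background at 10 min
    current_noise_sd = 0.02,
    w_noise_sd = 0.004,
    w_pulse = -0.02,            # m/s downwelling pulses
    w_pulse_rate = 0.05,        # fraction of profile time steps pulsed
    rotation_angle = 117,       # degrees clockwise from north
    beta = c(temp_2m = -0.35, temp_50m = 0.3, backscatter = 0.35,
             cs_48_5 = -0.15, cs_8_5 = 0.15, ls_48_5 = 0.2, ls_8_5 = 0.2,
             vertical_velocity = -0.3, time_to_high_tide = -2.2),
    interaction_pair = c("temp_50m", "vertical_velocity"),
    beta_interaction = -0.5,    # warm near-surface water + downwelling
                                # boost presence beyond the additive effects
    diel_beta = 0,              # optional extra day-weighting (peak 13:00);
                                # 0 = presence exactly the stated logistic
                                # model (day-weighting enters via temp_50m)
    target_prevalence = 0.04,
    n_tags = 19,
    ping_interval = c(30, 90),  # s
    detection_prob = 0.85,
    spurious_per_day = 0.2,     # isolated false pings across the array
    focal_receiver = "R-MA",
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(spec))
  if (length(bad)) stop("unknown truth_spec field(s): ",
                        paste(bad, collapse = ", "))
  spec[names(over)] <- over
  if (any(spec$constituents$period_h <= 0)) stop("tidal periods must be positive")
  if (spec$detection_prob <= 0 || spec$detection_prob > 1) {
    stop("detection_prob must be in (0, 1]")
  }
  structure(spec, class = "tidaltag_truth_spec")
}

# Tidal elevation (m) and its time derivative at POSIXct instants.
tide_elevation <- function(spec, times, origin) {
  th <- as.numeric(difftime(times, origin, units = "hours"))
  eta <- 0
  deta <- 0
  for (i in seq_len(nrow(spec$constituents))) {
    A <- spec$constituents$amplitude[i]
    Tm <- spec$constituents$period_h[i]
    ph <- spec$constituents$phase[i]
    eta <- eta + A * cos(2 * pi * th / Tm - ph)
    deta <- deta - A * (2 * pi / Tm) * sin(2 * pi * th / Tm - ph)
  }
  list(eta = eta, deta = deta)
}

# Normalized flood forcing in [0, 1] (rising water only) with an
# exponential decay memory, on instants with cadence dt_s seconds.
flood_forcing <- function(spec, times, origin, dt_s) {
  td <- tide_elevation(spec, times, origin)
  f <- pmax(0, td$deta) / max(abs(td$deta))
  a <- exp(-dt_s / 60 / spec$bore_decay_min)
  as.numeric(stats::filter(f * (1 - a), a, method = "recursive", init = f[1]))
}

# Analytic high-tide instants: elevation maxima on a 1-min lattice.
true_high_tides <- function(spec, start, end) {
  fine <- seq(as.POSIXct(start, tz = "UTC"), as.POSIXct(end, tz = "UTC"),
              by = 60)
  eta <- tide_elevation(spec, fine, start)$eta
  i <- find_peaks(eta, min_dist = ceiling(5.5 * 60))
  fine[i]
}

#' Simulate the instrument series
#'
#' Emits the raw series the feature pipeline consumes: two 5-s CTD records
#' (near-bed temperature + pressure; near-surface temperature) and 10-min
#' ADCP profiles over 25 x 2-m bins (backscatter amplitude, u, v, w). The
#' u/v components are built by inverse rotation so that rotating them
#' clockwise by the spec angle recovers the specified longshore and
#' cross-shore truth.
#'
#' @param spec A [truth_spec()].
#' @param start,end Span (POSIXct or parseable, UTC); at least 2 days.
#' @param seed Integer seed (default the spec's).
#' @return List with `ctd` (data.frame time/temp_2m/temp_50m/pressure),
#'   `adcp` (list time, amp/u/v/w matrices 25 bins), and `truth` (high-tide
#'   instants, per-instant forcing, the longshore/cross-shore truth
#'   series).
#' @export
simulate_ocean <- function(spec, start, end, seed = spec$seed) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (as.numeric(difftime(end, start, units = "days")) < 2) {
    stop("simulated span must be at least 2 days")
  }
  with_seed(derive_seed(seed, 101L), {
    high_tides <- true_high_tides(spec, start, end)
    # one random bore realization per tidal cycle (interval between highs):
    # most floods carry a bore of random strength, some none at all
    n_cycles <- length(high_tides) + 1L
    bore_scale <- ifelse(runif(n_cycles) < spec$bore_prob,
                         runif(n_cycles, spec$bore_scale_range[1],
                               spec$bore_scale_range[2]), 0)
    cycle_of <- function(times) {
      findInterval(as.numeric(times), as.numeric(high_tides)) + 1L
    }

    t5 <- seq(start, end, by = 5)
    t5 <- t5[t5 < end]
    td <- tide_elevation(spec, t5, start)
    bore5 <- flood_forcing(spec, t5, start, 5) * bore_scale[cycle_of(t5)]
    hour5 <- as.numeric(format(t5, "%H", tz = "UTC")) +
      as.numeric(format(t5, "%M", tz = "UTC")) / 60
    n5 <- length(t5)
    ctd <- data.frame(
      time = t5,
      temp_2m = spec$temp2_base - spec$bore_amp * bore5 +
        rnorm(n5, 0, spec$temp_noise_sd),
      temp_50m = spec$temp50_base +
        spec$diel_amp * cos(2 * pi * (hour5 - 14) / 24) +
        rnorm(n5, 0, spec$temp_noise_sd),
      pressure = (spec$mean_depth + td$eta) / 0.9928)

    t10 <- seq(start, end, by = 600)
    t10 <- t10[t10 < end]
    n10 <- length(t10)
    nb <- 25
    flood10 <- flood_forcing(spec, t10, start, 600)
    bore10 <- flood10 * bore_scale[cycle_of(t10)]
    deta10 <- tide_elevation(spec, t10, start)$deta
    deta10n <- deta10 / max(abs(deta10))
    # slowly varying wind-driven backgrounds, AR(1) at the 10-min cadence
    ar_bg <- function(sd, phi) {
      as.numeric(stats::filter(rnorm(n10, 0, sd * sqrt(1 - phi^2)), phi,
                               method = "recursive"))
    }

    amp <- matrix(spec$backscatter_base, n10, nb)
    amp <- amp + outer(spec$backscatter_pulse * bore10, rep(1, nb)) +
      outer(rep(1, n10), -0.05 * (seq_len(nb) - 1)) +
      matrix(rnorm(n10 * nb, 0, spec$backscatter_noise_sd), n10, nb)
    spikes <- matrix(runif(n10 * nb) < spec$spike_rate, n10, nb)
    amp[spikes] <- amp[spikes] + spec$spike_amp

    # linear vertical shear: near-bed bins carry ls_shear of the
    # near-surface longshore amplitude
    shear <- spec$ls_shear + (1 - spec$ls_shear) * (seq_len(nb) - 1) / (nb - 1)
    ls_true <- outer(spec$ls_amp * deta10n +
                       ar_bg(spec$current_bg_sd, spec$current_bg_phi), shear)
    cs_true <- outer(spec$cs_amp * (flood10 - mean(flood10)) +
                       ar_bg(spec$current_bg_sd / 2, spec$current_bg_phi),
                     rep(1, nb))
    ls_noisy <- ls_true + matrix(rnorm(n10 * nb, 0, spec$current_noise_sd),
                                 n10, nb)
    cs_noisy <- cs_true + matrix(rnorm(n10 * nb, 0, spec$current_noise_sd),
                                 n10, nb)
    uv <- unrotate_currents(ls_noisy, cs_noisy, spec$rotation_angle)

    w <- matrix(rnorm(n10 * nb, 0, spec$w_noise_sd), n10, nb)
    pulsed <- runif(n10) < spec$w_pulse_rate
    w[pulsed, ] <- w[pulsed, ] + spec$w_pulse

    list(
      ctd = ctd,
      adcp = list(time = t10, amp = amp, u = uv$u, v = uv$v, w = w),
      truth = list(
        start = start, end = end,
        high_tide_times = high_tides,
        flood_10min = flood10, bore_10min = bore10,
        longshore_true = ls_true, cross_shore_true = cs_true))
  })
}

# Build the nine predictors on the 5-min grid from simulated instruments,
# using the package's own feature operations (bin means, despiking,
# depth-means, interpolation, rotation, tide phase from the truth's highs).
ocean_to_predictors <- function(ocean, grid, spec) {
  ctd <- ocean$ctd
  adcp <- ocean$adcp
  amp_clean <- despike_profile(adcp$amp)
  rot <- rotate_currents(adcp$u, adcp$v, spec$rotation_angle)
  ls <- rot$longshore
  cs <- rot$cross_shore
  data.frame(
    temp_2m = bin_mean(ctd$time, ctd$temp_2m, grid),
    temp_50m = bin_mean(ctd$time, ctd$temp_50m, grid),
    backscatter = interp_to_grid(adcp$time, depth_mean(amp_clean), grid),
    cs_48_5 = interp_to_grid(adcp$time,
                             select_velocity_bin(cs, 48.5), grid),
    cs_8_5 = interp_to_grid(adcp$time,
                            select_velocity_bin(cs, 8.5), grid),
    ls_48_5 = interp_to_grid(adcp$time,
                             select_velocity_bin(ls, 48.5), grid),
    ls_8_5 = interp_to_grid(adcp$time,
                            select_velocity_bin(ls, 8.5), grid),
    vertical_velocity = vertical_velocity_mean(adcp$time, adcp$w, grid),
    time_to_high_tide = time_to_high_tide(grid,
                                          ocean$truth$high_tide_times))
}

#' Simulate bin-level presence from the predictors
#'
#' Standardizes the predictors, applies the spec's logistic coefficients
#' plus the single product term (and an optional diel weight when bin
#' instants are supplied), calibrates the intercept so the expected
#' prevalence matches the spec target, and draws Bernoulli presence.
#'
#' @param predictors data.frame of the nine predictors (no missing rows).
#' @param spec A [truth_spec()].
#' @param times Optional POSIXct bin instants for the diel term.
#' @param seed Integer seed.
#' @return List: `p` (per-bin probability), `presence` (0/1 draws),
#'   `beta0` (calibrated intercept), `bayes_auc` (AUC of the true
#'   probability against its own draws).
#' @export
simulate_presence <- function(predictors, spec, times = NULL,
                              seed = spec$seed) {
  stopifnot(all(PREDICTOR_NAMES %in% names(predictors)))
  if (anyNA(predictors[PREDICTOR_NAMES])) {
    stop("predictors must be complete; drop missing rows first")
  }
  Z <- scale(as.matrix(predictors[PREDICTOR_NAMES]))
  lp <- as.numeric(Z %*% spec$beta[PREDICTOR_NAMES]) +
    spec$beta_interaction * Z[, spec$interaction_pair[1]] *
      Z[, spec$interaction_pair[2]]
  if (!is.null(times) && spec$diel_beta != 0) {
    hr <- as.numeric(format(times, "%H", tz = "UTC")) +
      as.numeric(format(times, "%M", tz = "UTC")) / 60
    lp <- lp + spec$diel_beta * cos(2 * pi * (hr - 13) / 24)
  }
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  beta0 <- uniroot(function(c) mean(stats::plogis(c + lp)) -
                     spec$target_prevalence,
                   interval = c(-30, 10), tol = 1e-10)$root
  p <- stats::plogis(beta0 + lp)
  presence <- with_seed(derive_seed(seed, 211L),
                        as.integer(runif(length(p)) < p))
  list(p = p, presence = presence, beta0 = beta0,
       bayes_auc = auc_score(presence, p))
}

#' Simulate the detection log
#'
#' In each present bin, one to three of the tagged animals are present;
#' each emits pings at uniform 30-90 s intervals for the duration of the
#' bin, and every ping is detected independently with the spec probability
#' at the focal receiver. Isolated spurious pings (decoder noise) are
#' injected at the configured daily rate across all receivers to exercise
#' the false-detection screen.
#'
#' @param presence 0/1 vector on the grid.
#' @param grid Bin start instants.
#' @param spec A [truth_spec()].
#' @param tag_ids Character tag identifiers (default `"T01"...`).
#' @param receiver_ids All receiver ids (focal first).
#' @param seed Integer seed.
#' @param step Bin width, seconds.
#' @return Detection data.frame (`timestamp`, `tag_id`, `receiver_id`)
#'   sorted by time, with attribute `ledger`: per-bin emitted and detected
#'   ping counts and the spurious count.
#' @export
simulate_detections <- function(presence, grid, spec,
                                tag_ids = sprintf("T%02d", seq_len(spec$n_tags)),
                                receiver_ids = spec$focal_receiver,
                                seed = spec$seed, step = 300) {
  with_seed(derive_seed(seed, 307L), {
    rows <- vector("list", 256)
    nr <- 0L
    emitted <- integer(length(grid))
    detected <- integer(length(grid))
    for (i in which(presence == 1)) {
      n_present <- 1 + rbinom(1, 2, 0.3)
      tags_here <- sample(tag_ids, min(n_present, length(tag_ids)))
      t0 <- as.numeric(grid[i])
      for (tag in tags_here) {
        t <- t0 + runif(1, 0, spec$ping_interval[1])
        while (t < t0 + step) {
          emitted[i] <- emitted[i] + 1L
          if (runif(1) < spec$detection_prob) {
            detected[i] <- detected[i] + 1L
            nr <- nr + 1L
            if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
            rows[[nr]] <- list(t, tag, spec$focal_receiver)
          }
          t <- t + runif(1, spec$ping_interval[1], spec$ping_interval[2])
        }
      }
    }
    span_days <- as.numeric(grid[length(grid)] + step - grid[1]) / 86400
    n_spur <- rpois(1, spec$spurious_per_day * span_days)
    for (s in seq_len(n_spur)) {
      nr <- nr + 1L
      if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nr]] <- list(as.numeric(grid[1]) + runif(1) * span_days * 86400,
                         sample(tag_ids, 1), sample(receiver_ids, 1))
    }
    rows <- rows[seq_len(nr)]
    dets <- data.frame(
      timestamp = as.POSIXct(vapply(rows, `[[`, 0, 1),
                             origin = "1970-01-01", tz = "UTC"),
      tag_id = vapply(rows, `[[`, "", 2),
      receiver_id = vapply(rows, `[[`, "", 3),
      stringsAsFactors = FALSE)
    dets <- dets[order(dets$timestamp), , drop = FALSE]
    rownames(dets) <- NULL
    structure(dets, ledger = list(emitted = emitted, detected = detected,
                                  n_spurious = n_spur))
  })
}

default_receivers <- function(spec) {
  data.frame(
    receiver_id = c(spec$focal_receiver, "R-IS", "R-NC", "R-SM", "R-SE"),
    site_name = c("Manta Alley", "Ile Sipaille", "North IdR Cleaning Station",
                  "South Manta Alley", "Ile Sudest"),
    lat = c(-6.64, -6.67, -6.64, -6.67, -6.70),
    lon = c(71.35, 71.32, 71.32, 71.39, 71.40),
    depth = c(70, 14.6, 13.6, 14.2, 15),
    height_above_seabed = c(48, 1.5, 1.6, 1.8, 1.8),
    stringsAsFactors = FALSE)
}

default_tags <- function(spec, start) {
  n <- spec$n_tags
  sex <- rep(c("F", "M"), length.out = n)
  maturity <- rep(c("adult", "sub-adult", "juvenile"), length.out = n)
  data.frame(
    tag_id = sprintf("T%02d", seq_len(n)),
    manta_id = sprintf("SIM-MA-%04d", seq_len(n)),
    sex = sex, maturity = maturity,
    deploy_date = as.Date(start) - 7,
    deploy_site = "Manta Alley",
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic bundle
#'
#' Simulates the ocean, derives the nine predictors with the package's own
#' feature operations, draws presence and the detection log, and (when
#' `dir` is given) writes the instrument files, detection log, metadata
#' tables and a JSON truth ledger. Fully reproducible per seed;
#' `size = "small"` spans 7 days (2,016 bins), `"paper-scale"` 100 days
#' (28,800 bins).
#'
#' @param seed Integer seed.
#' @param size `"small"` or `"paper-scale"`.
#' @param spec A [truth_spec()].
#' @param dir Optional output directory for the file bundle.
#' @return List of class `tidaltag_bundle`: `spec`, `grid`, `ocean`,
#'   `predictors` (with NA rows), `design` (complete rows with response),
#'   `presence` (ledger from [simulate_presence()]), `detections`, `tags`,
#'   `receivers`, `truth`.
#' @export
make_fixture <- function(seed = 1, size = c("small", "paper-scale"),
                         spec = truth_spec(), dir = NULL) {
  size <- match.arg(size)
  start <- as.POSIXct("2019-12-01 00:00:00", tz = "UTC")
  end <- start + c(small = 7, `paper-scale` = 100)[[size]] * 86400
  ocean <- simulate_ocean(spec, start, end, seed = seed)
  grid <- make_grid(start, end)
  predictors <- ocean_to_predictors(ocean, grid, spec)
  complete <- complete.cases(predictors)
  pres <- simulate_presence(predictors[complete, , drop = FALSE], spec,
                            times = grid[complete], seed = seed)
  presence_full <- integer(length(grid))
  presence_full[complete] <- pres$presence
  dets <- simulate_detections(presence_full, grid, spec,
                              receiver_ids = default_receivers(spec)$receiver_id,
                              seed = seed)
  design <- cbind(data.frame(time = grid[complete],
                             response = pres$presence),
                  predictors[complete, , drop = FALSE])
  rownames(design) <- NULL
  bundle <- structure(list(
    spec = spec, seed = seed, size = size, grid = grid, ocean = ocean,
    predictors = predictors, design = design, presence = pres,
    detections = dets, tags = default_tags(spec, start),
    receivers = default_receivers(spec),
    truth = c(ocean$truth, list(
      prevalence = mean(pres$presence),
      n_detections = nrow(dets),
      ledger = attr(dets, "ledger")))), class = "tidaltag_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @export
print.tidaltag_bundle <- function(x, ...) {
  cat(sprintf("Synthetic bundle (%s, seed %d): %d bins, prevalence %.3f, %d detections\n",
              x$size, x$seed, length(x$grid), x$truth$prevalence,
              nrow(x$detections)))
  invisible(x)
}

# Write the bundle as the delimited files + JSON ledger the readers consume.
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  dets <- bundle$detections
  write.csv(data.frame(timestamp = fmt(dets$timestamp),
                       receiver = dets$receiver_id,
                       transmitter = dets$tag_id),
            file.path(dir, "detections.csv"), row.names = FALSE)
  ctd <- bundle$ocean$ctd
  write.csv(data.frame(timestamp = fmt(ctd$time), temp_2m = ctd$temp_2m,
                       temp_50m = ctd$temp_50m, pressure = ctd$pressure),
            file.path(dir, "ctd.csv"), row.names = FALSE)
  adcp <- bundle$ocean$adcp
  for (nm in c("amp", "u", "v", "w")) {
    m <- as.data.frame(adcp[[nm]])
    names(m) <- sprintf("bin_%02d", seq_len(ncol(m)))
    write.csv(cbind(data.frame(timestamp = fmt(adcp$time)), m),
              file.path(dir, sprintf("adcp_%s.csv", nm)), row.names = FALSE)
  }
  write.csv(bundle$tags, file.path(dir, "tags.csv"), row.names = FALSE)
  write.csv(bundle$receivers, file.path(dir, "receivers.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(
    seed = bundle$seed, size = bundle$size,
    prevalence = bundle$truth$prevalence,
    beta0 = bundle$presence$beta0,
    bayes_auc = bundle$presence$bayes_auc,
    high_tide_times = fmt(bundle$truth$high_tide_times),
    p = bundle$presence$p, presence = bundle$presence$presence,
    emitted = bundle$truth$ledger$emitted,
    detected = bundle$truth$ledger$detected,
    n_spurious = bundle$truth$ledger$n_spurious),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
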