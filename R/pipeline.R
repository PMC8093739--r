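# End-to-end orchestration: qc -> events -> features -> fit -> interpret,
# from a single validated config, with a reproducible run manifest.

#' Read an instrument profile file (time x 25 bins)
#'
#' @param path Delimited file with a `timestamp` column and `bin_01..bin_25`
#'   columns.
#' @return List with `time` (POSIXct) and `values` (matrix).
#' @export
read_profile <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  bins <- grep("^bin_", names(raw), value = TRUE)
  list(time = parse_timestamp(raw$timestamp),
       values = as.matrix(raw[bins]))
}

#' Read a CTD record
#'
#' @param path Delimited file with `timestamp` plus value columns (e.g.
#'   `temp_2m`, `temp_50m`, `pressure`).
#' @return data.frame with parsed `time` plus the value columns.
#' @export
read_ctd <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  cbind(data.frame(time = parse_timestamp(raw$timestamp)),
        raw[setdiff(names(raw), "timestamp")])
}

# Minimal schema validation: required fields present and well-typed before
# any stage executes.
validate_config <- function(config) {
  need <- c("paths", "grid", "focal_receiver", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config lacks field(s): ", paste(missing, collapse = ", "))
  }
  path_need <- c("detections", "ctd", "adcp_amp", "adcp_u", "adcp_v",
                 "adcp_w", "out_dir")
  missing <- setdiff(path_need, names(config$paths))
  if (length(missing)) {
    stop("config$paths lacks: ", paste(missing, collapse = ", "))
  }
  if (is.null(config$grid$start) || is.null(config$grid$end)) {
    stop("config$grid needs start and end")
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- detection QC, resident events, feature
#' engineering, model fitting (stepwise CV), interpretation -- writing
#' versioned outputs and a manifest (input hashes, seed, package version)
#' to the configured output directory. Re-running with an identical config
#' and seed reproduces identical outputs.
#'
#' @param config A named list (or path to a JSON file): `paths` (input
#'   files + `out_dir`), `grid` (`start`, `end`; ISO strings),
#'   `focal_receiver`, `seed`, and optional `filter` (`short`, `long`),
#'   `events` (`timeout`, `switch_count`), `fit` (any [brt_config()]
#'   field plus `n_trees` to skip stepwise selection), `interpret`
#'   (`pd_predictors`, `n_grid`, `interaction_pairs` as a list of
#'   2-vectors).
#' @return Invisibly, a list with the stage outputs (`qc`, `events`,
#'   `design`, `model`, `report`, `influence`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  # qc ---------------------------------------------------------------
  qc <- run_stage("qc", {
    dets <- read_detections(config$paths$detections)
    flt <- config$filter %||% list()
    filter_false_detections(dets,
                            short = flt$short %||% (30 * 60),
                            long = flt$long %||% (12 * 3600))
  })
  write.csv(qc$kept, file.path(out_dir, "detections_kept.csv"),
            row.names = FALSE)

  # events -----------------------------------------------------------
  events <- run_stage("events", {
    ev <- config$events %||% list()
    detect_resident_events(qc$kept, timeout = ev$timeout %||% 3600,
                           switch_count = ev$switch_count %||% 2L)
  })
  write.csv(events, file.path(out_dir, "resident_events.csv"),
            row.names = FALSE)

  # features ---------------------------------------------------------
  design <- run_stage("features", {
    grid <- make_grid(as.POSIXct(config$grid$start, tz = "UTC"),
                      as.POSIXct(config$grid$end, tz = "UTC"))
    ctd <- read_ctd(config$paths$ctd)
    amp <- read_profile(config$paths$adcp_amp)
    u <- read_profile(config$paths$adcp_u)
    v <- read_profile(config$paths$adcp_v)
    w <- read_profile(config$paths$adcp_w)
    amp_clean <- despike_profile(amp$values)
    rot <- rotate_currents(u$values, v$values)
    depth <- pressure_to_depth(ctd$pressure)
    tide <- extract_tide(ctd$time, depth)
    predictors <- data.frame(
      temp_2m = bin_mean(ctd$time, ctd$temp_2m, grid),
      temp_50m = bin_mean(ctd$time, ctd$temp_50m, grid),
      backscatter = interp_to_grid(amp$time, depth_mean(amp_clean), grid),
      cs_48_5 = interp_to_grid(u$time,
                               select_velocity_bin(rot$cross_shore, 48.5),
                               grid),
      cs_8_5 = interp_to_grid(u$time,
                              select_velocity_bin(rot$cross_shore, 8.5),
                              grid),
      ls_48_5 = interp_to_grid(u$time,
                               select_velocity_bin(rot$longshore, 48.5),
                               grid),
      ls_8_5 = interp_to_grid(u$time,
                              select_velocity_bin(rot$longshore, 8.5),
                              grid),
      vertical_velocity = vertical_velocity_mean(w$time, w$values, grid),
      time_to_high_tide = time_to_high_tide(grid, tide))
    assemble_design_matrix(qc$kept, grid, predictors,
                           focal_receiver = config$focal_receiver)
  })
  write.csv(design, file.path(out_dir, "design_matrix.csv"),
            row.names = FALSE)

  # fit --------------------------------------------------------------
  fitres <- run_stage("fit", {
    fc <- config$fit %||% list()
    cfg <- brt_config(tc = fc$tc %||% 6, lr = fc$lr %||% 0.005,
                      bf = fc$bf %||% 0.7, ss = fc$ss %||% 50,
                      n_folds = fc$n_folds %||% 10,
                      max_trees = fc$max_trees %||% 10000,
                      min_obs = fc$min_obs %||% 10,
                      patience = fc$patience %||% 5,
                      seed = config$seed)
    X <- design[PREDICTOR_NAMES]
    y <- design$response
    model <- if (!is.null(fc$n_trees)) {
      fit_brt(X, y, cfg, n_trees = fc$n_trees)
    } else {
      step_cv_fit(X, y, cfg)
    }
    list(model = model, report = evaluate_brt(model, X, y))
  })
  write_model_json(fitres$model, file.path(out_dir, "model.json"))

  # interpret --------------------------------------------------------
  interp <- run_stage("interpret", {
    ic <- config$interpret %||% list()
    X <- design[PREDICTOR_NAMES]
    infl <- relative_influence(fitres$model)
    pd_vars <- ic$pd_predictors %||% infl$predictor[1]
    pd <- lapply(pd_vars, function(v) {
      partial_dependence(fitres$model, v, X,
                         n_grid = ic$n_grid %||% 100)
    })
    names(pd) <- pd_vars
    list(influence = infl, pd = pd)
  })
  write.csv(interp$influence, file.path(out_dir, "influence.csv"),
            row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tidaltag")),
    seed = config$seed,
    stages = stages,
    inputs = as.list(tools::md5sum(unlist(config$paths[
      c("detections", "ctd", "adcp_amp", "adcp_u", "adcp_v", "adcp_w")]))),
    n_detections_kept = nrow(qc$kept),
    n_detections_flagged = nrow(qc$flagged),
    n_events = nrow(events),
    n_design_rows = nrow(design),
    n_design_dropped = attr(design, "n_dropped"),
    n_trees_selected = fitres$model$n_trees_selected,
    report = fitres$report[c("t_auc", "cv_auc", "delta_auc", "d2")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qc = qc, events = events, design = design,
                 model = fitres$model, report = fitres$report,
                 influence = interp$influence, pd = interp$pd,
                 manifest = manifest))
}

#' Serialize a boosted model to JSON
#'
#' @param model A `tidaltag_brt`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    intercept = model$intercept, lr = model$lr,
    n_trees_selected = model$n_trees_selected,
    var_names = model$var_names,
    config = unclass(model$config),
    prevalence = model$prevalence,
    trees = lapply(model$trees[seq_len(model$n_trees_selected)],
                   function(m) as.data.frame(m))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a boosted model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A `tidaltag_brt`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(brt_config, j$config)
  structure(list(
    intercept = j$intercept,
    trees = lapply(j$trees, function(d) as.matrix(d)),
    lr = j$lr, n_trees_selected = as.integer(j$n_trees_selected),
    var_names = j$var_names, config = cfg, prevalence = j$prevalence,
    cv = NULL), class = "tidaltag_brt")
}
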