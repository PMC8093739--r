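# Boosted regression trees for a binomial response: configuration, fixed
# tree-count fitting, stepwise cross-validated tree selection, and model
# evaluation (AUC, deviance explained). The tree/boosting engine lives in
# src/boost.cpp; all randomness is derived from the config seed.

#' Boosting configuration
#'
#' @param tc Tree complexity: maximum interaction depth of each tree
#'   (>= 1; 1 gives stumps).
#' @param lr Learning rate (shrinkage) per tree, 0 < lr <= 1.
#' @param bf Bag fraction: fraction of rows subsampled without replacement
#'   for each tree, 0 < bf <= 1.
#' @param ss Step size: trees added per cross-validation step.
#' @param n_folds Number of cross-validation folds (default 10, stratified
#'   on the response).
#' @param max_trees Ceiling on the ensemble size during stepwise selection.
#' @param min_obs Minimum training rows in a terminal node.
#' @param patience Stepwise selection stops after this many steps without
#'   improvement in held-out deviance.
#' @param seed Integer seed governing subsampling and fold assignment.
#' @return A list of class `tidaltag_brt_config`.
#' @export
brt_config <- function(tc = 6, lr = 0.005, bf = 0.7, ss = 50, n_folds = 10,
                       max_trees = 10000, min_obs = 10, patience = 5,
                       seed = 1) {
  stopifnot(tc >= 1, lr > 0, lr <= 1, bf > 0, bf <= 1, ss >= 1,
            n_folds >= 2, max_trees >= 1, min_obs >= 1, patience >= 1)
  structure(list(tc = as.integer(tc), lr = lr, bf = bf, ss = as.integer(ss),
                 n_folds = as.integer(n_folds),
                 max_trees = as.integer(max_trees),
                 min_obs = as.integer(min_obs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "tidaltag_brt_config")
}

as_predictor_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

logit <- function(p) log(p / (1 - p))

#' Mean binomial deviance
#'
#' `mean(-2 * (y * log(p) + (1 - y) * log(1 - p)))` with probabilities
#' clipped to `[1e-8, 1 - 1e-8]`.
#'
#' @param y Binary response vector.
#' @param p Predicted probabilities.
#' @return Mean deviance (scalar).
#' @export
binomial_deviance <- function(y, p) {
  if (length(y) != length(p)) stop("y and p must have equal length")
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  mean(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores count one half.
#'
#' @param y Binary response.
#' @param score Numeric scores (any monotone scale).
#' @return AUC in `[0, 1]`, or NA if only one class is present.
#' @export
auc_score <- function(y, score) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a boosted regression tree ensemble with a fixed tree count
#'
#' Logistic stochastic gradient boosting: the model starts at the logit of
#' the training prevalence; each stage fits a depth-limited least-squares
#' regression tree to the gradient residuals `y - p` on a `bf`-fraction
#' subsample (without replacement), with terminal-node values given by the
#' one-step Newton estimate, and contributes with shrinkage `lr`.
#'
#' @param X Predictor data.frame or matrix.
#' @param y Binary response vector.
#' @param config A [brt_config()].
#' @param n_trees Number of boosting stages.
#' @return Object of class `tidaltag_brt`.
#' @export
fit_brt <- function(X, y, config = brt_config(), n_trees = 100) {
  X <- as_predictor_matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (all(y == y[1])) stop("response is constant; intercept logit undefined")
  intercept <- logit(mean(y))
  fit <- cpp_boost(X, y, rep(intercept, length(y)), as.integer(n_trees),
                   config$tc, config$lr, config$bf, config$min_obs,
                   derive_seed(config$seed, 1L))
  structure(list(intercept = intercept, trees = fit$trees, lr = config$lr,
                 n_trees_selected = as.integer(n_trees),
                 var_names = colnames(X), config = config,
                 prevalence = mean(y), cv = NULL),
            class = "tidaltag_brt")
}

#' Predict from a boosted model
#'
#' `logistic(intercept + lr * sum of tree contributions)` over the first
#' `n_trees` stages.
#'
#' @param object A `tidaltag_brt` model.
#' @param newdata Predictor data.frame or matrix with the training columns.
#' @param n_trees Number of leading trees to use (default: the selected
#'   count).
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.tidaltag_brt <- function(object, newdata,
                                 n_trees = object$n_trees_selected,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing_vars <- setdiff(object$var_names, colnames(newdata))
  if (length(missing_vars)) {
    stop("newdata lacks predictor(s): ", paste(missing_vars, collapse = ", "))
  }
  Xm <- as_predictor_matrix(newdata[object$var_names])
  f <- object$intercept + object$lr * cpp_tree_sum(object$trees, Xm,
                                                  as.integer(n_trees))
  if (type == "link") f else 1 / (1 + exp(-f))
}

#' @export
print.tidaltag_brt <- function(x, ...) {
  cat("Boosted regression trees (binomial)\n")
  cat(sprintf("  %d trees selected of %d grown; tc = %d, lr = %g, bf = %g\n",
              x$n_trees_selected, length(x$trees), x$config$tc, x$config$lr,
              x$config$bf))
  cat(sprintf("  training prevalence %.4f; predictors: %s\n", x$prevalence,
              paste(x$var_names, collapse = ", ")))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV deviance at selection: %.4f (%d folds)\n",
                min(x$cv$curve$cv_deviance), x$config$n_folds))
  }
  invisible(x)
}

# Stratified fold assignment: shuffles each response class separately so
# every fold preserves the prevalence as closely as integer counts allow.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    i <- i[rand_perm(length(i), derive_seed(seed, 97L, cls))]
    fold[i] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

# Deterministic permutation from an integer seed, isolated from the global
# RNG stream.
rand_perm <- function(n, seed) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n)
}

#' Stepwise cross-validated boosted model
#'
#' Grows the ensemble `ss` trees at a time. At each step, `n_folds`
#' stratified training subsets are each extended by `ss` trees and the mean
#' held-out binomial deviance is recorded; growth stops once the held-out
#' deviance has not improved for `patience` steps (or at `max_trees`). The
#' selected tree count is the argmin of the CV deviance curve and the
#' returned model is fit on all data with that many trees. Held-out
#' predictions at the selected size are retained for cross-validated AUC.
#'
#' @param X Predictor data.frame or matrix.
#' @param y Binary response.
#' @param config A [brt_config()].
#' @return A `tidaltag_brt` with a `cv` element: `curve` (data.frame
#'   `n_trees`, `cv_deviance`), `folds`, `cv_link` (held-out logit
#'   predictions at the selected size).
#' @export
step_cv_fit <- function(X, y, config = brt_config()) {
  X <- as_predictor_matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  n <- length(y)
  if (n < 2 * config$n_folds) stop("too few rows for cross-validation")
  if (config$max_trees < config$ss) stop("max_trees smaller than step size")
  folds <- stratified_folds(y, config$n_folds, config$seed)

  intercept_all <- logit(mean(y))
  state <- lapply(seq_len(config$n_folds), function(k) {
    train <- folds != k
    list(train = train,
         F = rep(logit(mean(y[train])), sum(train)),
         hold_link = rep(logit(mean(y[train])), sum(!train)),
         trees = list())
  })
  full <- list(F = rep(intercept_all, n), trees = list())

  curve <- data.frame(n_trees = integer(), cv_deviance = numeric())
  best <- list(dev = Inf, n_trees = 0L, hold = NULL)
  step <- 0L
  repeat {
    step <- step + 1L
    n_total <- step * config$ss
    if (n_total > config$max_trees) break
    hold_link_all <- rep(NA_real_, n)
    for (k in seq_len(config$n_folds)) {
      st <- state[[k]]
      res <- cpp_boost(X[st$train, , drop = FALSE], y[st$train], st$F,
                       config$ss, config$tc, config$lr, config$bf,
                       config$min_obs, derive_seed(config$seed, k, step))
      st$F <- res$F
      st$hold_link <- st$hold_link + config$lr *
        cpp_tree_sum(res$trees, X[!st$train, , drop = FALSE], config$ss)
      st$trees <- c(st$trees, res$trees)
      state[[k]] <- st
      hold_link_all[!st$train] <- st$hold_link
    }
    res_full <- cpp_boost(X, y, full$F, config$ss, config$tc, config$lr,
                          config$bf, config$min_obs,
                          derive_seed(config$seed, 0L, step))
    full$F <- res_full$F
    full$trees <- c(full$trees, res_full$trees)

    cv_dev <- binomial_deviance(y, 1 / (1 + exp(-hold_link_all)))
    curve <- rbind(curve, data.frame(n_trees = n_total, cv_deviance = cv_dev))
    if (cv_dev < best$dev - 1e-12) {
      best <- list(dev = cv_dev, n_trees = n_total, hold = hold_link_all,
                   step = step)
    }
    if (step - (best$step %||% 0L) >= config$patience) break
  }
  if (best$n_trees == 0L) stop("stepwise fit produced no trees")
  structure(list(intercept = intercept_all,
                 trees = full$trees[seq_len(best$n_trees)],
                 lr = config$lr, n_trees_selected = best$n_trees,
                 var_names = colnames(X), config = config,
                 prevalence = mean(y),
                 cv = list(curve = curve, folds = folds,
                           cv_link = best$hold)),
            class = "tidaltag_brt")
}

#' Evaluate a boosted model
#'
#' Training AUC, cross-validated AUC (mean over folds of held-out AUC at
#' the selected ensemble size, when fold predictions are available), their
#' difference (the overfitting gauge), and the proportion of deviance
#' explained `D^2 = 1 - residual/total`, where the total deviance is that
#' of the intercept-only model. Single-class folds are skipped with a
#' warning. AUC bands: < 0.5 fail, 0.6-0.7 poor, 0.7-0.8 acceptable,
#' 0.8-0.9 excellent, > 0.9 outstanding.
#'
#' @param model A `tidaltag_brt`.
#' @param X,y Training predictors and response.
#' @return A list of class `tidaltag_brt_report` with elements `t_auc`,
#'   `cv_auc`, `delta_auc`, `d2`, `residual_deviance`, `total_deviance`,
#'   and qualitative `bands`.
#' @export
evaluate_brt <- function(model, X, y) {
  p <- predict(model, X)
  t_auc <- auc_score(y, p)
  cv_auc <- NA_real_
  if (!is.null(model$cv)) {
    fold_auc <- vapply(sort(unique(model$cv$folds)), function(k) {
      i <- model$cv$folds == k
      if (length(unique(y[i])) < 2) {
        warning("fold ", k, " has a single class; skipped for CV AUC")
        return(NA_real_)
      }
      auc_score(y[i], model$cv$cv_link[i])
    }, 0)
    cv_auc <- mean(fold_auc, na.rm = TRUE)
  }
  residual <- binomial_deviance(y, p)
  total <- binomial_deviance(y, rep(mean(y), length(y)))
  band <- function(a) {
    if (is.na(a)) NA_character_
    else if (a < 0.5) "fail" else if (a < 0.6) "marginal"
    else if (a < 0.7) "poor" else if (a < 0.8) "acceptable"
    else if (a < 0.9) "excellent" else "outstanding"
  }
  structure(list(t_auc = t_auc, cv_auc = cv_auc, delta_auc = t_auc - cv_auc,
                 d2 = 1 - residual / total, residual_deviance = residual,
                 total_deviance = total,
                 bands = c(t_auc = band(t_auc), cv_auc = band(cv_auc))),
            class = "tidaltag_brt_report")
}

#' @export
print.tidaltag_brt_report <- function(x, ...) {
  cat(sprintf("T_AUC %.3f (%s) | CV_AUC %.3f (%s) | dAUC %.3f | D^2 %.3f\n",
              x$t_auc, x$bands[["t_auc"]], x$cv_auc, x$bands[["cv_auc"]],
              x$delta_auc, x$d2))
  invisible(x)
}

#' Hyperparameter grid
#'
#' Cartesian product of the candidate tree complexities, learning rates,
#' bag fractions and step sizes; the defaults give the 144-model grid.
#'
#' @param tc_set,lr_set,bf_set,ss_set Candidate values.
#' @return data.frame with columns `tc`, `lr`, `bf`, `ss`.
#' @export
grid_configs <- function(tc_set = 1:6, lr_set = c(0.01, 0.005, 0.001, 1e-4),
                         bf_set = c(0.5, 0.7, 0.9), ss_set = c(25, 50)) {
  stopifnot(length(tc_set) > 0, length(lr_set) > 0, length(bf_set) > 0,
            length(ss_set) > 0)
  expand.grid(tc = tc_set, lr = lr_set, bf = bf_set, ss = ss_set,
              KEEP.OUT.ATTRS = FALSE)
}

#' Cross-validated hyperparameter grid search
#'
#' Runs [step_cv_fit()] and [evaluate_brt()] for every combination in the
#' grid, ranking by cross-validated AUC (descending) with the overfitting
#' gauge `delta_auc` (ascending) as tiebreak.
#'
#' @param X,y Predictors and response.
#' @param grid data.frame from [grid_configs()].
#' @param base_config A [brt_config()] supplying the non-gridded controls
#'   (folds, max_trees, min_obs, patience, seed).
#' @return data.frame: the grid plus `n_trees`, `t_auc`, `cv_auc`,
#'   `delta_auc`, `d2`, sorted by rank.
#' @export
grid_search <- function(X, y, grid = grid_configs(),
                        base_config = brt_config()) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- brt_config(tc = grid$tc[i], lr = grid$lr[i], bf = grid$bf[i],
                      ss = grid$ss[i], n_folds = base_config$n_folds,
                      max_trees = base_config$max_trees,
                      min_obs = base_config$min_obs,
                      patience = base_config$patience,
                      seed = base_config$seed)
    m <- step_cv_fit(X, y, cfg)
    r <- evaluate_brt(m, X, y)
    cbind(grid[i, , drop = FALSE],
          data.frame(n_trees = m$n_trees_selected, t_auc = r$t_auc,
                     cv_auc = r$cv_auc, delta_auc = r$delta_auc, d2 = r$d2))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cv_auc, out$delta_auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
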