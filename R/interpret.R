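# Post-fit interpretation: relative influence, partial dependence with
# bootstrap bands, pairwise interaction strength, and permutation
# significance of interactions.

#' Relative influence of predictors
#'
#' Per predictor, the summed squared-error improvement of every split using
#' it across the selected trees, normalized to percentages summing to 100.
#'
#' @param model A `tidaltag_brt`.
#' @return data.frame `predictor`, `influence` (percent), sorted descending.
#' @export
relative_influence <- function(model) {
  imp <- setNames(numeric(length(model$var_names)), model$var_names)
  for (t in seq_len(model$n_trees_selected)) {
    tr <- model$trees[[t]]
    split_rows <- tr[, "var"] >= 0
    if (any(split_rows)) {
      v <- tr[split_rows, "var"] + 1 # 0-based in C++
      im <- tr[split_rows, "improve"]
      for (j in seq_along(v)) imp[v[j]] <- imp[v[j]] + im[j]
    }
  }
  if (sum(imp) <= 0) {
    warning("no split improvement recorded; returning uniform influence")
    imp[] <- 1
  }
  out <- data.frame(predictor = names(imp),
                    influence = 100 * as.numeric(imp) / sum(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$influence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Quantile-spaced evaluation grid for one predictor (deduplicated, so ties
# in heavily repeated values collapse).
quantile_grid <- function(x, n_grid) {
  unique(as.numeric(quantile(x, probs = seq(0, 1, length.out = n_grid),
                             type = 7, names = FALSE)))
}

#' Partial dependence of the fitted response on one predictor
#'
#' Default is the at-means profile: all other predictors held at their
#' training means (the values reported alongside the predictor table) while
#' the focal predictor sweeps a quantile-spaced grid, with the fitted
#' response on the probability scale. `others = "marginal"` instead
#' averages logit-scale predictions over the rows of `X` (the
#' data-marginalizing partial dependence, computed on the link scale as is
#' conventional for boosted models) before transforming back; the two
#' profiles then agree up to a constant logit offset for purely additive
#' models.
#'
#' @param model A `tidaltag_brt`.
#' @param predictor Predictor name.
#' @param X Training predictor data.
#' @param n_grid Number of quantile grid points (default 100).
#' @param others `"mean"` (default) or `"marginal"`.
#' @return data.frame of class `tidaltag_pd`: `value`, `fit`.
#' @export
partial_dependence <- function(model, predictor, X, n_grid = 100,
                               others = c("mean", "marginal")) {
  others <- match.arg(others)
  X <- as.data.frame(X)[model$var_names]
  if (!predictor %in% model$var_names) {
    stop("unknown predictor: ", predictor)
  }
  gridv <- quantile_grid(X[[predictor]], n_grid)
  if (others == "mean") {
    nd <- as.data.frame(lapply(X, function(col) rep(mean(col), length(gridv))))
    nd[[predictor]] <- gridv
    fit <- predict(model, nd)
  } else {
    fit <- stats::plogis(vapply(gridv, function(v) {
      nd <- X
      nd[[predictor]] <- v
      mean(predict(model, nd, type = "link"))
    }, 0))
  }
  structure(data.frame(value = gridv, fit = fit),
            predictor = predictor, others = others,
            class = c("tidaltag_pd", "data.frame"))
}

#' Bootstrap confidence band for a partial-dependence curve
#'
#' Case-resampling bootstrap: rows of `(X, y)` are resampled with
#' replacement, the model is refit with the supplied configuration and tree
#' count on each replicate, and pointwise percentile bands are taken over
#' the replicate curves (evaluated on the original data's quantile grid
#' with the other predictors at the original means). Degenerate resamples
#' (single-class response) are redrawn, up to 25 retries. The reported
#' point curve is the replicate median, so the band contains it by
#' construction; the full-data curve is returned alongside.
#'
#' @param X,y Training data.
#' @param predictor Focal predictor name.
#' @param config A [brt_config()]; its seed drives the resampling.
#' @param n_trees Trees per replicate refit.
#' @param n_boot Number of bootstrap replicates (1000 for reports; tests
#'   use fewer).
#' @param level Band coverage (default 0.95).
#' @param n_grid Grid size.
#' @return data.frame of class `tidaltag_pd_band`: `value`, `fit`
#'   (full-data curve), `boot_median`, `lower`, `upper`.
#' @export
pd_bootstrap <- function(X, y, predictor, config = brt_config(),
                         n_trees = 100, n_boot = 1000, level = 0.95,
                         n_grid = 100) {
  X <- as.data.frame(X)
  n <- nrow(X)
  full <- fit_brt(X, y, config, n_trees = n_trees)
  base_curve <- partial_dependence(full, predictor, X, n_grid = n_grid)
  gridv <- base_curve$value
  means <- vapply(X, mean, 0)
  nd <- as.data.frame(lapply(means, rep, length(gridv)))
  names(nd) <- names(X)
  nd[[predictor]] <- gridv

  curves <- matrix(NA_real_, n_boot, length(gridv))
  for (b in seq_len(n_boot)) {
    for (try in seq_len(25)) {
      idx <- 1 + (floor(runif_det(n, derive_seed(config$seed, 811L, b, try)) * n))
      idx[idx > n] <- n
      yb <- y[idx]
      if (length(unique(yb)) == 2) break
      if (try == 25) stop("could not draw a two-class bootstrap resample")
    }
    cfg_b <- config
    cfg_b$seed <- derive_seed(config$seed, 813L, b)
    mb <- fit_brt(X[idx, , drop = FALSE], yb, cfg_b, n_trees = n_trees)
    curves[b, ] <- predict(mb, nd)
  }
  alpha <- (1 - level) / 2
  structure(data.frame(
    value = gridv, fit = base_curve$fit,
    boot_median = apply(curves, 2, median),
    lower = apply(curves, 2, quantile, probs = alpha),
    upper = apply(curves, 2, quantile, probs = 1 - alpha)),
    predictor = predictor, n_boot = n_boot, level = level,
    class = c("tidaltag_pd_band", "data.frame"))
}

# Deterministic uniforms from an integer seed without disturbing the global
# RNG stream.
runif_det <- function(n, seed) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  runif(n)
}

#' Pairwise interaction strength
#'
#' Predictions on an `n_grid` x `n_grid` quantile lattice of the predictor
#' pair (all other predictors at their means, logit scale) are decomposed
#' by least squares into row + column main effects; the interaction size is
#' 1000 times the mean squared residual of that additive fit. Purely
#' additive models therefore score ~0, and the statistic is symmetric in
#' its arguments.
#'
#' @param model A `tidaltag_brt`.
#' @param pair Character vector of two predictor names.
#' @param X Training predictor data.
#' @param n_grid Lattice size per axis (default 20).
#' @return Interaction size (non-negative scalar).
#' @export
interaction_strength <- function(model, pair, X, n_grid = 20) {
  stopifnot(length(pair) == 2)
  X <- as.data.frame(X)[model$var_names]
  if (!all(pair %in% model$var_names)) {
    stop("unknown predictor(s): ", paste(setdiff(pair, model$var_names),
                                         collapse = ", "))
  }
  g1 <- quantile_grid(X[[pair[1]]], n_grid)
  g2 <- quantile_grid(X[[pair[2]]], n_grid)
  lat <- expand.grid(a = g1, b = g2, KEEP.OUT.ATTRS = FALSE)
  nd <- as.data.frame(lapply(X, function(col) rep(mean(col), nrow(lat))))
  nd[[pair[1]]] <- lat$a
  nd[[pair[2]]] <- lat$b
  f <- predict(model, nd, type = "link")
  if (max(f) - min(f) < 1e-12) return(0)
  fit <- lm(f ~ factor(lat$a) + factor(lat$b))
  1000 * mean(fit$residuals^2)
}

#' Interaction strengths for all predictor pairs
#'
#' @inheritParams interaction_strength
#' @return data.frame `pred1`, `pred2`, `size`, sorted descending.
#' @export
interaction_strengths <- function(model, X, n_grid = 20) {
  vars <- model$var_names
  pairs <- utils::combn(vars, 2)
  sizes <- apply(pairs, 2, function(pr) interaction_strength(model, pr, X,
                                                             n_grid))
  out <- data.frame(pred1 = pairs[1, ], pred2 = pairs[2, ], size = sizes,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation significance of a pairwise interaction
#'
#' Builds the null distribution of the interaction size by randomly
#' permuting the response and refitting the model `n_null` times, and
#' reports the add-one permutation p-value
#' `(1 + #(null >= observed)) / (n_null + 1)`. By convention only pairs
#' whose observed size exceeds the screening threshold (100) are worth
#' testing; the function itself tests any pair it is given.
#'
#' @param X,y Training data.
#' @param pair Character vector of two predictor names.
#' @param config A [brt_config()]; seed drives the permutations.
#' @param n_trees Trees per refit.
#' @param n_null Number of null refits (default 100).
#' @param n_grid Lattice size for the interaction statistic.
#' @return List of class `tidaltag_interaction`: `pair`, `size`,
#'   `null_sizes`, `p_value`.
#' @export
interaction_significance <- function(X, y, pair, config = brt_config(),
                                     n_trees = 100, n_null = 100,
                                     n_grid = 20) {
  X <- as.data.frame(X)
  model <- fit_brt(X, y, config, n_trees = n_trees)
  observed <- interaction_strength(model, pair, X, n_grid)
  null_sizes <- vapply(seq_len(n_null), function(b) {
    perm <- rand_perm(length(y), derive_seed(config$seed, 1709L, b))
    cfg_b <- config
    cfg_b$seed <- derive_seed(config$seed, 1721L, b)
    mb <- fit_brt(X, y[perm], cfg_b, n_trees = n_trees)
    interaction_strength(mb, pair, X, n_grid)
  }, 0)
  p <- (1 + sum(null_sizes >= observed)) / (n_null + 1)
  structure(list(pair = pair, size = observed, null_sizes = null_sizes,
                 p_value = p), class = "tidaltag_interaction")
}

#' @export
print.tidaltag_interaction <- function(x, ...) {
  cat(sprintf("Interaction %s x %s: size %.2f, p = %.4f (%d permutations)\n",
              x$pair[1], x$pair[2], x$size, x$p_value, length(x$null_sizes)))
  invisible(x)
}
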