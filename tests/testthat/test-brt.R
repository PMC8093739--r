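# 1-D logistic problem with a known monotone signal.
sim_logistic <- function(n, seed, beta = 2) {
  set.seed(seed)
  x <- rnorm(n)
  p <- stats::plogis(-1 + beta * x)
  list(X = data.frame(x = x), y = rbinom(n, 1, p), p = p)
}

test_that("binomial deviance matches the closed form and the oracle", {
  expect_lt(binomial_deviance(rep(1, 50), rep(1 - 1e-9, 50)), 1e-6)
  expect_equal(binomial_deviance(c(0, 1, 0, 1), rep(0.5, 4)), 2 * log(2))
  set.seed(3)
  y <- rbinom(200, 1, 0.3)
  p <- runif(200)
  expect_equal(binomial_deviance(y, p), oracle_deviance(y, p))
  expect_error(binomial_deviance(c(0, 1), 0.5), "length")
})

test_that("AUC equals the brute-force concordant-pair fraction", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_true(is.na(auc_score(c(1, 1), c(0.3, 0.4))))
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # force ties
    expect_equal(auc_score(y, score), oracle_auc(y, score))
  }
})

test_that("tree splits match exhaustive search on small instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:50, 1)
    X <- data.frame(a = rnorm(n), b = sample(1:4, n, replace = TRUE))
    y <- rbinom(n, 1, stats::plogis(X$a + 0.5 * X$b - 1))
    if (length(unique(y)) < 2) next
    cfg <- brt_config(tc = 1, lr = 1, bf = 1, min_obs = 3, seed = seed)
    m <- fit_brt(X, y, cfg, n_trees = 1)
    tr <- m$trees[[1]]
    r <- y - mean(y) # gradient at the intercept-only model
    want <- oracle_best_split(as.matrix(X), r, min_obs = 3)
    if (is.na(want$var)) {
      expect_equal(unname(tr[1, "var"]), -1)
    } else {
      expect_equal(unname(tr[1, "var"]) + 1, want$var)
      expect_equal(unname(tr[1, "split"]), want$split)
      expect_equal(unname(tr[1, "improve"]), want$improve, tolerance = 1e-9)
    }
  }
})

test_that("a step-function signal is split at its boundary", {
  X <- data.frame(x = c(1:10, 21:30))
  y <- rep(c(0, 1), each = 10)
  m <- fit_brt(X, y, brt_config(tc = 1, lr = 1, bf = 1, min_obs = 2),
               n_trees = 1)
  expect_equal(unname(m$trees[[1]][1, "split"]), 15.5)
  # pure noise with a huge min_obs constraint: single leaf
  m2 <- fit_brt(X, y, brt_config(tc = 1, lr = 1, bf = 1, min_obs = 15),
                n_trees = 1)
  expect_equal(unname(m2$trees[[1]][1, "var"]), -1)
})

test_that("training deviance is monotone non-increasing at bf = 1", {
  d <- sim_logistic(300, seed = 11)
  cfg <- brt_config(tc = 2, lr = 0.1, bf = 1, min_obs = 5, seed = 1)
  devs <- vapply(c(1, 5, 10, 20, 40), function(k) {
    m <- fit_brt(d$X, d$y, cfg, n_trees = k)
    binomial_deviance(d$y, predict(m, d$X))
  }, 0)
  expect_true(all(diff(devs) <= 1e-10))
})

test_that("boosting behaves sanely at the extremes", {
  # response independent of X: training AUC near 1/2 with few trees
  set.seed(5)
  X <- data.frame(x = rnorm(400))
  y <- rbinom(400, 1, 0.3)
  m <- fit_brt(X, y, brt_config(tc = 1, lr = 0.01, bf = 1), n_trees = 5)
  expect_lt(auc_score(y, predict(m, X)), 0.65)
  # separable 1-D problem driven to purity
  Xs <- data.frame(x = c(rnorm(100, -2), rnorm(100, 2)))
  ys <- rep(c(0, 1), each = 100)
  ms <- fit_brt(Xs, ys, brt_config(tc = 1, lr = 0.1, bf = 1), n_trees = 500)
  expect_equal(auc_score(ys, predict(ms, Xs)), 1)
  expect_error(fit_brt(X, rep(1, 400), brt_config()), "constant")
})

test_that("predictions are probabilities and constants are never split on", {
  d <- sim_logistic(200, seed = 21)
  cfg <- brt_config(tc = 2, lr = 0.1, bf = 1, seed = 9)
  m1 <- fit_brt(d$X, d$y, cfg, n_trees = 30)
  X2 <- cbind(d$X, cst = 1)
  m2 <- fit_brt(X2, d$y, cfg, n_trees = 30)
  p1 <- predict(m1, d$X)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(predict(m2, X2), p1)
  inf <- relative_influence(m2)
  expect_equal(inf$influence[inf$predictor == "cst"], 0)
})

test_that("stepwise CV selection finds an interior optimum and is reproducible", {
  d <- sim_logistic(600, seed = 7)
  cfg <- brt_config(tc = 2, lr = 0.05, bf = 0.7, ss = 10, n_folds = 5,
                    max_trees = 400, patience = 4, seed = 42)
  m <- step_cv_fit(d$X, d$y, cfg)
  curve <- m$cv$curve
  expect_equal(m$n_trees_selected,
               curve$n_trees[which.min(curve$cv_deviance)])
  expect_equal(length(m$trees), m$n_trees_selected)
  # rerun with the identical seed: bit-identical selection and trees
  m2 <- step_cv_fit(d$X, d$y, cfg)
  expect_identical(m$n_trees_selected, m2$n_trees_selected)
  expect_identical(m$trees, m2$trees)
  # an aggressive learning rate overfits and is stopped early
  cfg_hot <- brt_config(tc = 2, lr = 0.9, bf = 0.7, ss = 10, n_folds = 5,
                        max_trees = 400, patience = 4, seed = 42)
  m_hot <- step_cv_fit(d$X, d$y, cfg_hot)
  expect_lt(m_hot$n_trees_selected, m$n_trees_selected + 1)
  expect_error(step_cv_fit(d$X[1:12, , drop = FALSE], d$y[1:12],
                           brt_config(n_folds = 10)), "too few")
})

test_that("evaluation reports AUCs, their gap and deviance explained", {
  d <- sim_logistic(600, seed = 13)
  cfg <- brt_config(tc = 2, lr = 0.05, bf = 0.7, ss = 10, n_folds = 5,
                    max_trees = 300, patience = 4, seed = 3)
  m <- step_cv_fit(d$X, d$y, cfg)
  r <- evaluate_brt(m, d$X, d$y)
  expect_equal(r$delta_auc, r$t_auc - r$cv_auc)
  expect_true(r$t_auc >= r$cv_auc - 0.05) # training at least matches CV
  expect_equal(r$d2, 1 - r$residual_deviance / r$total_deviance)
  expect_gt(r$d2, 0)
  # D^2 restated: residual = 0.28 x total gives 0.72
  expect_equal(1 - 0.28, 0.72)
})

test_that("the hyperparameter grid enumerates the full Cartesian product", {
  g <- grid_configs()
  expect_equal(nrow(g), 144)
  expect_equal(nrow(unique(g)), 144)
  # the reported final choice is one of the cells
  expect_true(any(g$tc == 6 & g$lr == 0.005 & g$bf == 0.7 & g$ss == 50))
  expect_equal(nrow(grid_configs(tc_set = 2, lr_set = 0.1, bf_set = 1,
                                 ss_set = 5)), 1)
})

test_that("grid search ranks by CV AUC with the overfitting gauge as tiebreak", {
  d <- sim_logistic(300, seed = 17)
  g <- grid_configs(tc_set = 1:2, lr_set = 0.1, bf_set = 1, ss_set = 10)
  res <- grid_search(d$X, d$y, g,
                     brt_config(n_folds = 4, max_trees = 60, patience = 2,
                                seed = 5))
  expect_equal(nrow(res), 2)
  expect_true(all(c("tc", "lr", "bf", "ss", "n_trees", "t_auc", "cv_auc",
                    "delta_auc", "d2") %in% names(res)))
  expect_true(res$cv_auc[1] >= res$cv_auc[2])
})

test_that("model JSON round-trips predictions exactly", {
  d <- sim_logistic(150, seed = 31)
  m <- fit_brt(d$X, d$y, brt_config(tc = 2, lr = 0.1, bf = 0.8, seed = 2),
               n_trees = 25)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(predict(m2, d$X), predict(m, d$X), tolerance = 1e-12)
})
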