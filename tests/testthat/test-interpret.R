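# Additive two-predictor logistic data (no interaction).
sim_additive <- function(n, seed, b1 = 1.5, b2 = -1) {
  set.seed(seed)
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  p <- stats::plogis(-0.5 + b1 * X$a + b2 * X$b)
  list(X = X, y = rbinom(n, 1, p))
}

# Product-term logistic data.
sim_product <- function(n, seed, bint) {
  set.seed(seed)
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  p <- stats::plogis(-0.5 + 0.5 * X$a + 0.5 * X$b + bint * X$a * X$b)
  list(X = X, y = rbinom(n, 1, p))
}

test_that("relative influence sums to 100 and honours structure", {
  d <- sim_additive(400, seed = 1)
  m <- fit_brt(d$X["a"], d$y, brt_config(tc = 2, lr = 0.1, bf = 1, seed = 1),
               n_trees = 30)
  inf <- relative_influence(m)
  expect_equal(inf$influence, 100) # single predictor takes everything
  m2 <- fit_brt(d$X, d$y, brt_config(tc = 2, lr = 0.1, bf = 1, seed = 1),
                n_trees = 50)
  inf2 <- relative_influence(m2)
  expect_equal(sum(inf2$influence), 100, tolerance = 1e-9)
  expect_true(all(inf2$influence >= 0))
})

test_that("influence of an irrelevant predictor is near zero on average", {
  infl_noise <- vapply(1:15, function(seed) {
    set.seed(seed)
    X <- data.frame(x1 = rnorm(500), x2 = rnorm(500))
    y <- rbinom(500, 1, stats::plogis(2 * X$x1))
    m <- fit_brt(X, y, brt_config(tc = 2, lr = 0.1, bf = 1, seed = seed),
                 n_trees = 40)
    inf <- relative_influence(m)
    inf$influence[inf$predictor == "x2"]
  }, 0)
  expect_lt(mean(infl_noise), 5)
})

test_that("partial dependence profiles behave for known models", {
  d <- sim_additive(500, seed = 3)
  # a model with no splits is flat at the prevalence
  m0 <- fit_brt(d$X, d$y, brt_config(tc = 1, lr = 0.1, bf = 1,
                                     min_obs = 400, seed = 1), n_trees = 5)
  pd0 <- partial_dependence(m0, "a", d$X, n_grid = 20)
  expect_equal(diff(range(pd0$fit)), 0)
  expect_equal(pd0$fit[1], mean(d$y), tolerance = 1e-9)
  # a single-split stump produces a step at the split point
  m1 <- fit_brt(d$X, d$y, brt_config(tc = 1, lr = 1, bf = 1, seed = 1),
                n_trees = 1)
  split <- m1$trees[[1]][1, "split"]
  pd1 <- partial_dependence(m1, "a", d$X, n_grid = 50)
  expect_equal(length(unique(round(pd1$fit, 10))), 2)
  expect_true(all(diff(pd1$fit)[pd1$value[-1] < split] == 0))
  expect_error(partial_dependence(m1, "zz", d$X), "unknown predictor")
})

test_that("at-means and marginal PD agree for additive models", {
  d <- sim_additive(600, seed = 5)
  m <- fit_brt(d$X, d$y, brt_config(tc = 1, lr = 0.1, bf = 1, seed = 2),
               n_trees = 80) # stumps: strictly additive on the link scale
  pd_mean <- partial_dependence(m, "a", d$X, n_grid = 25, others = "mean")
  pd_marg <- partial_dependence(m, "a", d$X, n_grid = 25,
                                others = "marginal")
  # identical shapes up to the monotone link applied at different offsets:
  # compare on the link scale where additivity is exact
  link <- function(p) log(p / (1 - p))
  expect_equal(diff(link(pd_mean$fit)), diff(link(pd_marg$fit)),
               tolerance = 1e-8)
})

test_that("pd bootstrap is reproducible and its band brackets the median", {
  d <- sim_additive(200, seed = 9)
  cfg <- brt_config(tc = 1, lr = 0.2, bf = 1, seed = 7)
  b1 <- pd_bootstrap(d$X, d$y, "a", cfg, n_trees = 15, n_boot = 8,
                     n_grid = 15)
  b2 <- pd_bootstrap(d$X, d$y, "a", cfg, n_trees = 15, n_boot = 8,
                     n_grid = 15)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$boot_median + 1e-12))
  expect_true(all(b1$boot_median <= b1$upper + 1e-12))
})

test_that("pd bootstrap band tightens with sample size under strong signal", {
  width <- vapply(c(300, 3000), function(n) {
    set.seed(1)
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- as.integer(X$a > 0) # noiseless signal
    bb <- pd_bootstrap(X, y, "a", brt_config(tc = 1, lr = 0.3, bf = 1,
                                             seed = 3),
                       n_trees = 20, n_boot = 10, n_grid = 11)
    mean(bb$upper - bb$lower)
  }, 0)
  expect_lt(width[2], width[1])
})

test_that("interaction strength separates additive from product models", {
  # strictly additive model (stumps): interaction size collapses
  d <- sim_additive(600, seed = 11)
  m_add <- fit_brt(d$X, d$y, brt_config(tc = 1, lr = 0.1, bf = 1, seed = 4),
                   n_trees = 60)
  expect_lt(interaction_strength(m_add, c("a", "b"), d$X), 1e-6)
  # size is symmetric in the pair
  dp <- sim_product(800, seed = 13, bint = 1.2)
  m <- fit_brt(dp$X, dp$y, brt_config(tc = 2, lr = 0.1, bf = 1, seed = 4),
               n_trees = 120)
  s_ab <- interaction_strength(m, c("a", "b"), dp$X)
  s_ba <- interaction_strength(m, c("b", "a"), dp$X)
  expect_equal(s_ab, s_ba, tolerance = 1e-9)
  expect_gt(s_ab, 0)
  # strength grows with the product coefficient
  sizes <- vapply(c(0, 0.6, 1.5), function(bint) {
    dd <- sim_product(800, seed = 17, bint = bint)
    mm <- fit_brt(dd$X, dd$y, brt_config(tc = 2, lr = 0.1, bf = 1, seed = 4),
                  n_trees = 120)
    interaction_strength(mm, c("a", "b"), dd$X)
  }, 0)
  expect_true(all(diff(sizes) > 0))
  # one-predictor models cannot interact
  m1 <- fit_brt(d$X["a"], d$y, brt_config(tc = 1, lr = 0.1, bf = 1,
                                          seed = 1), n_trees = 20)
  expect_error(interaction_strength(m1, c("a", "b"), d$X["a"]), "unknown")
})

test_that("permutation test flags a strong product term and bounds p", {
  dp <- sim_product(400, seed = 19, bint = 2)
  cfg <- brt_config(tc = 2, lr = 0.15, bf = 1, seed = 23)
  res <- interaction_significance(dp$X, dp$y, c("a", "b"), cfg,
                                  n_trees = 60, n_null = 49, n_grid = 12)
  expect_lte(res$p_value, 0.02)
  expect_gte(res$p_value, 1 / 50)
  expect_length(res$null_sizes, 49)
})

test_that("permutation test attains its nominal size under the null", {
  # response permuted before analysis: rejections at alpha = 0.2 should be
  # binomial(n_sim, 0.2); with 50 simulations the 99.9% envelope is <= 19
  n_sim <- 50
  rejections <- 0
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    X <- data.frame(a = rnorm(120), b = rnorm(120), c = rnorm(120))
    y <- rbinom(120, 1, 0.25) # independent of X by construction
    cfg <- brt_config(tc = 2, lr = 0.2, bf = 1, min_obs = 5, seed = s)
    res <- interaction_significance(X, y, c("a", "b"), cfg, n_trees = 25,
                                    n_null = 19, n_grid = 8)
    if (res$p_value <= 0.2) rejections <- rejections + 1
  }
  expect_lte(rejections, qbinom(0.999, n_sim, 0.2))
})
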