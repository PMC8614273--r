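test_that("the logistic sex-ratio norm has its definitional anchors", {
  expect_equal(sex_ratio(30.24, P = 30.24, S = 0.4), 0.5)
  expect_equal(sex_ratio(1e6, P = 30.24, S = 0.4), 1)
  expect_equal(sex_ratio(-1e6, P = 30.24, S = 0.4), 0)
  # S chosen so the TRT 5% is 3.84 C wide: 5% females at the lower limit
  expect_equal(sex_ratio(28.32, P = 30.24, S = 0.6521), 0.05,
               tolerance = 1e-3)
  t <- seq(25, 35, by = 0.25)
  expect_true(all(diff(sex_ratio(t, 30.24, 0.652)) > 0))
  expect_error(sex_ratio(30, P = 30, S = 0), "non-zero")
})

test_that("the double-logistic hatching norm peaks between its midpoints", {
  hs <- function(t) hatching_success(t, max_hs = 0.8, p_low = 24.83,
                                     s_low = 1, dp = 8.74, s_high = -1)
  # each transition midpoint sits at ~ MaxHS/2 when well separated
  expect_equal(hs(24.83), 0.4, tolerance = 1e-3)
  expect_equal(hs(24.83 + 8.74), 0.4, tolerance = 1e-3)
  # vanishes at both extremes
  expect_lt(hs(15), 1e-10)
  expect_lt(hs(42), 1e-10)
  # bounded by MaxHS everywhere
  t <- seq(15, 45, by = 0.1)
  expect_true(all(hs(t) >= 0 & hs(t) <= 0.8))
  # unimodal when the transitions are well separated
  d <- diff(hs(t))
  expect_lte(sum(diff(sign(d[abs(d) > 1e-14])) != 0), 1)
  expect_error(hatching_success(30, 0.8, 25, -1, 8, -1), "s_low")
  expect_error(hatching_success(30, 0.8, 25, 1, 8, 1), "s_high")
})

test_that("binomial likelihoods sum per-record terms over usable records", {
  dat <- data.frame(temperature_C = c(29, 31), n_eggs = c(50, 40),
                    n_hatched = c(40, 30), n_sexed = c(20, 25),
                    n_female = c(5, 20), n_male = c(15, 5))
  par <- c(P = 30.24, S = 0.652)
  byhand <- -dbinom(5, 20, sex_ratio(29, 30.24, 0.652), log = TRUE) -
    dbinom(20, 25, sex_ratio(31, 30.24, 0.652), log = TRUE)
  expect_equal(binomial_negloglik(dat, "sex_ratio", par), byhand,
               tolerance = 1e-12)

  parh <- c(max_hs = 0.8, p_low = 24.83, s_low = 1, dp = 8.74, s_high = -1)
  byhand_h <- -sum(dbinom(c(40, 30), c(50, 40),
                          hatching_success(c(29, 31), 0.8, 24.83, 1, 8.74,
                                           -1), log = TRUE))
  expect_equal(binomial_negloglik(dat, "hatching_success", parh), byhand_h,
               tolerance = 1e-12)

  # an unsexed record leaves the sex-ratio likelihood unchanged
  dat2 <- rbind(dat, data.frame(temperature_C = 33, n_eggs = 30,
                                n_hatched = 10, n_sexed = 0, n_female = 0,
                                n_male = 0))
  expect_equal(binomial_negloglik(dat2, "sex_ratio", par),
               binomial_negloglik(dat, "sex_ratio", par))

  # the saturated probability is the per-record minimum
  one <- dat[1, ]
  sat <- -dbinom(5, 20, 5 / 20, log = TRUE)
  for (p in seq(0.05, 0.95, by = 0.05)) {
    P_at <- 29 + 0.652 * log(1 / p - 1)  # P giving sr(29) = p
    val <- binomial_negloglik(one, "sex_ratio", c(P = P_at, S = 0.652))
    expect_gte(val, sat - 1e-9)
  }
})

test_that("TRT closed form matches its definition and numeric inversion", {
  S <- 3.84 / (2 * log(19))
  tr <- trt(P = 30.24, S = S)
  expect_equal(tr$width, 3.84, tolerance = 1e-12)
  expect_equal(tr$upper, 32.16, tolerance = 1e-12)
  expect_equal(tr$lower, 28.32, tolerance = 1e-12)
  # the limits produce exactly l and 1 - l females
  expect_equal(sex_ratio(tr$lower, 30.24, S), 0.05, tolerance = 1e-9)
  expect_equal(sex_ratio(tr$upper, 30.24, S), 0.95, tolerance = 1e-9)
  # width shrinks to zero as l -> 0.5
  expect_lt(trt(30.24, S, l = 0.4999)$width, 1e-3)
  expect_error(trt(30.24, S, l = 0.7), "0, 0.5")

  set.seed(31)
  for (k in 1:50) {
    P <- runif(1, 26, 34); Sg <- runif(1, 0.05, 3); l <- runif(1, 0.01, 0.45)
    tr <- trt(P, Sg, l)
    low <- uniroot(function(t) sex_ratio(t, P, Sg) - l,
                   c(P - 60, P), tol = 1e-12)$root
    up <- uniroot(function(t) sex_ratio(t, P, Sg) - (1 - l),
                  c(P, P + 60), tol = 1e-12)$root
    expect_equal(tr$lower, low, tolerance = 1e-9)
    expect_equal(tr$upper, up, tolerance = 1e-9)
  }
})

test_that("maximum-likelihood fits recover generating norms", {
  # near-noiseless limit: expected counts at huge clutch sizes
  cfg <- scenario_config(seed = 101, eggs_per_temp = 200000,
                        temp_grid = seq(24, 37, length.out = 25))
  inc <- gen_incubation(cfg)
  fs <- fit_norm(inc, "sex_ratio", n_restarts = 5, seed = 2)
  expect_equal(fs$par[["P"]], 30.24, tolerance = 2e-3)
  expect_equal(fs$par[["S"]], TRUE_SEX[["S"]], tolerance = 1e-2)
  fh <- fit_norm(inc, "hatching_success", n_restarts = 5, seed = 2)
  expect_equal(fh$par[["p_low"]], 24.83, tolerance = 0.05)
  expect_equal(fh$par[["p_low"]] + fh$par[["dp"]], 33.57, tolerance = 0.05)
  expect_equal(fh$par[["max_hs"]], 0.8, tolerance = 0.01)
  # definitional check on the fit: sr(P_hat) = 0.5
  expect_equal(sex_ratio(fs$par[["P"]], fs$par[["P"]], fs$par[["S"]]), 0.5)
  # bias shrinks as clutch size grows
  err <- vapply(c(20, 200, 2000), function(n) {
    e <- numeric(5)
    for (s in 1:5) {
      inc_n <- gen_incubation(scenario_config(seed = 300 + 7 * s + n,
                                              eggs_per_temp = n))
      f <- fit_norm(inc_n, "sex_ratio", n_restarts = 3, seed = s)
      e[s] <- abs(f$par[["P"]] - 30.24)
    }
    mean(e)
  }, numeric(1))
  expect_lt(err[3], 0.1)
  expect_lt(err[3], err[1] + 0.05)
  expect_error(fit_norm(inc[1:2, ], "sex_ratio"), "3 distinct")
})

test_that("credible intervals are equal-tailed quantiles of the draws", {
  expect_equal(unname(credible_interval(0:100)), c(2.5, 97.5))
  expect_equal(unname(credible_interval(rep(4.2, 50))), c(4.2, 4.2))
  set.seed(8)
  x <- rnorm(500)
  w1 <- diff(credible_interval(x, level = 0.5))
  w2 <- diff(credible_interval(x, level = 0.9))
  w3 <- diff(credible_interval(x, level = 0.99))
  expect_true(w1 < w2 && w2 < w3)
  expect_error(credible_interval(numeric(0)), "empty")
})

test_that("TRT credible intervals propagate the parameter chain", {
  # degenerate chain: intervals collapse onto that parameter set's TRT
  draws <- cbind(P = rep(30.24, 10), S = rep(0.652, 10))
  tc <- trt_credible(draws)
  tr <- trt(30.24, 0.652)
  expect_equal(unname(tc$width), rep(tr$width, 2))
  expect_equal(unname(tc$lower), rep(tr$lower, 2))
  expect_equal(unname(tc$upper), rep(tr$upper, 2))

  # well-spread chain: the interval contains the point estimate's TRT
  set.seed(12)
  draws2 <- cbind(P = rnorm(2000, 30.24, 0.1),
                  S = abs(rnorm(2000, 0.652, 0.05)))
  tc2 <- trt_credible(draws2)
  expect_lt(tc2$width[["lower"]], tr$width)
  expect_gt(tc2$width[["upper"]], tr$width)
})
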