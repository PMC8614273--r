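test_that("temporal totals follow the three model families", {
  expect_equal(temporal_totals("constant", 100, 2000:2002), rep(100, 3))
  expect_equal(temporal_totals("exponential", c(100, 0), 2000:2002),
               rep(100, 3))
  expect_equal(temporal_totals("exponential", c(100, log(2)), 2000:2002),
               c(100, 200, 400))
  expect_equal(temporal_totals("year_specific", c(5, 7, 9), 2000:2002),
               c(5, 7, 9))
  expect_error(temporal_totals("constant", -5, 2000:2002), "positive")
})

test_that("expected nests multiply totals by simplex proportions", {
  expect_equal(expected_nests(c(3, 8), 1), cbind(c(3, 8)))
  expect_equal(expected_nests(10, c(0.25, 0.75)),
               matrix(c(2.5, 7.5), nrow = 1))
  set.seed(5)
  for (k in 1:10) {
    totals <- rexp(4) + 1
    p <- rexp(3); p <- p / sum(p)
    E <- expected_nests(totals, p)
    expect_equal(rowSums(E), totals, tolerance = 1e-12)
  }
  expect_error(expected_nests(10, c(0.3, 0.3)), "simplex")
})

test_that("the Gaussian likelihood sums over observed cells only", {
  # one cell observed at its expectation with sd ~= 1
  tab <- nest_count_table("b1", 2000, 100)
  nll <- nesting_negloglik(tab, totals = 100, p = 1, a = 1e-12, b = 1)
  expect_equal(nll, 0.5 * log(2 * pi), tolerance = 1e-6)

  # two observed cells, hand-summed
  tab2 <- nest_count_table(c("b1", "b1"), c(2000, 2001), c(12, 20))
  a <- 0.2; b <- 3
  byhand <- -dnorm(12, 15, a * 12 + b, log = TRUE) -
    dnorm(20, 15, a * 20 + b, log = TRUE)
  expect_equal(nesting_negloglik(tab2, totals = c(15, 15), p = 1, a = a,
                                 b = b), byhand, tolerance = 1e-12)

  # a missing cell contributes nothing
  tab3 <- nest_count_table(c("b1", "b1", "b2"), c(2000, 2001, 2000),
                           c(12, 20, 7))
  tab3$N[2, 2] <- NA  # make beach b2 unobserved in 2001
  p <- c(15, 7) / 22
  full <- nesting_negloglik(tab3, c(22, 22), p, a, b)
  tab4 <- tab3
  tab4$N[1, 2] <- NA
  less <- nesting_negloglik(tab4, c(22, 22), p, a, b)
  expect_equal(full - less, -dnorm(7, 7, a * 7 + b, log = TRUE),
               tolerance = 1e-12)
  expect_error(nesting_negloglik(tab3, c(22, 22), p, a = 0, b = 1), "> 0")
})

test_that("a noiseless constant-model table is recovered to high accuracy", {
  p_true <- c(0.5, 0.3, 0.2)
  tab <- toy_nest_table(rep(1000, 4), p_true)
  fit <- fit_nesting_model(tab, "constant", n_restarts = 4, seed = 1)
  expect_equal(unname(fit$p), p_true, tolerance = 1e-3)
  expect_equal(unname(fit$totals), rep(1000, 4), tolerance = 1)
  expect_equal(sum(fit$p), 1, tolerance = 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$n_params, 1 + 2 + 2)
  expect_equal(fit$aic, 2 * fit$n_params + 2 * fit$negloglik)
})

test_that("richer nested families never fit worse", {
  cfg <- scenario_config(n_beaches = 4, n_years = 6, obs_prob = 0.8,
                         temporal_kind = "exponential",
                         temporal_params = c(500, 0.1), seed = 21)
  bv <- gen_beaches(cfg)
  nc <- gen_nest_counts(cfg, bv$beaches)
  tab <- nest_count_table(nc$nests$beach_id, nc$nests$year, nc$nests$nests)
  sel <- select_nesting_model(tab, n_restarts = 3, seed = 2)
  nll <- setNames(sel$table$negloglik, sel$table$model)
  expect_lte(nll[["year_specific"]], nll[["exponential"]] + 1e-6)
  expect_lte(nll[["exponential"]], nll[["constant"]] + 1e-6)
})

test_that("Akaike weights normalise and order as expected", {
  expect_equal(akaike_weights(123.4)$weights, 1)
  expect_equal(akaike_weights(c(10, 10))$weights, c(0.5, 0.5))
  aw <- akaike_weights(c(12, 10, 16))
  expect_equal(aw$delta, c(2, 0, 6))
  expect_equal(sum(aw$weights), 1, tolerance = 1e-12)
  expect_equal(which.max(aw$weights), which.min(aw$delta))
  expect_error(akaike_weights(c(1, NA)), "finite")
})

test_that("model selection favours the generating family and keeps its
           table invariants", {
  cfg <- scenario_config(n_beaches = 4, n_years = 8, obs_prob = 1,
                         temporal_kind = "year_specific",
                         temporal_params = c(200, 2000, 150, 1800, 300,
                                             2500, 100, 1500),
                         a = 0.05, b = 2, seed = 9)
  bv <- gen_beaches(cfg)
  nc <- gen_nest_counts(cfg, bv$beaches)
  tab <- nest_count_table(nc$nests$beach_id, nc$nests$year, nc$nests$nests)
  sel <- select_nesting_model(tab, n_restarts = 3, seed = 5)
  expect_equal(sel$best$kind, "year_specific")
  expect_equal(min(sel$table$delta_aic), 0)
  expect_equal(sum(sel$table$delta_aic == 0), 1)
  expect_true(all(sel$table$delta_aic >= 0))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-9)
  expect_equal(which.max(sel$table$weight), which.min(sel$table$delta_aic))
})

test_that("the nesting index keeps observations and imputes the rest", {
  p_true <- c(0.5, 0.3, 0.2)
  totals <- c(100, 200, 300, 150)
  observed <- matrix(TRUE, 4, 3)
  observed[2, ] <- FALSE       # one fully missing year
  tab <- toy_nest_table(totals, p_true, observed)
  fit <- fit_nesting_model(tab, "year_specific", n_restarts = 4, seed = 3)
  idx <- nesting_index(fit, tab)
  # observed cells pass through untouched
  expect_identical(idx$filled[!idx$imputed], tab$N[!is.na(tab$N)])
  # the fully imputed year is T_i * p, conserving its total
  expect_equal(unname(idx$filled[2, ]), unname(fit$totals[2] * fit$p),
               tolerance = 1e-9)
  expect_equal(sum(idx$filled[2, ]), fit$totals[2], tolerance = 1e-9)
  expect_equal(unname(idx$log10_p), log10(unname(idx$p)))

  # fully observed table: nothing imputed
  tab2 <- toy_nest_table(totals, p_true)
  idx2 <- nesting_index(fit_nesting_model(tab2, "year_specific",
                                          n_restarts = 3, seed = 3), tab2)
  expect_false(any(idx2$imputed))
  expect_equal(idx2$filled, tab2$N)
})

test_that("underdetermined fits warn about identifiability", {
  tab <- nest_count_table(c("a", "b", "c"), c(2000, 2000, 2001),
                          c(10, 20, 30))
  expect_warning(fit_nesting_model(tab, "year_specific", n_restarts = 2,
                                   seed = 1), "unidentifiable")
})
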