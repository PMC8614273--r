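#' Sex ratio at a constant incubation temperature
#'
#' Logistic thermal reaction norm for temperature-dependent sex
#' determination:
#' \deqn{sr(t) = 1 / (1 + e^{(P - t)/S})}
#' returning the expected female proportion. `P` is the pivotal temperature
#' (where both sexes are produced in equal proportion) and `S` controls the
#' steepness of the transition; with `S > 0` warmer incubation gives more
#' females, as in sea turtles.
#'
#' @param t Temperature(s) in degrees C.
#' @param P Pivotal temperature in degrees C.
#' @param S Shape parameter in degrees C; must be non-zero.
#' @return Female proportion(s) in (0, 1).
#' @export
#' @examples
#' sex_ratio(30.24, P = 30.24, S = 0.652)  # 0.5 by definition
sex_ratio <- function(t, P, S) {
  if (any(S == 0)) stop("S must be non-zero", call. = FALSE)
  1 / (1 + exp((P - t) / S))
}

#' Hatching success at a constant incubation temperature
#'
#' Double-logistic thermal reaction norm: a rising transition from 0 to
#' `max_hs` around `p_low` with slope parameter `s_low > 0`, and a falling
#' transition back to 0 around `p_low + dp` with slope parameter
#' `s_high < 0`:
#' \deqn{HS(t) = MaxHS \cdot [1 + e^{4(P_{low}-t)/S_{low}}]^{-1}
#'                     \cdot [1 + e^{4(P_{low}+\Delta P-t)/S_{high}}]^{-1}}
#' The factor 4 makes each `S` the slope of its transition at the midpoint.
#'
#' @param t Temperature(s) in degrees C.
#' @param max_hs Asymptotic hatching success in (0, 1].
#' @param p_low Midpoint of the rising transition (degrees C).
#' @param s_low Slope parameter of the rising transition; > 0.
#' @param dp Separation of the two midpoints (degrees C); > 0.
#' @param s_high Slope parameter of the falling transition; < 0.
#' @return Hatching success in `[0, max_hs]`.
#' @export
#' @examples
#' hatching_success(29, max_hs = 0.8, p_low = 24.83, s_low = 1,
#'                  dp = 8.74, s_high = -1)
hatching_success <- function(t, max_hs, p_low, s_low, dp, s_high) {
  if (any(s_low <= 0)) stop("s_low must be > 0", call. = FALSE)
  if (any(s_high >= 0)) stop("s_high must be < 0", call. = FALSE)
  if (any(dp <= 0)) stop("dp must be > 0", call. = FALSE)
  max_hs / (1 + exp(4 * (p_low - t) / s_low)) /
    (1 + exp(4 * (p_low + dp - t) / s_high))
}

# Model probabilities are clamped away from 0/1 inside the binomial
# log-likelihood so observed successes at extreme temperatures cannot
# produce -Inf.
PROB_FLOOR <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)

#' Binomial negative log-likelihood of incubation outcomes
#'
#' For the sex-ratio norm, each record with sexed hatchlings contributes
#' `-log Binom(n_female; n_sexed, sr(t))`; for the hatching-success norm,
#' each record with incubated eggs contributes
#' `-log Binom(n_hatched; n_eggs, HS(t))`. Records with a zero denominator
#' are ignored.
#'
#' @param data Incubation data frame with columns `temperature_C`,
#'   `n_eggs`, `n_hatched`, `n_sexed`, `n_female`, `n_male` (see
#'   [read_incubation()] / [gen_incubation()]).
#' @param which `"sex_ratio"` or `"hatching_success"`.
#' @param par Named parameter vector: `c(P=, S=)` for the sex ratio,
#'   `c(max_hs=, p_low=, s_low=, dp=, s_high=)` for hatching success.
#' @return Summed negative log-likelihood.
#' @export
binomial_negloglik <- function(data, which = c("sex_ratio",
                                               "hatching_success"), par) {
  which <- match.arg(which)
  if (which == "sex_ratio") {
    use <- data$n_sexed > 0
    if (!any(use)) stop("no records with sexed hatchlings", call. = FALSE)
    pr <- clamp_prob(sex_ratio(data$temperature_C[use], par[["P"]],
                               par[["S"]]))
    -sum(dbinom(data$n_female[use], data$n_sexed[use], pr, log = TRUE))
  } else {
    use <- data$n_eggs > 0
    if (!any(use)) stop("no records with incubated eggs", call. = FALSE)
    pr <- clamp_prob(hatching_success(data$temperature_C[use],
                                      par[["max_hs"]], par[["p_low"]],
                                      par[["s_low"]], par[["dp"]],
                                      par[["s_high"]]))
    -sum(dbinom(data$n_hatched[use], data$n_eggs[use], pr, log = TRUE))
  }
}

# Box bounds shared by the ML fit and the MCMC priors. Sex-ratio bounds are
# broad enough to span all reported turtle pivotal temperatures; the
# hatching-success bounds are the uniform prior supports.
norm_bounds <- function(which) {
  if (which == "sex_ratio") {
    list(lower = c(P = 25, S = 0.01), upper = c(P = 35, S = 5))
  } else {
    list(lower = c(max_hs = 1e-6, p_low = 20, s_low = 1e-6, dp = 1e-6,
                   s_high = -5),
         upper = c(max_hs = 1, p_low = 40, s_low = 5, dp = 10,
                   s_high = -1e-6))
  }
}

norm_start <- function(data, which) {
  if (which == "sex_ratio") {
    use <- data$n_sexed > 0
    t <- data$temperature_C[use]
    f <- data$n_female[use] / data$n_sexed[use]
    # temperature whose observed female fraction is nearest 0.5
    P0 <- t[which.min(abs(f - 0.5))]
    c(P = min(max(P0, 25.5), 34.5), S = 0.6)
  } else {
    use <- data$n_eggs > 0
    t <- data$temperature_C[use]
    h <- data$n_hatched[use] / data$n_eggs[use]
    top <- max(h)
    half <- top / 2
    above <- t[h >= half]
    p_low0 <- if (length(above)) min(above) - 0.5 else min(t)
    dp0 <- if (length(above)) max(above) - min(above) + 1 else 5
    c(max_hs = min(max(top, 0.05), 0.999),
      p_low = min(max(p_low0, 20.5), 39), s_low = 1,
      dp = min(max(dp0, 0.5), 9.5), s_high = -1)
  }
}

#' Fit a thermal reaction norm by binomial maximum likelihood
#'
#' Minimises [binomial_negloglik()] over the norm's parameters within their
#' box bounds (the same supports used as uniform priors by [mh_sample()]),
#' using L-BFGS-B from a data-driven start plus several random restarts
#' drawn uniformly within the bounds.
#'
#' @inheritParams binomial_negloglik
#' @param n_restarts Number of additional random starts.
#' @param seed Integer seed controlling the restarts.
#' @param init Optional named starting vector overriding the data-driven
#'   start.
#' @return Object of class `norm_fit`: list with `which`, `par`,
#'   `negloglik`, `aic`, `converged`, `n_records`.
#' @export
fit_norm <- function(data, which = c("sex_ratio", "hatching_success"),
                     n_restarts = 10, seed = NULL, init = NULL) {
  which <- match.arg(which)
  use <- if (which == "sex_ratio") data$n_sexed > 0 else data$n_eggs > 0
  if (length(unique(data$temperature_C[use])) < 3L) {
    stop("need records at >= 3 distinct temperatures", call. = FALSE)
  }
  bd <- norm_bounds(which)
  obj <- function(par) {
    v <- binomial_negloglik(data, which, setNames(par, names(bd$lower)))
    if (!is.finite(v)) 1e12 else v
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- list(if (is.null(init)) norm_start(data, which)
                 else init[names(bd$lower)])
  for (k in seq_len(n_restarts)) {
    starts[[k + 1L]] <- bd$lower + runif(length(bd$lower)) *
      (bd$upper - bd$lower)
  }
  best <- NULL
  codes <- integer(length(starts))
  for (k in seq_along(starts)) {
    fit <- tryCatch(
      optim(starts[[k]], obj, method = "L-BFGS-B",
            lower = bd$lower, upper = bd$upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) { codes[k] <- 99L; next }
    codes[k] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  par <- setNames(best$par, names(bd$lower))
  structure(list(which = which, par = par, negloglik = best$value,
                 aic = 2 * length(par) + 2 * best$value,
                 converged = any(codes == 0L), convergence_codes = codes,
                 n_records = sum(use)),
            class = "norm_fit")
}

#' @export
print.norm_fit <- function(x, ...) {
  cat(sprintf("Thermal reaction norm (%s), %d records, -lnL = %.3f\n",
              x$which, x$n_records, x$negloglik))
  print(round(x$par, 4))
  if (x$which == "sex_ratio") {
    tr <- trt(x$par[["P"]], x$par[["S"]])
    cat(sprintf("  pivotal %.2f C, TRT5%% %.2f C (%.2f-%.2f C)\n",
                x$par[["P"]], tr$width, tr$lower, tr$upper))
  }
  if (!x$converged) cat("  warning: no start reported convergence\n")
  invisible(x)
}

#' Transitional range of temperatures
#'
#' Under the symmetric logistic sex-ratio norm, the temperatures producing
#' female proportions `l` and `1 - l` have the closed form
#' `P -/+ |S| * log((1 - l)/l)`, so the TRT width is
#' `2 |S| log((1 - l)/l)`. The default `l = 0.05` gives the TRT 5%, the
#' range producing 5% to 95% of each sex.
#'
#' @param P Pivotal temperature (degrees C).
#' @param S Logistic shape parameter (degrees C).
#' @param l Tail proportion, in (0, 0.5).
#' @return List with `level`, `lower`, `upper`, `width` (degrees C).
#' @export
#' @examples
#' trt(P = 30.24, S = 3.84 / (2 * log(19)))  # TRT 5% of width 3.84 C
trt <- function(P, S, l = 0.05) {
  if (l <= 0 || l >= 0.5) stop("l must be in (0, 0.5)", call. = FALSE)
  half <- abs(S) * log((1 - l) / l)
  list(level = l, lower = P - half, upper = P + half, width = 2 * half)
}

#' Equal-tailed credible interval from a posterior chain
#'
#' @param chain A `posterior_chain` from [mh_sample()], or a numeric
#'   vector/matrix of retained draws.
#' @param param Column name or index when `chain` has several parameters.
#' @param level Credibility level (default 0.95, i.e. the 2.5% and 97.5%
#'   quantiles).
#' @return Named vector `c(lower, upper)`.
#' @export
credible_interval <- function(chain, param = 1L, level = 0.95) {
  draws <- if (inherits(chain, "posterior_chain")) chain$draws else chain
  x <- if (is.matrix(draws)) draws[, param] else draws
  if (length(x) == 0L) stop("empty chain", call. = FALSE)
  alpha <- (1 - level) / 2
  q <- quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Credible intervals for TRT quantities
#'
#' Propagates a posterior chain over the sex-ratio parameters (columns `P`
#' and `S`) through [trt()], then summarises the derived lower limit, upper
#' limit and width with equal-tailed credible intervals.
#'
#' @param chain A `posterior_chain` (or matrix) with columns `P` and `S`.
#' @param l Tail proportion for the TRT.
#' @param level Credibility level.
#' @return List with per-quantity intervals (`lower`, `upper`, `width`) and
#'   the matrix of derived draws.
#' @export
trt_credible <- function(chain, l = 0.05, level = 0.95) {
  draws <- if (inherits(chain, "posterior_chain")) chain$draws else chain
  half <- abs(draws[, "S"]) * log((1 - l) / l)
  derived <- cbind(lower = draws[, "P"] - half,
                   upper = draws[, "P"] + half,
                   width = 2 * half)
  list(lower = credible_interval(derived, "lower", level),
       upper = credible_interval(derived, "upper", level),
       width = credible_interval(derived, "width", level),
       draws = derived)
}
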