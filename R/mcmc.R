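#' Configuration for the Metropolis-Hastings sampler
#'
#' @param n_iter Number of retained iterations after burn-in.
#' @param burn_in Iterations discarded (and used for proposal adaptation).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param proposal_sd Initial Gaussian proposal standard deviation, one per
#'   parameter (recycled). During burn-in each scale is adjusted every 100
#'   iterations toward a 0.2--0.5 acceptance rate; scales are frozen after
#'   burn-in so the retained chain is a valid Metropolis-Hastings sample.
#' @param seed Integer seed; the chain is fully reproducible given it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 40000, burn_in = 10000, thin = 1,
                        proposal_sd = 0.1, seed = 1) {
  stopifnot(n_iter >= 1, burn_in >= 0, thin >= 1)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 proposal_sd = proposal_sd, seed = seed),
            class = "mcmc_config")
}

#' Metropolis-Hastings sampling under uniform priors
#'
#' Random-walk Metropolis-Hastings with Gaussian proposals, updating one
#' parameter at a time. Priors are independent uniforms on `[lower, upper]`;
#' a proposal outside its support is rejected outright, which is the
#' Metropolis rule for a flat prior with bounded support. Used to obtain
#' credible intervals for the thermal reaction norms, whose likelihood is
#' supplied as a negative log-likelihood function.
#'
#' @param negloglik Function of the full parameter vector returning the
#'   negative log-likelihood (the target is `exp(-negloglik)` times the
#'   uniform prior).
#' @param lower,upper Named numeric vectors of prior bounds.
#' @param init Starting values inside the support; defaults to the
#'   mid-point of each interval.
#' @param config An [mcmc_config()].
#' @return Object of class `posterior_chain`: list with `draws` (matrix of
#'   retained draws, one column per parameter), `acceptance` (per-parameter
#'   post-burn-in acceptance rate), `proposal_sd` (adapted scales),
#'   `config`.
#' @export
#' @examples
#' chain <- mh_sample(function(p) 0.5 * p^2, lower = c(x = -10),
#'                    upper = c(x = 10),
#'                    config = mcmc_config(n_iter = 2000, burn_in = 500,
#'                                         seed = 7))
#' credible_interval(chain, "x")
mh_sample <- function(negloglik, lower, upper, init = NULL,
                      config = mcmc_config()) {
  if (length(lower) != length(upper) || any(upper <= lower)) {
    stop("prior bounds must satisfy lower < upper", call. = FALSE)
  }
  npar <- length(lower)
  pnames <- names(lower)
  if (is.null(init)) init <- (lower + upper) / 2
  init <- as.numeric(init)
  if (any(init < lower) || any(init > upper)) {
    stop("initial point outside the prior support", call. = FALSE)
  }
  cur <- init
  cur_nll <- negloglik(cur)
  if (!is.finite(cur_nll)) {
    stop("negloglik not finite at the initial point", call. = FALSE)
  }
  scales <- rep_len(config$proposal_sd, npar)
  set.seed(config$seed)
  total <- config$burn_in + config$n_iter * config$thin
  keep <- matrix(NA_real_, nrow = config$n_iter, ncol = npar,
                 dimnames = list(NULL, pnames))
  acc <- integer(npar)       # post-burn-in acceptances
  prop_count <- integer(npar)
  acc_win <- integer(npar)   # burn-in adaptation window
  win_count <- integer(npar)
  kept <- 0L
  for (it in seq_len(total)) {
    in_burn <- it <= config$burn_in
    for (k in seq_len(npar)) {
      prop <- cur
      prop[k] <- cur[k] + rnorm(1, sd = scales[k])
      accepted <- FALSE
      if (prop[k] >= lower[k] && prop[k] <= upper[k]) {
        prop_nll <- negloglik(prop)
        if (is.finite(prop_nll) &&
            log(runif(1)) < cur_nll - prop_nll) {
          cur <- prop
          cur_nll <- prop_nll
          accepted <- TRUE
        } else if (!is.finite(prop_nll)) {
          # rejected; burn the uniform draw for reproducibility symmetry
        }
      } else {
        runif(1)  # keep the random stream aligned across branches
      }
      if (in_burn) {
        acc_win[k] <- acc_win[k] + accepted
        win_count[k] <- win_count[k] + 1L
        if (win_count[k] == 100L) {
          rate <- acc_win[k] / 100
          if (rate > 0.5) scales[k] <- scales[k] * 1.3
          if (rate < 0.2) scales[k] <- scales[k] * 0.7
          acc_win[k] <- 0L
          win_count[k] <- 0L
        }
      } else {
        acc[k] <- acc[k] + accepted
        prop_count[k] <- prop_count[k] + 1L
      }
    }
    if (!in_burn && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      keep[kept, ] <- cur
    }
  }
  structure(list(draws = keep,
                 acceptance = setNames(acc / pmax(prop_count, 1L), pnames),
                 proposal_sd = setNames(scales, pnames),
                 config = config),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d draws x %d parameters\n",
              nrow(x$draws), ncol(x$draws)))
  cat("  acceptance:", paste(sprintf("%s %.2f", colnames(x$draws),
                                     x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior chain for a fitted reaction norm
#'
#' Convenience wrapper running [mh_sample()] on the binomial likelihood of
#' an incubation dataset, with the norm's box bounds as uniform priors and
#' the maximum-likelihood fit as the starting point.
#'
#' @inheritParams binomial_negloglik
#' @param fit Optional `norm_fit` to start from; fitted if missing.
#' @param config An [mcmc_config()].
#' @return A `posterior_chain` with one column per norm parameter.
#' @export
sample_norm_posterior <- function(data, which = c("sex_ratio",
                                                  "hatching_success"),
                                  fit = NULL, config = mcmc_config()) {
  which <- match.arg(which)
  if (is.null(fit)) fit <- fit_norm(data, which, seed = config$seed)
  bd <- norm_bounds(which)
  nll <- function(par) {
    binomial_negloglik(data, which, setNames(par, names(bd$lower)))
  }
  init <- pmin(pmax(fit$par, bd$lower), bd$upper)
  mh_sample(nll, bd$lower, bd$upper, init = init, config = config)
}
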