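#' Build a nest-count table from long records
#'
#' Assembles sparse beach-by-year nest counts into the year x beach matrix
#' `N[i, j]` used by the nesting model, with `NA` marking unobserved
#' beach-year cells. Most cells are typically missing: survey effort in the
#' region is sparse and the years with data differ between beaches, which is
#' what the model is built to bridge.
#'
#' @param beach_id Character vector of beach identifiers.
#' @param year Integer vector of years.
#' @param nests Non-negative counts of nests observed.
#' @param beaches,years Optional full sets of beaches and years defining
#'   the grid (defaults to those present in the observations); supply them
#'   to keep beaches or seasons that were never surveyed in the model.
#' @return An object of class `nest_count_table`: a list with `beaches`,
#'   `years` and the matrix `N` (rows = years, columns = beaches).
#' @export
#' @examples
#' nest_count_table(c("a", "a", "b"), c(2000, 2001, 2000), c(10, 12, 5))
nest_count_table <- function(beach_id, year, nests, beaches = NULL,
                             years = NULL) {
  if (length(beach_id) == 0L) {
    stop("at least one observation is required", call. = FALSE)
  }
  if (length(year) != length(beach_id) || length(nests) != length(beach_id)) {
    stop("beach_id, year and nests must have equal length", call. = FALSE)
  }
  if (anyNA(nests) || any(nests < 0)) {
    stop("nest counts must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(beaches)) beaches <- sort(unique(as.character(beach_id)))
  if (is.null(years)) years <- sort(unique(as.integer(year)))
  if (!all(as.character(beach_id) %in% beaches) ||
      !all(as.integer(year) %in% years)) {
    stop("observations outside the supplied beach/year grid", call. = FALSE)
  }
  N <- matrix(NA_real_, nrow = length(years), ncol = length(beaches),
              dimnames = list(years, beaches))
  i <- match(as.integer(year), years)
  j <- match(as.character(beach_id), beaches)
  if (anyDuplicated(cbind(i, j))) {
    stop("duplicate beach-year observations", call. = FALSE)
  }
  N[cbind(i, j)] <- as.numeric(nests)
  structure(list(beaches = beaches, years = years, N = N),
            class = "nest_count_table")
}

#' @export
print.nest_count_table <- function(x, ...) {
  cat(sprintf("Nest-count table: %d beaches x %d years, %d observed cells (%.0f%%)\n",
              length(x$beaches), length(x$years), sum(!is.na(x$N)),
              100 * mean(!is.na(x$N))))
  invisible(x)
}

#' Annual nest totals under a temporal model
#'
#' The regional total `T_i` for year `i` follows one of three families:
#' `constant` (`T_i = T`, one parameter), `exponential`
#' (`T_i = T_0 * exp(r * i)` with `i` counted from 0 at the first year; two
#' parameters) or `year_specific` (one free total per year).
#'
#' @param kind One of `"constant"`, `"exponential"`, `"year_specific"`.
#' @param params Numeric parameters: `T`; `c(T0, r)`; or `T_1..T_Y`.
#' @param years Vector of years (only its length and order matter).
#' @return Vector of totals, one per year.
#' @export
#' @examples
#' temporal_totals("exponential", c(100, log(2)), 2000:2002)
temporal_totals <- function(kind, params, years) {
  kind <- match.arg(kind, c("constant", "exponential", "year_specific"))
  ny <- length(years)
  totals <- switch(kind,
    constant = {
      stopifnot(length(params) == 1L)
      rep(params[1], ny)
    },
    exponential = {
      stopifnot(length(params) == 2L)
      params[1] * exp(params[2] * (seq_len(ny) - 1))
    },
    year_specific = {
      stopifnot(length(params) == ny)
      as.numeric(params)
    })
  if (any(!is.finite(totals)) || any(totals <= 0)) {
    stop("annual totals must be finite and positive", call. = FALSE)
  }
  totals
}

#' Expected nests per beach and year
#'
#' Under time-constant beach proportions, the expected count for year `i`
#' on beach `j` is `E[i, j] = T_i * p_j`, so each row sums to the annual
#' total.
#'
#' @param totals Vector of annual totals `T_i` (positive).
#' @param p Beach proportions on the simplex (non-negative, summing to 1).
#' @return Matrix `E` with `length(totals)` rows and `length(p)` columns.
#' @export
expected_nests <- function(totals, p) {
  if (any(totals <= 0)) stop("totals must be positive", call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("p must lie on the unit simplex", call. = FALSE)
  }
  outer(as.numeric(totals), as.numeric(p))
}

#' Negative log-likelihood of observed nest counts
#'
#' Gaussian model for the observed counts: each observed cell contributes
#' `-log dnorm(N_ij; mean = E_ij, sd = S_ij)` with `S_ij = a * N_ij + b`
#' (the dispersion grows with the observed count; a zero count has
#' dispersion `b`). Missing cells contribute nothing.
#'
#' @param table A [nest_count_table()].
#' @param totals Annual totals `T_i`.
#' @param p Beach proportions on the simplex.
#' @param a,b Dispersion parameters, both strictly positive.
#' @return The summed negative log-likelihood.
#' @export
nesting_negloglik <- function(table, totals, p, a, b) {
  if (!inherits(table, "nest_count_table")) {
    stop("table must be a nest_count_table", call. = FALSE)
  }
  if (a <= 0 || b <= 0) stop("a and b must be > 0", call. = FALSE)
  E <- expected_nests(totals, p)
  obs <- !is.na(table$N)
  n <- table$N[obs]
  s <- a * n + b
  nll <- -sum(dnorm(n, mean = E[obs], sd = s, log = TRUE))
  if (!is.finite(nll)) stop("non-finite likelihood", call. = FALSE)
  nll
}

# --- internal parameterization -------------------------------------------
# theta = c(temporal block, z (K-1 logit-simplex values), log a, log b)
#   constant:      log T
#   exponential:   log T0, r
#   year_specific: log T_1 .. log T_Y
# Positivity of totals, a, b enforced by the log scale; p by the additive
# logistic transform (softmax with a fixed last coordinate at 0).

softmax_simplex <- function(z) {
  w <- c(z, 0)
  w <- exp(w - max(w))
  w / sum(w)
}

n_temporal_params <- function(kind, ny) {
  switch(kind, constant = 1L, exponential = 2L, year_specific = ny)
}

theta_unpack <- function(theta, kind, ny, nb, b_min = 0) {
  nt <- n_temporal_params(kind, ny)
  tpar <- theta[seq_len(nt)]
  z <- theta[nt + seq_len(nb - 1L)]
  ab <- exp(theta[nt + nb - 1L + 1:2])
  params <- switch(kind,
    constant = exp(tpar),
    exponential = c(exp(tpar[1]), tpar[2]),
    year_specific = exp(tpar))
  list(params = params, p = softmax_simplex(z), a = ab[1],
       b = b_min + ab[2])
}

theta_objective <- function(table, kind, b_min = 0) {
  ny <- length(table$years)
  nb <- length(table$beaches)
  obs <- !is.na(table$N)
  n <- table$N[obs]
  function(theta) {
    q <- theta_unpack(theta, kind, ny, nb, b_min)
    totals <- switch(kind,
      constant = rep(q$params[1], ny),
      exponential = q$params[1] * exp(q$params[2] * (seq_len(ny) - 1)),
      year_specific = q$params)
    if (any(!is.finite(totals)) || any(totals <= 0)) return(1e12)
    E <- outer(totals, q$p)
    s <- q$a * n + q$b
    nll <- -sum(dnorm(n, mean = E[obs], sd = s, log = TRUE))
    if (!is.finite(nll)) 1e12 else nll
  }
}

theta_init <- function(table, kind, jitter = 0, b_min = 0) {
  N <- table$N
  ny <- nrow(N)
  cm <- apply(N, 2, mean, na.rm = TRUE)
  cm[!is.finite(cm) | cm <= 0] <- max(mean(N, na.rm = TRUE), 1e-3)
  p0 <- cm / sum(cm)
  t0 <- vapply(seq_len(ny), function(i) {
    j <- which(!is.na(N[i, ]))
    if (length(j) == 0) NA_real_ else sum(N[i, j]) / sum(p0[j])
  }, numeric(1))
  t0[!is.finite(t0) | t0 <= 0] <- mean(t0[is.finite(t0) & t0 > 0])
  if (all(!is.finite(t0))) t0 <- rep(sum(N, na.rm = TRUE), ny)
  tblock <- switch(kind,
    constant = log(mean(t0)),
    exponential = c(log(t0[1]),
                    if (ny > 1) (log(t0[ny]) - log(t0[1])) / (ny - 1) else 0),
    year_specific = log(t0))
  z <- log(p0[-length(p0)]) - log(p0[length(p0)])
  resid_sd <- max(sd(N[!is.na(N)]) / 2, 1e-2)
  theta <- c(tblock, z, log(0.2), log(max(resid_sd - b_min, 1e-2)))
  if (jitter > 0) theta <- theta + rnorm(length(theta), sd = jitter)
  theta
}

#' Fit a spatio-temporal nesting model
#'
#' Maximises the Gaussian likelihood of [nesting_negloglik()] over the
#' annual totals (one of the three temporal families), the time-constant
#' beach proportions `p_j` and the dispersion parameters `a`, `b`.
#' Proportions are optimised through the additive-logistic transform, so
#' they stay on the simplex; totals and `a`, `b` are optimised on the log
#' scale. Because the likelihood can be multimodal for sparse tables, the
#' optimiser is restarted from several jittered starting points and the
#' best local optimum is reported.
#'
#' @param table A [nest_count_table()].
#' @param kind Temporal family: `"constant"`, `"exponential"` or
#'   `"year_specific"`.
#' @param n_restarts Number of random restarts (first start is
#'   deterministic, the rest are jittered).
#' @param seed Integer seed controlling the restarts.
#' @param init Optional full starting vector on the internal scale
#'   (overrides the deterministic first start).
#' @param extra_starts Optional list of additional starting vectors on the
#'   internal scale, e.g. a simpler nested model's optimum embedded in this
#'   family's parameter space.
#' @param b_min Lower bound on the dispersion floor `b` (default 0.5, the
#'   rounding resolution of an integer count). Without it the likelihood is
#'   unbounded whenever some beach only ever shows zero counts: the fit can
#'   drive that beach's proportion and `b` jointly to zero and spike the
#'   Gaussian density on every zero cell.
#' @return An object of class `nesting_fit` with the fitted totals,
#'   proportions `p`, dispersion `a`, `b`, `negloglik`, `n_params`, `aic`
#'   and convergence diagnostics.
#' @export
fit_nesting_model <- function(table, kind = c("constant", "exponential",
                                              "year_specific"),
                              n_restarts = 10, seed = NULL, init = NULL,
                              extra_starts = list(), b_min = 0.5) {
  kind <- match.arg(kind)
  stopifnot(b_min >= 0)
  ny <- length(table$years)
  nb <- length(table$beaches)
  n_obs <- sum(!is.na(table$N))
  n_params <- n_temporal_params(kind, ny) + (nb - 1L) + 2L
  identifiable <- n_obs >= n_params
  if (!identifiable) {
    warning(sprintf(
      "only %d observations for %d parameters; fit may be unidentifiable",
      n_obs, n_params), call. = FALSE)
  }
  obj <- theta_objective(table, kind, b_min)
  if (!is.null(seed)) set.seed(seed)
  starts <- vector("list", n_restarts)
  starts[[1]] <- if (is.null(init)) theta_init(table, kind, b_min = b_min)
                 else init
  for (k in seq_len(n_restarts - 1L)) {
    starts[[k + 1L]] <- theta_init(table, kind, jitter = 0.3, b_min = b_min)
  }
  starts <- c(starts, extra_starts)
  best <- NULL
  codes <- integer(n_restarts)
  for (k in seq_along(starts)) {
    fit <- optim(starts[[k]], obj, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))
    fit <- optim(fit$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    codes[k] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  q <- theta_unpack(best$par, kind, ny, nb, b_min)
  totals <- temporal_totals(kind, q$params, table$years)
  structure(list(
    kind = kind,
    totals = totals,
    params = q$params,
    p = setNames(q$p, table$beaches),
    a = q$a, b = q$b,
    negloglik = best$value,
    b_min = b_min,
    n_params = n_params,
    aic = 2 * n_params + 2 * best$value,
    n_obs = n_obs,
    identifiable = identifiable,
    converged = any(codes == 0L),
    convergence_codes = codes,
    theta = best$par,
    table_dim = c(years = ny, beaches = nb)
  ), class = "nesting_fit")
}

#' @export
print.nesting_fit <- function(x, ...) {
  cat(sprintf("Nesting model (%s): %d parameters, -lnL = %.3f, AIC = %.3f\n",
              x$kind, x$n_params, x$negloglik, x$aic))
  cat(sprintf("  dispersion: sd = %.3g * N + %.3g; %d observations\n",
              x$a, x$b, x$n_obs))
  if (!x$identifiable) {
    cat("  warning: fewer observations than parameters\n")
  }
  invisible(x)
}

#' Akaike differences and weights
#'
#' Converts a set of AIC values into differences from the best model and the
#' relative probability that each model is the best of those compared:
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))`.
#'
#' @param aic Numeric vector of finite AIC values.
#' @return A list with `delta` and `weights` (both in input order; weights
#'   sum to 1).
#' @export
#' @examples
#' akaike_weights(c(2254.397, 2247.399, 2241.867))
akaike_weights <- function(aic) {
  aic <- as.numeric(aic)
  if (length(aic) == 0L || any(!is.finite(aic))) {
    stop("all AIC values must be finite", call. = FALSE)
  }
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  list(delta = delta, weights = w / sum(w))
}

#' Fit and compare the temporal model families
#'
#' Fits each requested temporal family to the same nest-count table,
#' assembles the AIC model-selection table with Akaike weights, and returns
#' the minimum-AIC fit.
#'
#' @inheritParams fit_nesting_model
#' @param kinds Character vector of at least two temporal families.
#' @return An object of class `nesting_selection`: list with `table` (data
#'   frame of model, n_params, negloglik, aic, delta_aic, weight), `fits`,
#'   and `best` (the min-AIC `nesting_fit`).
#' @export
select_nesting_model <- function(table,
                                 kinds = c("constant", "exponential",
                                           "year_specific"),
                                 n_restarts = 10, seed = NULL,
                                 b_min = 0.5) {
  if (length(kinds) < 2L) stop("need at least two models", call. = FALSE)
  order_kinds <- intersect(c("constant", "exponential", "year_specific"),
                           kinds)
  ny <- length(table$years)
  fits <- list()
  # The families are nested (constant = exponential at r = 0; exponential
  # totals are representable year-specifically), so each richer family also
  # starts from the best simpler optimum embedded in its parameter space.
  for (kind in order_kinds) {
    extra <- list()
    if (kind == "exponential" && !is.null(fits$constant)) {
      th <- fits$constant$theta
      extra <- c(extra, list(c(th[1], 0, th[-1])))
    }
    if (kind == "year_specific") {
      for (sub in fits[intersect(c("constant", "exponential"),
                                 names(fits))]) {
        extra <- c(extra, list(c(log(sub$totals), sub$theta[-seq_len(
          n_temporal_params(sub$kind, ny))])))
      }
    }
    fits[[kind]] <- fit_nesting_model(
      table, kind, n_restarts = n_restarts,
      seed = if (is.null(seed)) NULL else seed + match(kind, order_kinds),
      extra_starts = extra, b_min = b_min)
  }
  fits <- fits[kinds]
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  aw <- akaike_weights(aic)
  tab <- data.frame(
    model = kinds,
    n_params = vapply(fits, `[[`, integer(1), "n_params"),
    negloglik = vapply(fits, `[[`, numeric(1), "negloglik"),
    aic = aic,
    delta_aic = aw$delta,
    weight = aw$weights,
    row.names = NULL
  )
  structure(list(table = tab, fits = fits,
                 best = fits[[which.min(aic)]]),
            class = "nesting_selection")
}

#' @export
print.nesting_selection <- function(x, ...) {
  cat("Model selection for temporal distribution of nesting activity\n")
  tab <- x$table
  tab$negloglik <- round(tab$negloglik, 3)
  tab$aic <- round(tab$aic, 3)
  tab$delta_aic <- round(tab$delta_aic, 2)
  tab$weight <- signif(tab$weight, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Selected: %s\n", x$best$kind))
  invisible(x)
}

#' Nesting-activity index with imputed cells
#'
#' Produces the final beach-by-year matrix: the observed count `N_ij` where
#' a survey exists, the model expectation `E_ij = T_i * p_j` otherwise. The
#' per-beach index is the fitted proportion `p_j`; its log10 is reported
#' with proportions below `1e-12` flagged and set to `NA` (they would
#' otherwise map to -Inf and should be excluded from downstream
#' regressions).
#'
#' @param fit A `nesting_fit` from [fit_nesting_model()].
#' @param table The [nest_count_table()] the fit was made on.
#' @return An object of class `nesting_index`: list with `filled` (matrix),
#'   `imputed` (logical matrix of imputed cells), `p`, `log10_p`,
#'   `excluded` (names of beaches with a degenerate proportion).
#' @export
nesting_index <- function(fit, table) {
  if (!inherits(fit, "nesting_fit")) stop("fit must be a nesting_fit",
                                          call. = FALSE)
  E <- expected_nests(fit$totals, fit$p)
  dimnames(E) <- dimnames(table$N)
  filled <- ifelse(is.na(table$N), E, table$N)
  degenerate <- fit$p < 1e-12
  log10_p <- ifelse(degenerate, NA_real_, log10(pmax(fit$p, 1e-300)))
  structure(list(filled = filled, imputed = is.na(table$N),
                 p = fit$p, log10_p = setNames(log10_p, names(fit$p)),
                 excluded = names(fit$p)[degenerate]),
            class = "nesting_index")
}

#' @export
print.nesting_index <- function(x, ...) {
  cat(sprintf("Nesting index over %d beaches; %d cells imputed of %d\n",
              length(x$p), sum(x$imputed), length(x$imputed)))
  if (length(x$excluded)) {
    cat("  beaches excluded from log10 index:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
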