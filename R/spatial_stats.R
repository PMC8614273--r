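#' Pairwise great-circle distances between beach midpoints
#'
#' @param beaches Data frame with endpoint columns `lat1, lon1, lat2, lon2`
#'   and an `id` column used to label the matrix.
#' @return Symmetric distance matrix in km with zero diagonal.
#' @export
pairwise_geo <- function(beaches) {
  if (nrow(beaches) < 3L) stop("need at least 3 beaches", call. = FALSE)
  mid <- beach_midpoint(beaches)
  n <- nrow(mid)
  D <- matrix(0, n, n, dimnames = list(beaches$id, beaches$id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    D[i, j] <- haversine_km(mid$lat[i], mid$lon[i], mid$lat[j], mid$lon[j])
    D[j, i] <- D[i, j]
  }
  D
}

#' Pairwise absolute differences of a beach attribute
#'
#' Dissimilarity matrix `|x_i - x_j|`, e.g. for the sand-darkness index.
#'
#' @param values Numeric vector, one value per beach.
#' @param labels Optional labels for the matrix.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
pairwise_absdiff <- function(values, labels = names(values)) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  D <- abs(outer(values, values, "-"))
  dimnames(D) <- list(labels, labels)
  D
}

lower_tri <- function(M) M[lower.tri(M)]

#' Mantel permutation test
#'
#' Tests the correlation between two distance matrices: `r_obs` is the
#' Pearson correlation of the strictly-lower-triangle entries, and the null
#' distribution is generated by permuting the rows and columns of `B`
#' simultaneously (which preserves its internal structure while breaking
#' the pairing with `A`). The one-tailed p-value uses the +1-corrected
#' estimator `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`, so `p` is never
#' zero.
#'
#' @param A,B Square symmetric matrices with matching dimensions (same
#'   label order).
#' @param n_perm Number of permutations (default 9999).
#' @param tail `"greater"` (positive association, the default), `"less"`,
#'   or `"two_sided"`.
#' @param seed Integer seed for the sampled permutations.
#' @return Object of class `mantel_result`: list with `r_obs`, `p_value`,
#'   `n_perm`, `tail`, `seed`, `r_perm` (null draws).
#' @export
mantel_test <- function(A, B, n_perm = 9999, tail = c("greater", "less",
                                                      "two_sided"),
                        seed = NULL) {
  tail <- match.arg(tail)
  n <- nrow(A)
  if (!all(dim(A) == n) || !all(dim(B) == n)) {
    stop("A and B must be square with identical dimensions", call. = FALSE)
  }
  if (max(abs(A - t(A))) > 1e-9 || max(abs(B - t(B))) > 1e-9) {
    stop("matrices must be symmetric", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  a <- lower_tri(A)
  if (sd(a) == 0 || sd(lower_tri(B)) == 0) {
    stop("constant lower triangle: correlation undefined", call. = FALSE)
  }
  r_obs <- cor(a, lower_tri(B))
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(B)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    cor(a, B[idx, idx][lt])
  }, numeric(1))
  p <- switch(tail,
    greater = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
    less = (1 + sum(r_perm <= r_obs)) / (1 + n_perm),
    two_sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm))
  structure(list(r_obs = r_obs, p_value = p, n_perm = n_perm, tail = tail,
                 seed = seed, r_perm = r_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, %s tail)\n",
              x$r_obs, x$p_value, x$n_perm, x$tail))
  invisible(x)
}

#' Exact Mantel p-value by permutation enumeration
#'
#' Enumerates all `n!` simultaneous row/column permutations of `B`; only
#' feasible for small matrices (`n <= 7`). Serves as the exact reference
#' for the sampled test.
#'
#' @inheritParams mantel_test
#' @return List with `r_obs`, `p_value`, `n_perm` (= `n!`).
#' @export
mantel_exact <- function(A, B, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  n <- nrow(A)
  if (n > 7L) stop("exact enumeration only for n <= 7", call. = FALSE)
  a <- lower_tri(A)
  r_obs <- cor(a, lower_tri(B))
  perms <- all_permutations(n)
  lt <- lower.tri(B)
  r_all <- vapply(seq_len(nrow(perms)), function(k) {
    idx <- perms[k, ]
    cor(a, B[idx, idx][lt])
  }, numeric(1))
  p <- switch(tail,
    greater = mean(r_all >= r_obs - 1e-12),
    less = mean(r_all <= r_obs + 1e-12),
    two_sided = mean(abs(r_all) >= abs(r_obs) - 1e-12))
  list(r_obs = r_obs, p_value = p, n_perm = nrow(perms))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 0L
  for (s in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[s, ], n, after = pos - 1L)
    }
  }
  out
}

#' Regression of log10 nesting proportion on sand darkness
#'
#' Ordinary least squares of the log10 per-beach nesting proportion on the
#' darkness index, optionally adding beach length as a covariate or using
#' the per-km proportion `p_j / length_km` as the response. Beaches with a
#' degenerate (near-zero) proportion are excluded and reported.
#'
#' @param index A [nesting_index()] result.
#' @param beaches Data frame with `id`, `darkness` and (if needed)
#'   `length_km` columns.
#' @param per_km Use `log10(p_j / length_km)` as the response.
#' @param include_length Add `length_km` as a covariate.
#' @return Object of class `activity_fit`: the `lm` fit plus `aic`,
#'   `excluded`, `n`, and the data used.
#' @export
fit_log10_activity <- function(index, beaches, per_km = FALSE,
                               include_length = FALSE) {
  p <- index$p
  m <- match(names(p), beaches$id)
  if (anyNA(m)) stop("index beaches missing from the beach table",
                     call. = FALSE)
  dark <- beaches$darkness[m]
  len <- beaches$length_km[m]
  usable <- !(names(p) %in% index$excluded)
  if (per_km) usable <- usable & is.finite(len) & len > 0
  if (sum(usable) < 3L) stop("fewer than 3 usable beaches", call. = FALSE)
  y <- if (per_km) log10(p[usable] / len[usable]) else index$log10_p[usable]
  df <- data.frame(y = y, darkness = dark[usable],
                   length_km = len[usable])
  if (sd(df$darkness) == 0) stop("darkness is constant: degenerate design",
                                 call. = FALSE)
  fml <- if (include_length) y ~ darkness + length_km else y ~ darkness
  fit <- lm(fml, data = df)
  structure(list(fit = fit, coefficients = coef(fit),
                 sigma = summary(fit)$sigma, loglik = as.numeric(logLik(fit)),
                 aic = AIC(fit), n = nrow(df),
                 excluded = setdiff(names(p), names(p)[usable]),
                 per_km = per_km, data = df),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf("log10 nesting %s ~ %s (n = %d, AIC = %.2f)\n",
              if (x$per_km) "proportion per km" else "proportion",
              paste(names(x$coefficients)[-1], collapse = " + "),
              x$n, x$aic))
  print(round(x$coefficients, 4))
  if (length(x$excluded)) {
    cat("  excluded beaches:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Does volcano proximity explain sand darkness?
#'
#' Compares, by AIC and Akaike weight, a Gaussian linear model of the
#' darkness index on the distance to the nearest Holocene volcano against
#' the intercept-only model.
#'
#' @param beaches Data frame with endpoints and `darkness`.
#' @param volcanos Data frame with `lat`, `lon`.
#' @return List with the two fits, `delta_aic` (intercept-only minus
#'   distance model; positive favours the distance model), `weights`
#'   (named, summing to 1), `slope`.
#' @export
darkness_vs_volcano <- function(beaches, volcanos) {
  if (nrow(beaches) < 3L) stop("need at least 3 beaches", call. = FALSE)
  dist_km <- nearest_volcano_km(beaches, volcanos)
  df <- data.frame(darkness = beaches$darkness, dist_km = dist_km)
  fit1 <- lm(darkness ~ dist_km, data = df)
  fit0 <- lm(darkness ~ 1, data = df)
  aics <- c(distance = AIC(fit1), intercept_only = AIC(fit0))
  aw <- akaike_weights(aics)
  list(fit_distance = fit1, fit_null = fit0, aic = aics,
       delta_aic = unname(aics["intercept_only"] - aics["distance"]),
       weights = setNames(aw$weights, names(aics)),
       slope = unname(coef(fit1)["dist_km"]))
}
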