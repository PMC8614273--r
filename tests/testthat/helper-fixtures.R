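# Shared fixture builders (all seeded, all built in code).

# A small symmetric distance-like matrix with zero diagonal.
random_dist_matrix <- function(n, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n), n, n)
  M <- M + t(M)
  diag(M) <- 0
  M
}

# Beach table with endpoints along a meridian, darkness supplied.
toy_beaches <- function(darkness, lat0 = 10, step = 0.5) {
  n <- length(darkness)
  data.frame(
    id = sprintf("T%02d", seq_len(n)),
    lat1 = lat0 + step * (seq_len(n) - 1),
    lon1 = -86,
    lat2 = lat0 + step * (seq_len(n) - 1) + 0.01,
    lon2 = -86,
    darkness = darkness,
    length_km = rep(2, n),
    stringsAsFactors = FALSE
  )
}

# Noise-free nest-count table from known totals and proportions, with an
# observation mask.
toy_nest_table <- function(totals, p, observed = NULL) {
  ny <- length(totals)
  nb <- length(p)
  E <- outer(totals, p)
  if (is.null(observed)) observed <- matrix(TRUE, ny, nb)
  idx <- which(observed, arr.ind = TRUE)
  nest_count_table(sprintf("b%d", idx[, 2]), 2000 + idx[, 1],
                   round(E[idx]),
                   beaches = sprintf("b%d", seq_len(nb)),
                   years = 2000 + seq_len(ny))
}

# Default truths used across recovery tests (the study-system values).
TRUE_SEX <- c(P = 30.24, S = 3.84 / (2 * log(19)))
TRUE_HATCH <- c(max_hs = 0.8, p_low = 24.83, s_low = 1, dp = 8.74,
                s_high = -1)
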