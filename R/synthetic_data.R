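#' Scenario configuration for the synthetic-data generators
#'
#' Bundles every knob of the generators emulating the two data sources the
#' analysis was designed for: a regional nesting-count database (sparse
#' beach-by-year counts) and a constant-temperature incubation database
#' (hatched/sexed outcomes). The defaults mirror the study system: 90
#' nesting beaches monitored over 18 seasons with about 10% of beach-year
#' cells observed, count dispersion `sd = 0.1 N + 2`, a sex-ratio norm with
#' pivotal temperature 30.24 C and TRT 5% of 3.84 C, and a hatching-success
#' norm with transitions centred at 24.83 C and 33.57 C.
#'
#' @param n_beaches,n_years Number of beaches and of nesting seasons.
#' @param first_year First season (used to label years).
#' @param span_deg Length of the modelled coastline, in degrees along its
#'   axis.
#' @param origin `c(lat, lon)` of the coastline's southern end.
#' @param bearing_deg Coastline direction, degrees clockwise from north.
#' @param volcanos Data frame `name, lat, lon`; `NULL` places three
#'   volcanos evenly along the coast, 30 km inland.
#' @param darkness_corr_km Correlation length (km) of the Gaussian random
#'   field behind the darkness index; 0 gives spatially independent
#'   darkness.
#' @param volcano_effect,volcano_decay_km Amplitude and e-folding distance
#'   of the darkening effect of a nearby volcano (0 disables it).
#' @param temporal_kind,temporal_params Annual-total model passed to
#'   [temporal_totals()]. For `"year_specific"` with `NULL` params the
#'   totals are drawn log-normally (median 1000, sdlog 0.5) under the seed.
#' @param darkness_slope Slope of `log10 p_j` on darkness used to build the
#'   true beach proportions.
#' @param a,b Count-dispersion parameters; generation uses
#'   `sd = a * E_ij + b` on the latent expectation (the estimator then uses
#'   the observed count, as specified -- the mismatch is intentional and
#'   probes its robustness).
#' @param obs_prob Probability that a beach-year cell is observed.
#' @param sex_norm Named vector `c(P =, S =)`.
#' @param hatch_norm Named vector
#'   `c(max_hs =, p_low =, s_low =, dp =, s_high =)`.
#' @param temp_grid Constant incubation temperatures (degrees C).
#' @param eggs_per_temp Clutch size incubated at each temperature.
#' @param sexed_fraction Fraction of hatchlings that get sexed.
#' @param seed Mandatory integer seed; all generators derive their streams
#'   from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_beaches = 90, n_years = 18, first_year = 1997,
                            span_deg = 12, origin = c(8, -92.5),
                            bearing_deg = 305,
                            volcanos = NULL,
                            darkness_corr_km = 100,
                            volcano_effect = 1.5, volcano_decay_km = 100,
                            temporal_kind = "year_specific",
                            temporal_params = NULL,
                            darkness_slope = -2,
                            a = 0.1, b = 2, obs_prob = 169 / 1620,
                            sex_norm = c(P = 30.24,
                                         S = 3.84 / (2 * log(19))),
                            hatch_norm = c(max_hs = 0.8, p_low = 24.83,
                                           s_low = 1, dp = 8.74,
                                           s_high = -1),
                            temp_grid = seq(26, 34, length.out = 17),
                            eggs_per_temp = 20, sexed_fraction = 1,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_beaches >= 1, n_years >= 1, obs_prob >= 0, obs_prob <= 1,
            a >= 0, b >= 0, sexed_fraction >= 0, sexed_fraction <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

# Unit step along the coastline in (lat, lon) degrees for a given bearing.
coast_direction <- function(bearing_deg) {
  th <- bearing_deg * pi / 180
  c(lat = cos(th), lon = sin(th))
}

#' Generate a synthetic beach and volcano survey
#'
#' Places beaches along a straight stretch of coastline, draws each
#' beach's sand-darkness index from a squashed Gaussian random field with
#' exponential spatial covariance (correlation length
#' `darkness_corr_km`), and optionally darkens beaches near a volcano with
#' an exponentially decaying effect. Endpoints are placed along the coast
#' axis around each midpoint using a log-normal beach length.
#'
#' @param config A [scenario_config()].
#' @return List with `beaches` (data frame `id, lat1, lon1, lat2, lon2,
#'   darkness, length_km, image_date`) and `volcanos` (`name, lat, lon`).
#' @export
gen_beaches <- function(config) {
  set.seed(config$seed)
  dir <- coast_direction(config$bearing_deg)
  s <- sort(runif(config$n_beaches, 0, config$span_deg))
  lat <- config$origin[1] + s * dir["lat"]
  lon <- config$origin[2] + s * dir["lon"]
  len_km <- exp(rnorm(config$n_beaches, mean = log(2), sd = 0.5))
  half_deg <- len_km / 111.195 / 2
  beaches <- data.frame(
    id = sprintf("B%03d", seq_len(config$n_beaches)),
    lat1 = lat - half_deg * dir["lat"], lon1 = lon - half_deg * dir["lon"],
    lat2 = lat + half_deg * dir["lat"], lon2 = lon + half_deg * dir["lon"],
    stringsAsFactors = FALSE
  )
  volcanos <- config$volcanos
  if (is.null(volcanos)) {
    sv <- config$span_deg * c(0.2, 0.5, 0.8)
    # ~30 km inland, perpendicular to the coast axis
    off <- 30 / 111.195
    volcanos <- data.frame(
      name = paste0("V", seq_along(sv)),
      lat = config$origin[1] + sv * dir["lat"] + off * dir["lon"],
      lon = config$origin[2] + sv * dir["lon"] - off * dir["lat"],
      stringsAsFactors = FALSE
    )
  }
  D <- matrix(0, config$n_beaches, config$n_beaches)
  if (config$n_beaches > 1) {
    for (i in seq_len(config$n_beaches - 1)) {
      j <- (i + 1):config$n_beaches
      D[i, j] <- D[j, i] <- haversine_km(lat[i], lon[i], lat[j], lon[j])
    }
  }
  if (config$darkness_corr_km > 0) {
    Sigma <- exp(-D / config$darkness_corr_km)
    # nugget keeps the Cholesky stable for near-coincident beaches
    Sigma <- Sigma + diag(1e-8, nrow(Sigma))
    z <- drop(t(chol(Sigma)) %*% rnorm(config$n_beaches))
  } else {
    z <- rnorm(config$n_beaches)
  }
  field <- z
  if (config$volcano_effect > 0) {
    dv <- nearest_volcano_km(beaches, volcanos)
    field <- field + config$volcano_effect *
      exp(-dv / config$volcano_decay_km) * 2 - config$volcano_effect
  }
  beaches$darkness <- plogis(field)
  beaches$length_km <- len_km
  beaches$image_date <- as.character(as.Date("2020-01-01") +
                                       (seq_len(config$n_beaches) %% 365))
  list(beaches = beaches, volcanos = volcanos)
}

#' Generate a sparse synthetic nest-count table
#'
#' Builds true beach proportions log-linear in darkness
#' (`log10 p_j = darkness_slope * darkness_j`, then normalised), annual
#' totals from the configured temporal model, latent expectations
#' `E_ij = T_i p_j`, Gaussian noise with sd `a E_ij + b` truncated at zero
#' and rounded to integer counts, and finally masks each cell with the
#' configured observation probability.
#'
#' @param config A [scenario_config()].
#' @param beaches The beach table from [gen_beaches()] (or any data frame
#'   with `id` and `darkness`).
#' @return List with `nests` (long data frame `beach_id, year, nests` of
#'   observed cells) and `truth` (`p`, `totals`, `E`).
#' @export
gen_nest_counts <- function(config, beaches) {
  set.seed(config$seed + 1L)
  years <- config$first_year + seq_len(config$n_years) - 1L
  w <- 10^(config$darkness_slope * beaches$darkness)
  p <- w / sum(w)
  params <- config$temporal_params
  if (config$temporal_kind == "year_specific" && is.null(params)) {
    params <- exp(rnorm(config$n_years, mean = log(1000), sd = 0.5))
  }
  totals <- temporal_totals(config$temporal_kind, params, years)
  E <- outer(totals, p)
  noise <- matrix(rnorm(length(E), mean = 0, sd = config$a * E + config$b),
                  nrow = nrow(E))
  N <- round(pmax(E + noise, 0))
  observed <- matrix(runif(length(E)) < config$obs_prob, nrow = nrow(E))
  idx <- which(observed, arr.ind = TRUE)
  nests <- data.frame(beach_id = beaches$id[idx[, 2]],
                      year = years[idx[, 1]],
                      nests = N[idx],
                      stringsAsFactors = FALSE)
  nests <- nests[order(nests$beach_id, nests$year), , drop = FALSE]
  rownames(nests) <- NULL
  list(nests = nests,
       truth = list(p = setNames(p, beaches$id),
                    totals = setNames(totals, years), E = E))
}

#' Generate a synthetic constant-temperature incubation dataset
#'
#' At each grid temperature, hatched counts are binomial in the true
#' hatching-success norm, a configurable fraction of hatchlings is sexed,
#' and female counts are binomial in the true sex-ratio norm.
#'
#' @param config A [scenario_config()].
#' @return Data frame `temperature_C, n_eggs, n_hatched, n_sexed,
#'   n_female, n_male`.
#' @export
gen_incubation <- function(config) {
  set.seed(config$seed + 2L)
  t <- config$temp_grid
  hs <- hatching_success(t, config$hatch_norm[["max_hs"]],
                         config$hatch_norm[["p_low"]],
                         config$hatch_norm[["s_low"]],
                         config$hatch_norm[["dp"]],
                         config$hatch_norm[["s_high"]])
  sr <- sex_ratio(t, config$sex_norm[["P"]], config$sex_norm[["S"]])
  n_eggs <- rep(config$eggs_per_temp, length(t))
  n_hatched <- rbinom(length(t), n_eggs, hs)
  n_sexed <- round(config$sexed_fraction * n_hatched)
  n_female <- rbinom(length(t), n_sexed, sr)
  data.frame(temperature_C = t, n_eggs = n_eggs, n_hatched = n_hatched,
             n_sexed = n_sexed, n_female = n_female,
             n_male = n_sexed - n_female)
}

#' Generate a noisy pixel block
#'
#' Gaussian RGB noise around a mean colour, rounded and clipped to the
#' 0--255 channel range. `sd = 0` gives a constant block. A fixture
#' generator for the colour-scoring functions.
#'
#' @param mean_rgb Length-3 mean colour.
#' @param sd Per-channel noise standard deviation.
#' @param size Side of the square block in pixels (default the 85-pixel
#'   sampling square).
#' @param seed Integer seed.
#' @return Integer array `size x size x 3`.
#' @export
gen_pixel_block <- function(mean_rgb, sd = 5, size = 85, seed = 1) {
  stopifnot(sd >= 0, size >= 1)
  mean_rgb <- check_rgb(mean_rgb)
  set.seed(seed)
  px <- array(0L, dim = c(size, size, 3))
  for (ch in 1:3) {
    v <- round(rnorm(size * size, mean = mean_rgb[ch], sd = sd))
    px[, , ch] <- as.integer(pmin(pmax(v, 0), 255))
  }
  px
}
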