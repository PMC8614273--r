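#' Per-channel modal colour of a pixel block
#'
#' Summarises a rectangular block of RGB pixels (nominally the 85 x 85 pixel
#' square sampled at the centre of a beach) by the histogram mode of each
#' channel taken independently. Ties are broken toward the smaller (darker)
#' channel value, so the result is deterministic.
#'
#' @param block An integer array with dimensions `c(nrow, ncol, 3)` holding
#'   R, G and B values in 0--255, or an `nx3` matrix of pixels (one row per
#'   pixel, columns R, G, B).
#' @return Named integer vector `c(r =, g =, b =)` of per-channel modes.
#' @seealso [darkness_index()], [gen_pixel_block()]
#' @export
#' @examples
#' block <- gen_pixel_block(c(120, 110, 100), sd = 0, size = 5, seed = 1)
#' modal_rgb(block)
modal_rgb <- function(block) {
  px <- as_pixel_matrix(block)
  if (nrow(px) == 0L) {
    stop("pixel block is empty", call. = FALSE)
  }
  modes <- vapply(1:3, function(ch) {
    counts <- tabulate(px[, ch] + 1L, nbins = 256L)
    # which.max returns the first maximum, i.e. the smallest tied value
    which.max(counts) - 1L
  }, integer(1))
  c(r = modes[1], g = modes[2], b = modes[3])
}

# Coerce an array or matrix of pixels to an n x 3 integer matrix, validating
# the 0-255 channel range.
as_pixel_matrix <- function(block) {
  if (is.array(block) && length(dim(block)) == 3L) {
    if (dim(block)[3] != 3L) {
      stop("pixel array must have 3 channels in the third dimension",
           call. = FALSE)
    }
    px <- cbind(as.vector(block[, , 1]), as.vector(block[, , 2]),
                as.vector(block[, , 3]))
  } else if (is.matrix(block) && ncol(block) == 3L) {
    px <- block
  } else {
    stop("pixel block must be an array [h, w, 3] or a matrix [n, 3]",
         call. = FALSE)
  }
  storage.mode(px) <- "integer"
  if (anyNA(px) || any(px < 0L) || any(px > 255L)) {
    stop("pixel channels must be integers in [0, 255]", call. = FALSE)
  }
  px
}

#' Standardized sand-darkness index
#'
#' Standardizes the modal colour of the beach centre against the lightest and
#' darkest zones of the same image, correcting for illumination differences
#' between images. With `D_light` and `D_dark` the Euclidean distances in RGB
#' space from the centre colour to the light and dark endpoints, the index is
#'
#' \deqn{d = D_{light} / (D_{light} + D_{dark})}
#'
#' so that `d = 0` for a beach matching the lightest zone and `d = 1` for one
#' matching the darkest. The index is inversely related to sand albedo.
#'
#' @param center,lightest,darkest RGB triples (length-3 numeric vectors, each
#'   channel in 0--255), typically the output of [modal_rgb()].
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' darkness_index(c(128, 128, 128), lightest = c(255, 255, 255),
#'                darkest = c(0, 0, 0))
darkness_index <- function(center, lightest, darkest) {
  center <- check_rgb(center)
  lightest <- check_rgb(lightest)
  darkest <- check_rgb(darkest)
  if (all(lightest == darkest)) {
    stop("lightest and darkest endpoints coincide; cannot standardize",
         call. = FALSE)
  }
  d_light <- sqrt(sum((center - lightest)^2))
  d_dark <- sqrt(sum((center - darkest)^2))
  d_light / (d_light + d_dark)
}

check_rgb <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || any(x < 0) || any(x > 255)) {
    stop("an RGB triple must be 3 values in [0, 255]", call. = FALSE)
  }
  x
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0 km (Earth mean radius).
#' Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
#' @examples
#' haversine_km(0, 0, 1, 0)  # one meridian degree, ~111.195 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(h)))
}

check_latlon <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon) || any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Beach midpoint
#'
#' Location of a beach as the arithmetic mean of its two endpoint
#' coordinates. Adequate at the regional scale of a Central American
#' coastline; no antimeridian handling is attempted.
#'
#' @param beaches A data frame with columns `lat1, lon1, lat2, lon2` (one row
#'   per beach), e.g. as read by [read_beaches()].
#' @return A data frame with columns `lat`, `lon`.
#' @export
beach_midpoint <- function(beaches) {
  check_latlon(beaches$lat1, beaches$lon1)
  check_latlon(beaches$lat2, beaches$lon2)
  data.frame(lat = (beaches$lat1 + beaches$lat2) / 2,
             lon = (beaches$lon1 + beaches$lon2) / 2)
}

#' Beach length from its endpoints
#'
#' @param beaches A data frame with columns `lat1, lon1, lat2, lon2`.
#' @return Lengths in km (haversine between the endpoints).
#' @export
beach_length_km <- function(beaches) {
  haversine_km(beaches$lat1, beaches$lon1, beaches$lat2, beaches$lon2)
}

#' Distance from each beach to its nearest Holocene volcano
#'
#' Minimum haversine distance from the beach midpoint to any volcano in the
#' supplied table.
#'
#' @param beaches A data frame with endpoint columns `lat1, lon1, lat2, lon2`.
#' @param volcanos A data frame with columns `lat`, `lon` (one row per
#'   volcano).
#' @return Numeric vector of distances in km, one per beach.
#' @export
nearest_volcano_km <- function(beaches, volcanos) {
  if (is.null(volcanos) || nrow(volcanos) == 0L) {
    stop("volcano table is empty", call. = FALSE)
  }
  mid <- beach_midpoint(beaches)
  vapply(seq_len(nrow(mid)), function(i) {
    min(haversine_km(mid$lat[i], mid$lon[i], volcanos$lat, volcanos$lon))
  }, numeric(1))
}
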