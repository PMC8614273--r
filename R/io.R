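# CSV dialect: UTF-8, comma-separated, header row, "." decimal, ISO dates.

read_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Report invariant violations with 1-based data-row numbers (header = row 0).
fail_rows <- function(path, bad, what) {
  if (any(bad)) {
    stop(sprintf("%s: %s (rows %s)", path, what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
}

#' Read and validate a beach table
#'
#' Expected columns: `id, lat1, lon1, lat2, lon2, darkness, length_km,
#' image_date` (the last two optional; a missing `length_km` is computed
#' from the endpoints). Coordinate bounds and `darkness` in `[0, 1]` are
#' enforced, with offending row numbers reported.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_beaches <- function(path) {
  df <- read_checked(path, c("id", "lat1", "lon1", "lat2", "lon2",
                             "darkness"))
  for (cc in c("lat1", "lat2")) {
    fail_rows(path, !is.finite(df[[cc]]) | abs(df[[cc]]) > 90,
              sprintf("invalid %s", cc))
  }
  for (cc in c("lon1", "lon2")) {
    fail_rows(path, !is.finite(df[[cc]]) | abs(df[[cc]]) > 180,
              sprintf("invalid %s", cc))
  }
  fail_rows(path, !is.finite(df$darkness) | df$darkness < 0 | df$darkness > 1,
            "darkness outside [0, 1]")
  fail_rows(path, duplicated(df$id), "duplicate beach id")
  if (is.null(df$length_km)) {
    df$length_km <- beach_length_km(df)
  } else {
    nofill <- !is.finite(df$length_km)
    df$length_km[nofill] <- beach_length_km(df[nofill, , drop = FALSE])
    fail_rows(path, df$length_km < 0, "negative length_km")
  }
  df
}

#' Read and validate a volcano table
#'
#' Expected columns: `name, lat, lon`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_volcanos <- function(path) {
  df <- read_checked(path, c("name", "lat", "lon"))
  fail_rows(path, !is.finite(df$lat) | abs(df$lat) > 90, "invalid lat")
  fail_rows(path, !is.finite(df$lon) | abs(df$lon) > 180, "invalid lon")
  df
}

#' Read and validate long-format nest counts
#'
#' Expected columns: `beach_id, year, nests`; absent beach-year rows are
#' the missing cells of the count table.
#'
#' @param path CSV file path.
#' @return A [nest_count_table()].
#' @export
read_nests <- function(path) {
  df <- read_checked(path, c("beach_id", "year", "nests"))
  fail_rows(path, !is.finite(df$nests) | df$nests < 0,
            "nests must be non-negative")
  fail_rows(path, !is.finite(df$year) | df$year != round(df$year),
            "year must be an integer")
  nest_count_table(df$beach_id, df$year, df$nests)
}

#' Read and validate a constant-temperature incubation table
#'
#' Expected columns: `temperature_C, n_eggs, n_hatched, n_sexed, n_female,
#' n_male`. Enforces `n_hatched <= n_eggs`, `n_sexed <= n_hatched`,
#' `n_female + n_male == n_sexed`, and a 15--45 C temperature sanity range.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_incubation <- function(path) {
  df <- read_checked(path, c("temperature_C", "n_eggs", "n_hatched",
                             "n_sexed", "n_female", "n_male"))
  fail_rows(path, !is.finite(df$temperature_C) | df$temperature_C < 15 |
              df$temperature_C > 45, "temperature outside 15-45 C")
  counts <- c("n_eggs", "n_hatched", "n_sexed", "n_female", "n_male")
  for (cc in counts) {
    fail_rows(path, !is.finite(df[[cc]]) | df[[cc]] < 0 |
                df[[cc]] != round(df[[cc]]),
              sprintf("%s must be a non-negative integer", cc))
  }
  fail_rows(path, df$n_hatched > df$n_eggs, "n_hatched > n_eggs")
  fail_rows(path, df$n_sexed > df$n_hatched, "n_sexed > n_hatched")
  fail_rows(path, df$n_female + df$n_male != df$n_sexed,
            "n_female + n_male != n_sexed")
  df
}

#' Write a data frame in the package's CSV dialect
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce an output: subcommand, input
#' file MD5 hashes, the settings used, the seed, the package version and a
#' timestamp. Embedded in every JSON result the command-line tool writes.
#'
#' @param subcommand Name of the pipeline stage.
#' @param inputs Character vector of input file paths (hashed).
#' @param settings Named list of settings.
#' @param seed Integer seed of the run.
#' @return Named list.
#' @export
run_manifest <- function(subcommand, inputs = character(), settings = list(),
                         seed = NULL) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  list(subcommand = subcommand,
       inputs = hashes,
       settings = settings,
       seed = seed,
       package_version = as.character(utils::packageVersion("nestnorm")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a result list with its manifest as JSON
#'
#' @param result Named list of results.
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, manifest, path) {
  jsonlite::write_json(c(result, list(manifest = manifest)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
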