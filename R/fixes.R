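#' Read GPS relocation fixes from a delimited text file
#'
#' Loads a table of timestamped animal relocations (one row per GPS fix) and
#' validates it into the canonical fix tibble used by every downstream stage.
#' The file must have a header row; comma and tab delimiters are
#' auto-detected. Column names are mapped through `schema` so that both the
#' public jaguar-collar schema and synthetic fixtures load without renaming.
#'
#' Rows whose coordinates or timestamp fail to parse, or whose coordinates
#' fall outside WGS84 ranges, are excluded and counted (never silently
#' dropped): the count is returned in `attr(, "n_rejected")`. Duplicated
#' `(animal, timestamp)` rows keep the first occurrence; the number removed
#' is in `attr(, "n_duplicates")`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named character vector mapping the roles `id`, `timestamp`,
#'   `lat`, `lon` to the column names in the file.
#' @param tz Time zone the timestamps are interpreted in (default `"UTC"`).
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A tibble of class `tm_fixes` with columns `animal_id`, `timestamp`
#'   (POSIXct), `lat`, `lon`, in file order, with attributes `n_rejected` and
#'   `n_duplicates`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,timestamp,lat,lon",
#'              "a,2015-02-01 00:00:00,-17.1,-57.4",
#'              "a,2015-02-01 01:00:00,-17.2,-57.5"), f)
#' read_fixes(f)
read_fixes <- function(path,
                       schema = c(id = "id", timestamp = "timestamp",
                                  lat = "lat", lon = "lon"),
                       tz = "UTC", delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  roles <- c("id", "timestamp", "lat", "lon")
  if (!all(roles %in% names(schema))) {
    stop("`schema` must map all of: ", paste(roles, collapse = ", "))
  }
  missing <- setdiff(unname(schema[roles]), names(raw))
  if (length(missing)) {
    stop("mapped column(s) not present in file: ", paste(missing, collapse = ", "))
  }
  out <- tibble::tibble(
    animal_id = as.character(raw[[schema[["id"]]]]),
    timestamp = parse_fix_time(raw[[schema[["timestamp"]]]], tz = tz),
    lat = suppressWarnings(as.numeric(raw[[schema[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[schema[["lon"]]]]))
  )
  as_fixes(out, source = path)
}

#' Validate a data frame of relocations into a fix tibble
#'
#' @param df Data frame with columns `animal_id`, `timestamp`, `lat`, `lon`.
#' @param source Optional label recorded for error messages.
#' @return A `tm_fixes` tibble; see [read_fixes()].
#' @export
as_fixes <- function(df, source = "input") {
  need <- c("animal_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop("fix table needs columns: ", paste(need, collapse = ", "))
  }
  out <- tibble::as_tibble(df[need])
  ok <- !is.na(out$animal_id) & !is.na(out$timestamp) &
    is.finite(out$lat) & is.finite(out$lon) &
    abs(out$lat) <= 90 & abs(out$lon) <= 180
  n_rejected <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L) stop("no parseable relocation rows in ", source)
  dup <- duplicated(out[c("animal_id", "timestamp")])
  n_duplicates <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  structure(out,
            n_rejected = n_rejected,
            n_duplicates = n_duplicates,
            class = c("tm_fixes", class(tibble::tibble())))
}

parse_fix_time <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, tz))
  suppressWarnings(
    lubridate::parse_date_time(x, orders = c("Ymd HMS", "Ymd HM", "Ymd"),
                               tz = tz, quiet = TRUE)
  )
}

#' Write fixes back to delimited text
#'
#' Timestamps are written as ISO-8601 in the timestamps' own zone; coordinates
#' at full double precision so a write/read round trip is lossless to well
#' under 1e-9 degrees.
#'
#' @param fixes A fix tibble ([read_fixes()]).
#' @param path Output file path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  tz <- attr(fixes$timestamp, "tzone")
  if (is.null(tz) || tz == "") tz <- "UTC"
  out <- tibble::tibble(
    id = fixes$animal_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = tz),
    lat = fixes$lat,
    lon = fixes$lon
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble per-animal, time-ordered trajectories
#'
#' Sorts fixes by animal and timestamp (stable sort: ties keep first
#' occurrence, duplicates already removed at read). Fix counts are conserved.
#'
#' @param fixes A fix tibble.
#' @return The same tibble sorted by `animal_id`, then `timestamp`.
#' @export
build_trajectories <- function(fixes) {
  out <- dplyr::arrange(fixes, .data$animal_id, .data$timestamp)
  structure(out,
            n_rejected = attr(fixes, "n_rejected"),
            n_duplicates = attr(fixes, "n_duplicates"),
            class = unique(c("tm_fixes", class(out))))
}

#' Nominal sampling interval of each trajectory
#'
#' @param fixes A fix tibble.
#' @return A tibble with `animal_id` and `interval_s`, the median time step in
#'   seconds (NA for single-fix tracks).
#' @export
sampling_intervals <- function(fixes) {
  fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      interval_s = if (dplyr::n() > 1)
        median(diff(as.numeric(sort(.data$timestamp)))) else NA_real_,
      .groups = "drop"
    )
}

#' Add calendar year and month columns
#'
#' Month membership uses the timestamp's calendar date in its own time zone,
#' so a fix at `2015-03-01 00:00` belongs to March (half-open month
#' intervals).
#'
#' @param df Data frame with a POSIXct column.
#' @param time_col Name of the timestamp column.
#' @return `df` with integer `year` and `month` columns appended.
#' @export
add_month <- function(df, time_col = "timestamp") {
  ts <- df[[time_col]]
  df$year <- lubridate::year(ts)
  df$month <- lubridate::month(ts)
  df
}

#' Partition timestamped records by calendar month
#'
#' Every record lands in exactly one bucket; the union of buckets is the
#' input (a true partition).
#'
#' @inheritParams add_month
#' @return A named list of tibbles keyed `"YYYY-MM"`, in chronological order.
#' @export
partition_by_month <- function(df, time_col = "timestamp") {
  with_m <- add_month(df, time_col)
  key <- sprintf("%04d-%02d", with_m$year, with_m$month)
  split(tibble::as_tibble(with_m), factor(key, levels = sort(unique(key))))
}
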