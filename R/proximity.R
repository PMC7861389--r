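#' Detect spatiotemporal co-occurrence events between animal pairs
#'
#' For every unordered pair of animals, every pair of fixes recorded within
#' `time_window` seconds of each other and strictly closer than `radius`
#' meters (Vincenty distance) yields a candidate event. Candidates are then
#' deduplicated to at most one event per pair per deduplication interval,
#' keeping the minimum-distance candidate (earliest on ties), so that a
#' single prolonged encounter is reported once per interval rather than once
#' per fix pair.
#'
#' @param fixes A fix tibble with at least two animals.
#' @param radius Distance threshold in meters (strict `<`). The two scales
#'   used for jaguar-style analyses are 200 m and 400 m.
#' @param time_window Maximum |time difference| between the paired fixes, in
#'   seconds (default 3600, one nominal hourly fix).
#' @param dedup_interval Deduplication interval in seconds; defaults to
#'   `time_window`. `0` disables deduplication.
#' @return A tibble of class `tm_events`, sorted by time: `animal_a`,
#'   `animal_b` (pair sorted alphabetically), `timestamp` (animal_a's fix),
#'   `distance_m`, `distance_km`, plus the `radius` and `time_window` used.
#' @export
detect_events <- function(fixes, radius, time_window = 3600,
                          dedup_interval = NULL) {
  stopifnot(radius > 0, time_window >= 0)
  if (is.null(dedup_interval)) dedup_interval <- time_window
  fixes <- dplyr::arrange(tibble::as_tibble(fixes), .data$animal_id,
                          .data$timestamp)
  ids <- sort(unique(fixes$animal_id))
  if (length(ids) < 2L) stop("co-occurrence detection needs >= 2 animals")
  parts <- split(fixes, fixes$animal_id)

  pairs <- utils::combn(ids, 2L, simplify = FALSE)
  events <- purrr::map(pairs, function(pr) {
    A <- parts[[pr[1]]]; B <- parts[[pr[2]]]
    tA <- as.numeric(A$timestamp); tB <- as.numeric(B$timestamp)
    # inclusive window |tB - tA| <= time_window, boundary-exact
    lo <- findInterval(tA - time_window, tB, left.open = TRUE) + 1L
    hi <- findInterval(tA + time_window, tB)
    cnt <- pmax(0L, hi - lo + 1L)
    if (sum(cnt) == 0L) return(NULL)
    ia <- rep.int(seq_along(tA), cnt)
    ib <- sequence(cnt[cnt > 0L], from = lo[cnt > 0L])
    d <- vincenty_distance(A$lat[ia], A$lon[ia], B$lat[ib], B$lon[ib])
    keep <- d < radius
    if (!any(keep)) return(NULL)
    tibble::tibble(
      animal_a = pr[1], animal_b = pr[2],
      timestamp = A$timestamp[ia[keep]],
      t_b = B$timestamp[ib[keep]],
      distance_m = d[keep])
  })
  events <- dplyr::bind_rows(events)
  if (nrow(events) == 0L) {
    out <- tibble::tibble(animal_a = character(), animal_b = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          distance_m = numeric(), distance_km = numeric())
  } else {
    if (dedup_interval > 0) {
      events <- events |>
        dplyr::mutate(.bucket = floor(as.numeric(.data$timestamp) /
                                        dedup_interval)) |>
        dplyr::arrange(.data$distance_m, .data$timestamp) |>
        dplyr::distinct(.data$animal_a, .data$animal_b, .data$.bucket,
                        .keep_all = TRUE) |>
        dplyr::select(-".bucket")
    }
    out <- events |>
      dplyr::mutate(distance_km = .data$distance_m / 1000) |>
      dplyr::select("animal_a", "animal_b", "timestamp", "distance_m",
                    "distance_km") |>
      dplyr::arrange(.data$timestamp)
  }
  structure(out, radius = radius, time_window = time_window,
            dedup_interval = dedup_interval,
            class = c("tm_events", class(out)))
}

#' Construct a transaction set for rule mining
#'
#' A transaction is one observed "basket" of co-occurring labels — the two
#' members of an animal pair for one co-occurrence event, or a behavioral
#' state together with the land-cover class under one fix. `D` is the number
#' of transactions; all supports are counts out of `D`.
#'
#' @param items List of character vectors (duplicate items within a
#'   transaction are collapsed).
#' @param scope Optional label (a month key or an animal id).
#' @return An object of class `tm_transactions`: list with `items`, `D`,
#'   `scope`.
#' @export
transaction_set <- function(items, scope = NULL) {
  stopifnot(is.list(items))
  items <- purrr::map(items, \(x) unique(as.character(x)))
  structure(list(items = items, D = length(items), scope = scope),
            class = "tm_transactions")
}

#' @export
print.tm_transactions <- function(x, ...) {
  cat("<transaction set", if (!is.null(x$scope)) paste0(" [", x$scope, "]"),
      ": D = ", x$D, ", ",
      length(unique(unlist(x$items))), " distinct items>\n", sep = "")
  invisible(x)
}

#' @export
glance.tm_transactions <- function(x, ...) {
  tibble::tibble(scope = x$scope %||% NA_character_, D = x$D,
                 n_items = length(unique(unlist(x$items))))
}

#' @export
tidy.tm_transactions <- function(x, ...) {
  counts <- table(unlist(purrr::map(x$items, unique)))
  tibble::tibble(item = names(counts), count = as.integer(counts),
                 support = as.integer(counts) / x$D) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$item)
}

#' Monthly animal-pair transaction sets from co-occurrence events
#'
#' Each deduplicated event becomes one transaction whose items are the two
#' animal ids; events are grouped by the calendar month of the event
#' timestamp, so each month's `D` is that month's event count. The sum of
#' `D` over months equals the total event count.
#'
#' @param events A `tm_events` tibble ([detect_events()]).
#' @return A named list of [transaction_set()] objects keyed `"YYYY-MM"`.
#' @export
pair_transactions <- function(events) {
  if (nrow(events) == 0L) return(list())
  by_month <- partition_by_month(events)
  purrr::imap(by_month, function(df, key) {
    transaction_set(purrr::map2(df$animal_a, df$animal_b, c), scope = key)
  })
}

#' Per-animal state-by-land-cover transaction sets
#'
#' One transaction per classified fix, with two items: the behavioral state
#' label and the land-cover class under the fix. Fixes falling off the grid
#' are dropped and counted (`attr(, "n_dropped")` on each set).
#'
#' @param states A `tm_states` tibble ([classify_behavior()]).
#' @param grid A [land_cover_grid()].
#' @return A named list of [transaction_set()] objects, one per animal.
#' @export
state_landcover_transactions <- function(states, grid) {
  parts <- split(tibble::as_tibble(states), states$animal_id)
  purrr::imap(parts, function(df, id) {
    cover <- class_at(grid, df$lat, df$lon)
    keep <- !is.na(cover)
    ts <- transaction_set(
      purrr::map2(as.character(df$state[keep]), cover[keep], c), scope = id)
    attr(ts, "n_dropped") <- sum(!keep)
    ts
  })
}

#' Write / read transactions in basket format
#'
#' One transaction per line, items tab-separated.
#'
#' @param tset A [transaction_set()].
#' @param path File path.
#' @return `path` (write) or a `tm_transactions` object (read).
#' @export
write_transactions <- function(tset, path) {
  writeLines(purrr::map_chr(tset$items, paste, collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_transactions
#' @param scope Optional scope label for the read set.
#' @export
read_transactions <- function(path, scope = NULL) {
  transaction_set(strsplit(readLines(path), "\t", fixed = TRUE), scope = scope)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
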