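#' Residence distance and residence time around each trajectory point
#'
#' Around each fix a circle of the given radius is constructed. The residence
#' distance (RD) is the total length of the trajectory's path segments lying
#' inside that circle, segments clipped exactly where they cross the circle
#' boundary (crossing points by linear interpolation along the segment). The
#' residence time (RT) is the total time spanned by those clipped portions,
#' time interpolated linearly with distance along each segment. RD and RT are
#' normalized by their per-track maxima, and the residual
#' `rd_norm - rt_norm` (in \[-1, 1\]) drives state classification: a point
#' where the animal spends long time but covers little path has a negative
#' residual (rest), much path in relatively little time a positive one
#' (foraging, area-restricted search), and a brief directed pass sits near
#' zero relative to both maxima (transit).
#'
#' Geometry is computed in a local equirectangular projection about each
#' track's centroid; at telemetry scales (< 50 km) the projection error is
#' negligible relative to the circle radius.
#'
#' @param fixes A fix tibble, time-ordered per animal.
#' @param radius Circle radius in meters. `NULL` (default) uses each track's
#'   median step length — scale-adaptive and reproducible.
#' @return A tibble with one row per fix: `animal_id`, `timestamp`, `lat`,
#'   `lon`, `rd`, `rt` (meters / seconds), `rd_norm`, `rt_norm`, `residual`,
#'   `radius`.
#' @export
residence_values <- function(fixes, radius = NULL) {
  fixes <- dplyr::arrange(tibble::as_tibble(fixes), .data$animal_id,
                          .data$timestamp)
  parts <- split(fixes, fixes$animal_id)
  out <- purrr::map(parts, residence_one_track, radius = radius)
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("tm_residence", class(res)))
  res
}

residence_one_track <- function(track, radius) {
  n <- nrow(track)
  if (n < 2L) {
    warning("single-fix track for ", track$animal_id[1],
            ": residence values set to zero")
    return(tibble::tibble(
      animal_id = track$animal_id, timestamp = track$timestamp,
      lat = track$lat, lon = track$lon,
      rd = 0, rt = 0, rd_norm = 0, rt_norm = 0, residual = 0,
      radius = NA_real_))
  }
  origin <- c(lat = mean(track$lat), lon = mean(track$lon))
  p <- project_local(track$lat, track$lon, origin)
  x <- p$x; y <- p$y
  tsec <- as.numeric(track$timestamp)

  dx <- diff(x); dy <- diff(y)
  seg_len <- sqrt(dx^2 + dy^2)
  seg_dt <- diff(tsec)
  if (is.null(radius)) radius <- median(seg_len)
  if (!is.finite(radius) || radius <= 0) {
    stop("circle radius must be positive (got ", radius, ")")
  }
  r2 <- radius^2
  ax0 <- x[-n]; ay0 <- y[-n]
  A <- seg_len^2
  zero_len <- A == 0

  rd <- rt <- numeric(n)
  for (i in seq_len(n)) {
    ax <- ax0 - x[i]; ay <- ay0 - y[i]
    C <- ax^2 + ay^2 - r2
    frac <- numeric(n - 1L)
    if (any(zero_len)) frac[zero_len] <- as.numeric(C[zero_len] <= 0)
    nz <- !zero_len
    if (any(nz)) {
      B <- 2 * (ax[nz] * dx[nz] + ay[nz] * dy[nz])
      disc <- B^2 - 4 * A[nz] * C[nz]
      pos <- disc > 0
      f <- numeric(sum(nz))
      if (any(pos)) {
        sq <- sqrt(disc[pos])
        t1 <- (-B[pos] - sq) / (2 * A[nz][pos])
        t2 <- (-B[pos] + sq) / (2 * A[nz][pos])
        f[pos] <- pmax(0, pmin(1, t2) - pmax(0, t1))
      }
      frac[nz] <- f
    }
    rd[i] <- sum(frac * seg_len)
    rt[i] <- sum(frac * seg_dt)
  }

  max_rd <- max(rd); max_rt <- max(rt)
  tibble::tibble(
    animal_id = track$animal_id, timestamp = track$timestamp,
    lat = track$lat, lon = track$lon,
    rd = rd, rt = rt,
    rd_norm = if (max_rd > 0) rd / max_rd else rd * 0,
    rt_norm = if (max_rt > 0) rt / max_rt else rt * 0,
    residual = (if (max_rd > 0) rd / max_rd else rd * 0) -
      (if (max_rt > 0) rt / max_rt else rt * 0),
    radius = radius)
}

#' Classify behavioral states from residence residuals
#'
#' A residual of exactly zero marks transit in the idealized rule; for real
#' tracks the rule is applied with a symmetric tolerance band `epsilon`:
#' `|residual| <= epsilon` is transit, `residual < -epsilon` rest (long
#' dwell, short path), `residual > epsilon` foraging (long path relative to
#' dwell). The three classes partition \[-1, 1\]; the mapping is total and
#' deterministic.
#'
#' @param values Output of [residence_values()].
#' @param epsilon Half-width of the transit band, `>= 0` (default 0.05).
#' @return The input with a `state` factor column
#'   (levels `rest`, `forage`, `transit`), class `tm_states`.
#' @export
classify_states <- function(values, epsilon = 0.05) {
  stopifnot(epsilon >= 0)
  out <- dplyr::mutate(values, state = factor(
    dplyr::case_when(
      abs(.data$residual) <= epsilon ~ "transit",
      .data$residual < -epsilon ~ "rest",
      TRUE ~ "forage"),
    levels = c("rest", "forage", "transit")))
  attr(out, "epsilon") <- epsilon
  class(out) <- unique(c("tm_states", setdiff(class(out), "tm_residence")))
  out
}

#' One-call behavioral classification of a fix table
#'
#' Convenience wrapper: [residence_values()] then [classify_states()].
#'
#' @inheritParams residence_values
#' @inheritParams classify_states
#' @return A `tm_states` tibble.
#' @export
classify_behavior <- function(fixes, radius = NULL, epsilon = 0.05) {
  classify_states(residence_values(fixes, radius = radius), epsilon = epsilon)
}

#' Collapse a state series into behavioral bouts
#'
#' Maximal runs of identical consecutive state labels become one bout. The
#' bout duration is closed on the nominal sampling interval —
#' `last fix - first fix + interval` — so a single-fix bout has the duration
#' of one sampling step; under this convention per-state durations sum to the
#' track span plus one interval. Each bout is assigned a day/night period
#' from its start and end clock times (see [daynight_frequency()]).
#'
#' @param states A `tm_states` tibble ([classify_states()]).
#' @param interval Nominal sampling interval in seconds; `NULL` uses each
#'   track's median time step.
#' @param day_start,day_end Daylight window in clock hours (default 06-18).
#' @return A tibble with one row per bout: `animal_id`, `state`, `start`,
#'   `end`, `duration_s`, `duration_h`, `period`, `year`, `month`.
#' @export
state_bouts <- function(states, interval = NULL, day_start = 6, day_end = 18) {
  states |>
    dplyr::arrange(.data$animal_id, .data$timestamp) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      iv <- interval
      if (is.null(iv)) {
        iv <- if (nrow(df) > 1) median(diff(as.numeric(df$timestamp))) else 0
      }
      r <- rle(as.character(df$state))
      last <- cumsum(r$lengths)
      first <- last - r$lengths + 1L
      tibble::tibble(
        state = factor(r$values, levels = levels(df$state)),
        start = df$timestamp[first],
        end = df$timestamp[last],
        duration_s = as.numeric(df$timestamp[last]) -
          as.numeric(df$timestamp[first]) + iv)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      duration_h = .data$duration_s / 3600,
      period = bout_period(.data$start, .data$end, day_start, day_end)) |>
    add_month("start")
}

bout_period <- function(start, end, day_start, day_end) {
  hr <- function(t) lubridate::hour(t) + lubridate::minute(t) / 60 +
    lubridate::second(t) / 3600
  in_day <- function(h) h >= day_start & h < day_end
  s <- in_day(hr(start)); e <- in_day(hr(end))
  dplyr::case_when(s & e ~ "day", !s & !e ~ "night", TRUE ~ "day/night")
}

#' Hour-by-day state matrix for one calendar month
#'
#' Returns the modal behavioral state of each (day-of-month, hour) cell;
#' hours with several states keep the first-observed one (deterministic
#' tie-break). Cells with no fixes are `NA` (no data).
#'
#' @param states A `tm_states` tibble for one animal.
#' @param year,month Calendar month to tabulate.
#' @return A long tibble with `day`, `hour`, `state`, one row per cell
#'   (`days-in-month x 24` rows), class `tm_state_matrix`.
#' @export
state_matrix <- function(states, year, month) {
  stopifnot(length(unique(states$animal_id)) == 1L)
  df <- add_month(tibble::as_tibble(states))
  df <- df[df$year == year & df$month == month, , drop = FALSE]
  ndays <- lubridate::days_in_month(lubridate::make_date(year, month, 1))
  grid <- tidyr::expand_grid(day = seq_len(ndays), hour = 0:23)
  obs <- df |>
    dplyr::mutate(day = lubridate::mday(.data$timestamp),
                  hour = lubridate::hour(.data$timestamp)) |>
    dplyr::group_by(.data$day, .data$hour) |>
    dplyr::summarise(state = modal_first(.data$state), .groups = "drop")
  out <- dplyr::left_join(grid, obs, by = c("day", "hour"))
  out$state <- factor(out$state, levels = c("rest", "forage", "transit"))
  structure(out, year = year, month = month,
            animal_id = states$animal_id[1],
            class = c("tm_state_matrix", class(out)))
}

modal_first <- function(x) {
  x <- as.character(x)
  tab <- table(factor(x, levels = unique(x)))
  names(tab)[which.max(tab)]
}

#' Mean bout duration per month and state
#'
#' @param bouts Output of [state_bouts()].
#' @return A tibble with `animal_id`, `year`, `month`, `state`, `n_bouts`,
#'   `mean_duration_h`.
#' @export
mean_bout_durations <- function(bouts) {
  bouts |>
    dplyr::group_by(.data$animal_id, .data$year, .data$month, .data$state) |>
    dplyr::summarise(n_bouts = dplyr::n(),
                     mean_duration_h = mean(.data$duration_h),
                     .groups = "drop")
}

#' Bout frequency by period of day
#'
#' A bout is "day" when it starts and ends inside the daylight window
#' `[day_start, day_end)`, "night" when both endpoints are outside it, and
#' "day/night" when it crosses the boundary in either direction.
#'
#' @inheritParams state_bouts
#' @param bouts Output of [state_bouts()].
#' @return Counts per `animal_id`, `year`, `month`, `state`, `period`.
#' @export
daynight_frequency <- function(bouts, day_start = 6, day_end = 18) {
  stopifnot(day_start >= 0, day_start < day_end, day_end <= 24)
  bouts |>
    dplyr::mutate(period = bout_period(.data$start, .data$end,
                                       day_start, day_end)) |>
    dplyr::count(.data$animal_id, .data$year, .data$month, .data$state,
                 .data$period, name = "n_bouts")
}
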