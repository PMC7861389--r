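#' Parameters for the multi-state movement simulator
#'
#' Per-state step-length distribution (truncated normal, meters), turning
#' behavior, and mean dwell (in fixes), plus the between-state transition
#' matrix and fix schedule. The defaults emulate the three canonical
#' regimes on an hourly fix schedule, chosen to be well separated:
#'
#' * `rest`: near-stationary (10 +- 5 m steps, uncorrelated headings), long
#'   bouts (mean 50 fixes) — long dwell, short path.
#' * `forage`: area-restricted search as a loopy correlated walk
#'   (100 +- 20 m steps, persistent ~80 degree turning whose sign is drawn
#'   per bout, so the path orbits within ~80 m of its center), bouts of
#'   mean 20 fixes — long path accumulated in a confined area.
#' * `transit`: fast directed travel (1500 +- 300 m steps, headings within
#'   a few degrees of a per-track azimuth), short bouts (mean 4 fixes).
#'
#' State switching is semi-Markov: a bout's dwell is drawn as
#' `1 + Poisson(mean_dwell - 1)`, then the next state is drawn from the
#' transition-matrix row with the self-transition removed and the rest
#' renormalized. A row that is one-hot on its own state is absorbing (the
#' track never leaves that state). By default rest and forage hand over to
#' transit, and transit splits evenly between rest and forage, so distinct
#' activity centers are separated by travel legs.
#'
#' @param states Named list of per-state parameter lists with entries
#'   `step_mean`, `step_sd`, `turn` (`"uniform"`, `"correlated"` or
#'   `"absolute"`), `turn_mean`, `turn_sd` (degrees), `dwell_mean`.
#' @param transition 3x3 matrix of between-state probabilities (rows sum
#'   to 1) over `rest`, `forage`, `transit`.
#' @param interval_s Fix interval in seconds (default 3600: hourly fixes).
#' @param start Named vector `c(lat=, lon=)` of the start location.
#' @param t0 POSIXct start time.
#' @return A list of class `tm_sim_params`.
#' @export
sim_params <- function(states = list(
                         rest = list(step_mean = 10, step_sd = 5,
                                     turn = "uniform", turn_mean = 0,
                                     turn_sd = 0, dwell_mean = 50),
                         forage = list(step_mean = 100, step_sd = 20,
                                       turn = "correlated", turn_mean = 80,
                                       turn_sd = 10, dwell_mean = 20),
                         transit = list(step_mean = 1500, step_sd = 300,
                                        turn = "absolute", turn_mean = 0,
                                        turn_sd = 5, dwell_mean = 4)),
                       transition = matrix(c(0, 0, 1,
                                             0, 0, 1,
                                             0.5, 0.5, 0), 3, 3,
                                           byrow = TRUE,
                                           dimnames = list(
                                             c("rest", "forage", "transit"),
                                             c("rest", "forage", "transit"))),
                       interval_s = 3600,
                       start = c(lat = -16.8, lon = -57.5),
                       t0 = as.POSIXct("2015-02-01 00:00:00", tz = "UTC")) {
  stopifnot(setequal(names(states), c("rest", "forage", "transit")),
            all(abs(rowSums(transition) - 1) < 1e-9))
  structure(list(states = states, transition = transition,
                 interval_s = interval_s, start = start, t0 = t0),
            class = "tm_sim_params")
}

sim_state_sequence <- function(n, params, start_state = "rest") {
  labs <- c("rest", "forage", "transit")
  P <- params$transition
  out <- character(0)
  state <- start_state
  while (length(out) < n) {
    mu <- params$states[[state]]$dwell_mean
    absorbing <- P[state, state] >= 1 - 1e-12
    dwell <- if (absorbing) n - length(out) else
      1L + stats::rpois(1L, max(0, mu - 1))
    out <- c(out, rep(state, dwell))
    if (absorbing) break
    p <- P[state, ]
    p[state] <- 0
    if (sum(p) <= 0) break  # no exit: treat as absorbing
    state <- sample(labs, 1L, prob = p / sum(p))
  }
  out[seq_len(n)]
}

# One correlated-walk realization for a given state sequence. The step
# between two fixes in different states is drawn from the faster regime of
# the two (transit > forage > rest): a regime change is a relocation, so
# activity sites stay separated from the travel legs that connect them.
sim_walk <- function(states, params) {
  n <- length(states)
  speed_rank <- c(rest = 1, forage = 2, transit = 3)
  azimuth <- runif(1, 0, 2 * pi)  # per-track travel direction
  heading <- azimuth
  turn_sign <- sample(c(-1, 1), 1)
  x <- y <- numeric(n)
  for (i in 2:n) {
    step_state <- if (speed_rank[states[i]] >= speed_rank[states[i - 1]])
      states[i] else states[i - 1]
    st <- params$states[[step_state]]
    if (i > 2 && states[i] != states[i - 1]) {
      turn_sign <- sample(c(-1, 1), 1)  # orbit direction redrawn per bout
    }
    heading <- sim_heading(st, heading, azimuth, turn_sign)
    len <- max(0, rnorm(1, st$step_mean, st$step_sd))
    x[i] <- x[i - 1] + len * cos(heading)
    y[i] <- y[i - 1] + len * sin(heading)
  }
  list(x = x, y = y)
}

# turn models: "uniform" redraws the heading each step; "correlated" turns
# by turn_mean (+- per-bout sign) with gaussian wobble; "absolute" points
# along the track azimuth with gaussian wobble (directed ranging).
sim_heading <- function(st, heading, azimuth, turn_sign) {
  switch(st$turn,
         uniform = runif(1, 0, 2 * pi),
         absolute = azimuth + rnorm(1, st$turn_mean, st$turn_sd) * pi / 180,
         heading + (turn_sign * st$turn_mean +
                      rnorm(1, 0, st$turn_sd)) * pi / 180)
}

#' Simulate one multi-state track with known true states
#'
#' Generates a semi-Markov state sequence ([sim_params()]), draws each
#' step's length and heading from the active state's model, accumulates
#' positions in a local flat-earth meter frame and converts them to WGS84
#' lat/lon offsets about the start location. Fully deterministic for a
#' fixed seed.
#'
#' @param n_fixes Number of fixes.
#' @param params A [sim_params()] object.
#' @param seed Integer seed (mandatory: fixtures must be reproducible).
#' @param start_state Initial behavioral state.
#' @param animal_id Label for the simulated animal.
#' @return A list: `fixes` (a `tm_fixes` tibble), `states` (tibble with the
#'   true `state` per fix), `params`.
#' @export
simulate_track <- function(n_fixes, params = sim_params(), seed,
                           start_state = "rest", animal_id = "sim1") {
  stopifnot(n_fixes >= 2, !missing(seed))
  set.seed(seed)
  states <- sim_state_sequence(n_fixes, params, start_state)

  walk <- sim_walk(states, params)
  ll <- unproject_local(walk$x, walk$y, c(lat = params$start[["lat"]],
                                          lon = params$start[["lon"]]))
  ts <- params$t0 + (seq_len(n_fixes) - 1L) * params$interval_s
  fixes <- as_fixes(tibble::tibble(
    animal_id = animal_id, timestamp = ts, lat = ll$lat, lon = ll$lon))
  list(fixes = fixes,
       states = tibble::tibble(animal_id = animal_id, timestamp = ts,
                               state = factor(states, levels = c(
                                 "rest", "forage", "transit"))),
       params = params)
}

#' Simulate an attracted pair of tracks with scripted encounters
#'
#' Animal A moves independently; animal B starts `separation_m` away and
#' follows its own dynamics, except during `n_encounters` scripted encounter
#' windows (evenly spaced through the track) when B is pulled to within half
#' the encounter radius of A's concurrent position — guaranteeing at least
#' `n_encounters` detectable co-occurrences at that radius. With
#' `n_encounters = 0` the tracks stay separated and co-occurrence at small
#' radii is (with overwhelming probability) absent.
#'
#' @param n_fixes Fixes per animal (shared hourly schedule).
#' @param params_a,params_b [sim_params()] for each animal.
#' @param n_encounters Number of scripted encounter windows.
#' @param encounter_radius Radius (m) within which the windows place B.
#' @param encounter_length Fixes per encounter window.
#' @param separation_m Initial separation between start locations.
#' @param seed Integer seed.
#' @return A list: `fixes` (both animals, one tibble), `states` (truth for
#'   both), `encounters` (tibble of scripted window fixes), `params`.
#' @export
simulate_pair <- function(n_fixes, params_a = sim_params(),
                          params_b = params_a, n_encounters = 5,
                          encounter_radius = 200, encounter_length = 2,
                          separation_m = 50000, seed) {
  stopifnot(!missing(seed))
  a <- simulate_track(n_fixes, params_a, seed = seed, animal_id = "A")

  set.seed(seed + 1L)
  states_b <- sim_state_sequence(n_fixes, params_b, "rest")
  origin <- c(lat = params_a$start[["lat"]], lon = params_a$start[["lon"]])
  pa <- project_local(a$fixes$lat, a$fixes$lon, origin)

  enc_starts <- if (n_encounters > 0) {
    unique(pmax(2L, floor(seq(0.1, 0.9, length.out = n_encounters) * n_fixes)))
  } else integer(0)
  enc_idx <- unique(unlist(purrr::map(enc_starts, \(s)
    seq(s, min(s + encounter_length - 1L, n_fixes)))))

  speed_rank <- c(rest = 1, forage = 2, transit = 3)
  azimuth_b <- runif(1, 0, 2 * pi)
  heading <- azimuth_b
  turn_sign <- sample(c(-1, 1), 1)
  x <- y <- numeric(n_fixes)
  x[1] <- separation_m
  for (i in 2:n_fixes) {
    if (i %in% enc_idx) {
      ang <- runif(1, 0, 2 * pi)
      r <- runif(1, 0, encounter_radius * 0.45)
      x[i] <- pa$x[i] + r * cos(ang)
      y[i] <- pa$y[i] + r * sin(ang)
      next
    }
    step_state <- if (speed_rank[states_b[i]] >= speed_rank[states_b[i - 1]])
      states_b[i] else states_b[i - 1]
    st <- params_b$states[[step_state]]
    if (i > 2 && states_b[i] != states_b[i - 1]) {
      turn_sign <- sample(c(-1, 1), 1)
    }
    heading <- sim_heading(st, heading, azimuth_b, turn_sign)
    len <- max(0, rnorm(1, st$step_mean, st$step_sd))
    x[i] <- x[i - 1] + len * cos(heading)
    y[i] <- y[i - 1] + len * sin(heading)
  }
  ll <- unproject_local(x, y, origin)
  ts <- params_a$t0 + (seq_len(n_fixes) - 1L) * params_a$interval_s
  b_fixes <- as_fixes(tibble::tibble(
    animal_id = "B", timestamp = ts, lat = ll$lat, lon = ll$lon))

  list(
    fixes = build_trajectories(dplyr::bind_rows(a$fixes, b_fixes)),
    states = dplyr::bind_rows(
      a$states,
      tibble::tibble(animal_id = "B", timestamp = ts,
                     state = factor(states_b,
                                    levels = c("rest", "forage", "transit")))),
    encounters = tibble::tibble(fix = sort(enc_idx),
                                timestamp = ts[sort(enc_idx)]),
    params = list(a = params_a, b = params_b))
}

#' Simulate a blobby categorical landscape
#'
#' Seeded random class map: `n_blobs` centers are placed uniformly in the
#' extent, each assigned a class (every class gets at least one center), and
#' each cell takes the class of its nearest center — a Voronoi mosaic of
#' contiguous patches.
#'
#' @param ncols,nrows Grid dimensions.
#' @param xll,yll Lower-left corner (degrees).
#' @param cellsize Cell size (degrees).
#' @param classes Character vector of class names (>= 1).
#' @param n_blobs Number of Voronoi centers (>= number of classes).
#' @param seed Integer seed.
#' @return A `tm_landcover` grid with codes `1..length(classes)` and the
#'   class names as legend.
#' @export
simulate_landscape <- function(ncols = 50, nrows = 50, xll = -57.8,
                               yll = -17.1, cellsize = 0.01,
                               classes = c("forest", "wetland", "water",
                                           "savanna"),
                               n_blobs = 12, seed) {
  stopifnot(!missing(seed), length(classes) >= 1,
            n_blobs >= length(classes))
  set.seed(seed)
  cx <- runif(n_blobs, xll, xll + ncols * cellsize)
  cy <- runif(n_blobs, yll, yll + nrows * cellsize)
  cls <- c(seq_along(classes),
           sample(seq_along(classes), n_blobs - length(classes),
                  replace = TRUE))
  gx <- xll + (seq_len(ncols) - 0.5) * cellsize
  gy <- yll + (nrows - seq_len(nrows) + 0.5) * cellsize  # row 1 = north
  near <- function(px, py) which.min((px - cx)^2 + (py - cy)^2)
  codes <- outer(gy, gx, Vectorize(function(py, px) cls[near(px, py)]))
  out <- land_cover_grid(codes, xll = xll, yll = yll, cellsize = cellsize,
                         legend = setNames(classes, seq_along(classes)))
  attr(out, "centers") <- tibble::tibble(lon = cx, lat = cy, code = cls)
  out
}
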