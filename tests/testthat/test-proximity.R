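t0 <- as.POSIXct("2015-02-01 00:00:00", tz = "UTC")

test_that("co-located simultaneous fixes give one zero-distance event", {
  fx <- as_fixes(tibble::tibble(
    animal_id = c("a", "b"), timestamp = t0, lat = -17.1, lon = -57.4))
  ev <- detect_events(fx, radius = 200)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$distance_m, 0)
  expect_equal(c(ev$animal_a, ev$animal_b), c("a", "b"))
})

test_that("the radius is a strict threshold", {
  dlat <- 500 / (pi / 180 * 6371008.8)
  fx <- as_fixes(tibble::tibble(
    animal_id = c("a", "b"), timestamp = t0,
    lat = c(0, dlat), lon = 0))
  d <- vincenty_distance(0, 0, dlat, 0)
  expect_equal(nrow(detect_events(fx, radius = 200)), 0L)
  expect_equal(nrow(detect_events(fx, radius = 600)), 1L)
  expect_equal(nrow(detect_events(fx, radius = d)), 0L)        # d < d is FALSE
  expect_equal(nrow(detect_events(fx, radius = d + 1e-6)), 1L)
})

test_that("events match the quadratic all-pairs oracle on a scripted trio", {
  sim <- simulate_pair(120, n_encounters = 4, encounter_radius = 300,
                       seed = 5)
  extra <- simulate_track(120, seed = 6, animal_id = "C")
  fx <- build_trajectories(dplyr::bind_rows(sim$fixes, extra$fixes))
  for (radius in c(200, 400)) {
    got <- detect_events(fx, radius = radius, time_window = 3600,
                         dedup_interval = 0)
    want <- oracle_events(fx, radius = radius, time_window = 3600)
    expect_equal(nrow(got), nrow(want))
    got_s <- dplyr::arrange(tibble::as_tibble(got), timestamp, animal_a,
                            animal_b, distance_m)
    expect_equal(got_s$distance_m, want$distance_m, tolerance = 1e-9)
    expect_equal(got_s$animal_a, want$animal_a)
  }
})

test_that("event count is monotone non-decreasing in the radius", {
  sim <- simulate_pair(300, n_encounters = 6, encounter_radius = 350,
                       seed = 9)
  n200 <- nrow(detect_events(sim$fixes, radius = 200))
  n400 <- nrow(detect_events(sim$fixes, radius = 400))
  expect_gte(n400, n200)
})

test_that("deduplication keeps one minimum-distance event per pair and interval", {
  fx <- as_fixes(tibble::tibble(
    animal_id = rep(c("a", "b"), each = 3),
    timestamp = rep(t0 + 0:2 * 3600, 2),
    lat = c(0, 0, 0, 1e-5, 2e-5, 3e-5), lon = 0))
  ev <- detect_events(fx, radius = 200, time_window = 3600)
  expect_equal(nrow(ev), 3L)  # one per hourly interval
  # minimum distance among the candidates whose reference (animal-a) fix
  # falls in each interval: B's closest fix within +-1 h of A's
  d <- vincenty_distance(0, 0, c(1e-5, 2e-5, 3e-5), 0)
  expect_equal(ev$distance_m, c(d[1], d[1], d[2]), tolerance = 1e-9)
  raw <- detect_events(fx, radius = 200, time_window = 3600,
                       dedup_interval = 0)
  expect_gt(nrow(raw), nrow(ev))
})

feb_events <- function(pairs_counts) {
  rows <- purrr::imap(pairs_counts, function(k, pair) {
    ab <- strsplit(pair, "-", fixed = TRUE)[[1]]
    tibble::tibble(animal_a = ab[1], animal_b = ab[2],
                   timestamp = t0 + seq_len(k) * 7200, distance_m = 50)
  })
  dplyr::bind_rows(rows)
}

test_that("monthly pair transactions reproduce the reference occurrence arithmetic", {
  ev <- feb_events(c("Alice-Picole" = 3, "Caiman-Dale" = 3,
                     "Caiman-Fera" = 2))
  tsets <- pair_transactions(ev)
  expect_equal(names(tsets), "2015-02")
  feb <- tsets[["2015-02"]]
  expect_equal(feb$D, 8L)
  n_caiman <- sum(vapply(feb$items, function(t) "Caiman" %in% t, logical(1)))
  expect_equal(n_caiman, 5L)
  expect_equal(n_caiman / feb$D, 0.625)

  ev2 <- feb_events(c("Caiman-Dale" = 3, "Caiman-Fera" = 1))
  feb2 <- pair_transactions(ev2)[["2015-02"]]
  expect_equal(feb2$D, 4L)
  n_c <- sum(vapply(feb2$items, function(t) "Caiman" %in% t, logical(1)))
  n_d <- sum(vapply(feb2$items, function(t) "Dale" %in% t, logical(1)))
  expect_equal(c(n_c / 4, n_d / 4), c(1, 0.75))

  expect_equal(pair_transactions(detect_events(as_fixes(tibble::tibble(
    animal_id = c("a", "b"), timestamp = t0, lat = c(0, 1), lon = 0)),
    radius = 10)), list())
})

test_that("monthly transaction counts conserve the event total", {
  sim <- simulate_pair(2000, n_encounters = 8, encounter_radius = 300,
                       seed = 14)
  ev <- detect_events(sim$fixes, radius = 400)
  tsets <- pair_transactions(ev)
  expect_equal(sum(vapply(tsets, `[[`, integer(1), "D")), nrow(ev))
  for (ts in tsets) {
    counts <- table(unlist(ts$items))
    expect_true(all(counts <= ts$D))
  }
})

test_that("state-landcover transactions pair each fix with its cover class", {
  grid <- land_cover_grid(matrix(1L, 10, 10), xll = 0, yll = 0,
                          cellsize = 0.01, legend = c("1" = "wetland"))
  st <- truth_states(tibble::tibble(
    animal_id = "a", timestamp = t0 + 0:9 * 3600,
    state = factor(rep("forage", 10),
                   levels = c("rest", "forage", "transit")),
    lat = 0.05, lon = seq(0.005, 0.095, by = 0.01)))
  tsets <- state_landcover_transactions(st, grid)
  expect_equal(tsets$a$D, 10L)
  expect_true(all(vapply(tsets$a$items, setequal, logical(1),
                         c("forage", "wetland"))))
  r <- mine_rules(tsets$a, 0.01, 0.01)
  expect_equal(r$sup[r$antecedent == "forage"], 1)

  st_off <- st
  st_off$lat[1] <- 5  # off the grid
  tsets2 <- state_landcover_transactions(st_off, grid)
  expect_equal(tsets2$a$D, 9L)
  expect_equal(attr(tsets2$a, "n_dropped"), 1L)
})

test_that("checkerboard transactions match direct cell lookup", {
  codes <- outer(1:8, 1:8, function(r, c) ((r + c) %% 2L) + 1L)
  grid <- land_cover_grid(codes, 0, 0, 0.01,
                          legend = c("1" = "forest", "2" = "wetland"))
  set.seed(30)
  lat <- runif(100, 0, 0.08); lon <- runif(100, 0, 0.08)
  st <- truth_states(tibble::tibble(
    animal_id = "a", timestamp = t0 + seq_len(100) * 3600,
    state = factor(sample(c("rest", "forage"), 100, replace = TRUE),
                   levels = c("rest", "forage", "transit")),
    lat = lat, lon = lon))
  tsets <- state_landcover_transactions(st, grid)
  covers <- vapply(tsets$a$items, function(t)
    intersect(t, c("forest", "wetland")), character(1))
  expect_equal(unname(table(covers)[c("forest", "wetland")]),
               unname(table(oracle_class_at(grid, lat, lon))[
                 c("forest", "wetland")]))
})

test_that("basket format round-trips transaction sets", {
  ts <- transaction_set(list(c("a", "b"), "c", c("b", "c")), scope = "x")
  f <- tempfile()
  write_transactions(ts, f)
  back <- read_transactions(f, scope = "x")
  expect_equal(back$items, ts$items)
  expect_equal(back$D, 3L)
})
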