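test_that("a whole segment inside the circle contributes its full length and time", {
  fx <- fixes_at(c(0, 100), c(0, 0), c(0, 1))
  rv <- residence_values(fx, radius = 500)
  expect_equal(rv$rd, c(100, 100), tolerance = 1e-9)
  expect_equal(rv$rt, c(3600, 3600), tolerance = 1e-6)
})

test_that("a small circle on a straight track clips to one diameter of path", {
  # equally spaced 1000 m steps, radius 300 m: at an interior fix the path
  # enters and leaves the circle, leaving exactly 2 * radius of clipped path
  fx <- fixes_at(seq(0, 4000, by = 1000), rep(0, 5), 0:4)
  rv <- residence_values(fx, radius = 300)
  expect_equal(rv$rd[3], 600, tolerance = 1e-9)
  # time interpolates linearly with distance: 600 m at 1000 m/h
  expect_equal(rv$rt[3], 0.6 * 3600, tolerance = 1e-6)
})

test_that("residence values match a fine-discretization clipping oracle", {
  set.seed(21)
  n <- 25
  x <- cumsum(rnorm(n, 0, 400)); y <- cumsum(rnorm(n, 0, 400))
  x <- x - mean(x); y <- y - mean(y)  # centered: projection exact at equator
  th <- cumsum(runif(n, 0.5, 2))
  fx <- fixes_at(x, y, th)
  for (radius in c(200, 600)) {
    rv <- residence_values(fx, radius = radius)
    orc <- oracle_residence(x, y, th * 3600, radius)
    expect_equal(rv$rd, orc$rd, tolerance = 2e-3)
    expect_equal(rv$rt, orc$rt, tolerance = 2e-3)
  }
})

test_that("normalized residence time peaks in the longest-dwell cluster", {
  # two clusters outside each other's circles; the animal dwells 2 h in the
  # first and 8 h in the second, so rt_norm = 1 falls in the second cluster
  x <- c(0, 5, 10, 500, 505, 510)
  t_hr <- c(0, 1, 2, 3, 10, 11)
  fx <- fixes_at(x, rep(0, 6), t_hr)
  rv <- residence_values(fx, radius = 100)
  expect_equal(max(rv$rt_norm), 1)
  expect_true(which.max(rv$rt_norm) %in% 4:6)
  expect_lt(max(rv$rt_norm[1:3]), 1)
  expect_true(all(rv$residual >= -1 & rv$residual <= 1))
})

test_that("single-fix tracks get zero residence values with a warning", {
  fx <- fixes_at(0, 0, 0)
  expect_warning(rv <- residence_values(fx, radius = 100), "single-fix")
  expect_equal(rv$rd, 0)
})

test_that("the residual rule is total and partitions [-1, 1]", {
  res <- tibble::tibble(residual = c(-0.5, 0.5, 0, -0.05, 0.05, -0.051,
                                     0.051, -1, 1))
  st <- classify_states(res, epsilon = 0.05)
  expect_equal(as.character(st$state),
               c("rest", "forage", "transit", "transit", "transit",
                 "rest", "forage", "rest", "forage"))
  # total and deterministic over a residual grid, any epsilon
  grid <- tibble::tibble(residual = seq(-1, 1, by = 0.01))
  for (eps in c(0, 0.05, 0.3)) {
    s1 <- classify_states(grid, eps)$state
    s2 <- classify_states(grid, eps)$state
    expect_identical(s1, s2)
    expect_false(anyNA(s1))
  }
})

make_states <- function(labels, t_hours, id = "a") {
  truth_states(tibble::tibble(
    animal_id = id,
    timestamp = as.POSIXct("2015-02-01", tz = "UTC") + t_hours * 3600,
    state = factor(labels, levels = c("rest", "forage", "transit"))))
}

test_that("bouts are maximal runs with interval-closed durations", {
  st <- make_states(c("rest", "rest", "forage"), 0:2)
  b <- state_bouts(st, interval = 3600)
  expect_equal(nrow(b), 2L)
  expect_equal(b$duration_h, c(2, 1))

  all_transit <- make_states(rep("transit", 6), 0:5)
  expect_equal(nrow(state_bouts(all_transit)), 1L)

  alt <- make_states(rep(c("rest", "forage"), 4), 0:7)
  expect_equal(nrow(state_bouts(alt)), 8L)
})

test_that("per-state bout durations sum to the track span plus one interval", {
  sim <- simulate_track(300, seed = 3)
  st <- classify_behavior(sim$fixes, radius = 200, epsilon = 0.15)
  b <- state_bouts(st, interval = 3600)
  span_h <- diff(range(as.numeric(st$timestamp))) / 3600
  expect_equal(sum(b$duration_h), span_h + 1)
})

test_that("the state matrix covers every hour-by-day cell with modal states", {
  labs <- rep(c("rest", "forage"), length.out = 48)
  st <- make_states(labs, 0:47)
  m <- state_matrix(st, 2015, 2)
  expect_equal(nrow(m), 28 * 24)
  filled <- m[!is.na(m$state), ]
  expect_equal(nrow(filled), 48L)
  expect_equal(as.character(filled$state), labs)
  # a day without fixes is entirely no-data
  expect_true(all(is.na(m$state[m$day == 5])))
})

test_that("hour-cell ties keep the first observed state", {
  st <- make_states(c("rest", "forage"), c(0, 0.5))  # same hour
  m <- state_matrix(st, 2015, 2)
  expect_equal(as.character(m$state[m$day == 1 & m$hour == 0]), "rest")
})

test_that("mean durations average bouts within month and state", {
  st <- make_states(c("forage", "rest", "forage", "forage", "rest"),
                    c(0, 1, 2, 3, 4))
  b <- state_bouts(st, interval = 3600)
  md <- mean_bout_durations(b)
  forage <- md[md$state == "forage", ]
  expect_equal(forage$n_bouts, 2L)
  expect_equal(forage$mean_duration_h, mean(c(1, 2)))
  one <- mean_bout_durations(b[1, ])
  expect_equal(one$mean_duration_h, b$duration_h[1])
})

test_that("day/night classing uses the bout endpoints against the day window", {
  b <- tibble::tibble(
    animal_id = "a",
    state = factor("forage", levels = c("rest", "forage", "transit")),
    start = as.POSIXct(c("2015-02-01 02:00", "2015-02-01 10:00",
                         "2015-02-01 16:00"), tz = "UTC"),
    end = as.POSIXct(c("2015-02-01 04:00", "2015-02-01 12:00",
                       "2015-02-01 20:00"), tz = "UTC"),
    duration_s = 7200, duration_h = 2, period = NA_character_,
    year = 2015L, month = 2L)
  f <- daynight_frequency(b, day_start = 6, day_end = 18)
  expect_equal(f$period[order(f$period)], c("day", "day/night", "night"))
})

test_that("synthetic months reproduce generator bout durations", {
  sim <- simulate_track(800, seed = 12)
  tb <- state_bouts(truth_states(sim$states), interval = 3600)
  st <- classify_behavior(sim$fixes, radius = 200, epsilon = 0.15)
  pb <- state_bouts(st, interval = 3600)
  tm <- tapply(tb$duration_h, tb$state, mean)
  pm <- tapply(pb$duration_h, pb$state, mean)
  expect_equal(unname(pm), unname(tm), tolerance = 0.25)
})
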