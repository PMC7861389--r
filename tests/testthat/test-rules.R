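test_that("frequent itemsets on a toy basket match exhaustive enumeration", {
  ts <- transaction_set(list(c("A", "B"), c("A", "B"), "A"))
  fr <- apriori(ts, min_sup = 0.5)
  sup_of <- function(items) {
    i <- which(vapply(fr$items, setequal, logical(1), items))
    fr$support[i]
  }
  expect_equal(sup_of("A"), 1)
  expect_equal(sup_of("B"), 2 / 3)
  expect_equal(sup_of(c("A", "B")), 2 / 3)
  expect_equal(nrow(fr), 3L)

  all_only <- apriori(ts, min_sup = 1)
  expect_equal(nrow(all_only), 1L)
  expect_equal(all_only$items[[1]], "A")

  expect_error(apriori(transaction_set(list())), "empty")
})

test_that("apriori equals the powerset oracle on random transaction sets", {
  set.seed(101)
  for (rep in 1:40) {
    ts <- random_tset()
    min_sup <- sample(c(0.05, 0.2, 0.5), 1)
    got <- apriori(ts, min_sup)
    want <- oracle_frequents(ts, min_sup)
    expect_equal(nrow(got), length(want$sets))
    key <- function(s) paste(sort(s), collapse = "|")
    got_map <- setNames(got$count, vapply(got$items, key, character(1)))
    want_map <- setNames(want$counts, vapply(want$sets, key, character(1)))
    if (length(want_map) == 0L) {
      expect_length(got_map, 0L)
    } else {
      expect_mapequal(as.list(got_map), as.list(want_map))
    }
  }
})

test_that("rule measures obey their defining identities exactly", {
  set.seed(102)
  for (rep in 1:10) {
    ts <- random_tset()
    rules <- mine_rules(ts, min_sup = 0.05, min_conf = 0.05)
    if (nrow(rules) == 0) next
    expect_equal(rules$lift * rules$sup_b, rules$conf, tolerance = 1e-12)
    expect_equal(rules$conf * rules$sup_a, rules$sup, tolerance = 1e-12)
    expect_true(all(rules$sup <= pmin(rules$sup_a, rules$sup_b) + 1e-12))
    expect_true(all(is.na(rules$phi) | abs(rules$phi) <= 1))
    # independent oracle per rule
    for (i in seq_len(nrow(rules))) {
      o <- oracle_rule(ts, rules$antecedent[i], rules$consequent[i])
      expect_equal(rules$lift[i], o$lift, tolerance = 1e-12)
      expect_equal(rules$phi[i], o$phi, tolerance = 1e-12)
    }
  }
})

test_that("the confidence threshold filters and never adds rules", {
  ts <- transaction_set(c(rep(list(c("Caiman", "Dale")), 3),
                          list(c("Caiman", "Fera"))))
  loose <- mine_rules(ts, 0.01, 0.5)
  strict <- mine_rules(ts, 0.01, 0.9)
  expect_true(all(strict$conf >= 0.9))
  expect_lt(nrow(strict), nrow(loose))
  key <- paste(strict$antecedent, strict$consequent)
  expect_true(all(key %in% paste(loose$antecedent, loose$consequent)))
})

test_that("phi reproduces its closed-form values and undefined cases", {
  expect_equal(phi_coefficient(0.625, 0.375, 0.375), 0.6, tolerance = 1e-12)
  expect_true(is.na(phi_coefficient(1, 1, 1)))
  expect_equal(phi_coefficient(0.5, 0.5, 0.25), 0)
  # antisymmetry under complementing one indicator on a 2x2 construction
  n11 <- 3; n10 <- 2; n01 <- 1; n00 <- 4; D <- 10
  sup_a <- (n11 + n10) / D; sup_b <- (n11 + n01) / D
  p1 <- phi_coefficient(sup_a, sup_b, n11 / D)
  p2 <- phi_coefficient(sup_a, 1 - sup_b, n10 / D)
  expect_equal(p1, -p2, tolerance = 1e-12)
})

test_that("lift is 1 exactly at independence", {
  # A in 2 of 4, B in 2 of 4, jointly in 1: sup = sup_a * sup_b
  ts <- transaction_set(list(c("A", "B"), "A", "B", "Z"))
  r <- mine_rules(ts, 0.01, 0.01)
  ab <- r[r$antecedent == "A" & r$consequent == "B", ]
  expect_equal(ab$lift, 1)
  expect_equal(ab$sup, ab$sup_a * ab$sup_b)
  expect_equal(ab$phi, 0)
})

test_that("phi bands map values with half-open edges toward the stronger class", {
  expect_equal(classify_phi(0.6), "moderate positive")
  expect_equal(classify_phi(-1), "perfect negative")
  expect_equal(classify_phi(0), "weak or none")
  expect_equal(classify_phi(c(0.35, 0.36, 0.67, 0.68, 1, NA)),
               c("weak or none", "moderate positive", "moderate positive",
                 "strong positive", "perfect positive", "undefined"))
  expect_equal(classify_phi(-0.68), "strong negative")
})

test_that("Cramer's V hits its closed-form anchors", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(cramers_v(matrix(5, 2, 2)), 0)
  # hand chi-square: n (ad - bc)^2 / (r1 r2 c1 c2) = 3, V = sqrt(3/3)
  expect_equal(cramers_v(matrix(c(2, 0, 0, 1), 2)), 1)
  set.seed(103)
  for (rep in 1:20) {
    tab <- matrix(sample(1:9, 6, replace = TRUE), 2, 3)
    expect_equal(cramers_v(tab),
                 sqrt(chi2_by_hand(tab) / (sum(tab) * 1)),
                 tolerance = 1e-12)
  }
  expect_warning(v <- cramers_v(matrix(c(2, 1), 1, 2)), "degenerate")
  expect_true(is.na(v))
})

test_that("pair contingency tables follow the event counts", {
  t0 <- as.POSIXct("2015-02-05", tz = "UTC")
  ev <- tibble::tibble(
    animal_a = c("Caiman", "Caiman", "Caiman"),
    animal_b = c("Dale", "Dale", "Fera"),
    timestamp = t0 + 1:3 * 3600)
  tab <- pair_contingency(ev)
  expect_equal(dim(tab), c(1L, 2L))
  expect_equal(as.vector(tab), c(2L, 1L))
  expect_true(attr(tab, "degenerate"))

  ev2 <- tibble::tibble(
    animal_a = rep(c("a", "c"), each = 3),
    animal_b = rep(c("b", "d"), each = 3),
    timestamp = t0 + 1:6 * 3600)
  tab2 <- pair_contingency(ev2)
  expect_false(attr(tab2, "degenerate"))
  expect_equal(cramers_v(tab2), 1)
  expect_error(pair_contingency(ev2[0, ]), "no events")

  cv <- cramer_by_month(ev2)
  expect_equal(cv$n_events, 6L)
  expect_equal(cv$cramers_v, 1)
})
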