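# Independent oracles and fixture builders. Each oracle is a deliberately
# naive reimplementation (brute force / enumeration) kept free of the code
# paths it checks.

M_PER_DEG <- pi / 180 * 6371008.8

# fixes at local meter offsets on the equator, where the package's
# equirectangular projection is exact and axis-aligned
fixes_at <- function(x, y, t_hours, id = "a",
                     t0 = as.POSIXct("2015-02-01 00:00:00", tz = "UTC")) {
  as_fixes(tibble::tibble(
    animal_id = id,
    timestamp = t0 + t_hours * 3600,
    lat = y / M_PER_DEG,
    lon = x / M_PER_DEG))
}

# --- rule mining -----------------------------------------------------------

# exhaustive powerset enumeration of frequent itemsets (bitmask subset test
# against every transaction; no candidate generation or pruning)
oracle_frequents <- function(tset, min_sup) {
  items <- sort(unique(unlist(tset$items)))
  D <- length(tset$items)
  tmask <- vapply(tset$items, function(t)
    sum(bitwShiftL(1L, which(items %in% t) - 1L)), numeric(1))
  subsets <- list(); counts <- integer(0)
  for (m in seq_len(2^length(items) - 1L)) {
    cnt <- sum(bitwAnd(tmask, m) == m)
    if (cnt / D >= min_sup - 1e-12) {
      subsets[[length(subsets) + 1L]] <-
        items[bitwAnd(m, bitwShiftL(1L, seq_along(items) - 1L)) != 0L]
      counts <- c(counts, cnt)
    }
  }
  list(sets = subsets, counts = counts)
}

# rule measures straight from transaction counts
oracle_rule <- function(tset, a, b) {
  D <- length(tset$items)
  n_a <- sum(vapply(tset$items, function(t) a %in% t, logical(1)))
  n_b <- sum(vapply(tset$items, function(t) b %in% t, logical(1)))
  n_ab <- sum(vapply(tset$items, function(t) all(c(a, b) %in% t),
                     logical(1)))
  sup_a <- n_a / D; sup_b <- n_b / D; sup <- n_ab / D
  conf <- sup / sup_a
  den2 <- sup_a * sup_b * (1 - sup_a) * (1 - sup_b)
  list(sup_a = sup_a, sup_b = sup_b, sup = sup, conf = conf,
       lift = conf / sup_b,
       phi = if (den2 <= 1e-15) NA_real_ else
         (sup - sup_a * sup_b) / sqrt(den2))
}

random_tset <- function(n_items = 12, n_trans = 64) {
  items <- LETTERS[seq_len(sample(2:n_items, 1))]
  nt <- sample(2:n_trans, 1)
  transaction_set(lapply(seq_len(nt), function(i) {
    sample(items, sample(seq_len(min(5, length(items))), 1))
  }))
}

chi2_by_hand <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}

# --- proximity -------------------------------------------------------------

# quadratic all-pairs scan over every fix pair of distinct animals
oracle_events <- function(fixes, radius, time_window) {
  fixes <- dplyr::arrange(fixes, animal_id, timestamp)
  out <- list()
  for (i in seq_len(nrow(fixes))) {
    for (j in seq_len(nrow(fixes))) {
      if (fixes$animal_id[i] >= fixes$animal_id[j]) next
      dt <- abs(as.numeric(fixes$timestamp[i]) -
                  as.numeric(fixes$timestamp[j]))
      if (dt > time_window + 1e-9) next
      d <- vincenty_distance(fixes$lat[i], fixes$lon[i],
                             fixes$lat[j], fixes$lon[j])
      if (d < radius) {
        out[[length(out) + 1L]] <- tibble::tibble(
          animal_a = fixes$animal_id[i], animal_b = fixes$animal_id[j],
          timestamp = fixes$timestamp[i], distance_m = d)
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), timestamp, animal_a, animal_b,
                 distance_m)
}

# --- residence geometry ----------------------------------------------------

# fine discretization of every path segment; counts sub-segment lengths and
# times falling inside the circle around each fix
oracle_residence <- function(x, y, t_sec, radius, n_sub = 4000L) {
  n <- length(x)
  rd <- rt <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1L)) {
      u <- (seq_len(n_sub) - 0.5) / n_sub
      px <- x[s] + u * (x[s + 1] - x[s])
      py <- y[s] + u * (y[s + 1] - y[s])
      inside <- (px - x[i])^2 + (py - y[i])^2 <= radius^2
      seg_len <- sqrt((x[s + 1] - x[s])^2 + (y[s + 1] - y[s])^2)
      rd[i] <- rd[i] + sum(inside) / n_sub * seg_len
      rt[i] <- rt[i] + sum(inside) / n_sub * (t_sec[s + 1] - t_sec[s])
    }
  }
  list(rd = rd, rt = rt)
}

# --- landcover -------------------------------------------------------------

oracle_class_at <- function(grid, lat, lon) {
  vapply(seq_along(lat), function(i) {
    col <- floor((lon[i] - grid$xll) / grid$cellsize) + 1
    yul <- grid$yll + grid$nrows * grid$cellsize
    row <- floor((yul - lat[i]) / grid$cellsize) + 1
    if (lat[i] == yul) row <- 1
    if (col < 1 || col > grid$ncols || row < 1 || row > grid$nrows) {
      return(NA_character_)
    }
    code <- grid$codes[row, col]
    if (code == grid$nodata) return(NA_character_)
    if (is.null(grid$legend)) return(as.character(code))
    nm <- grid$legend[as.character(code)]
    if (is.na(nm)) "unknown" else unname(nm)
  }, character(1))
}

# tm_states tibble from a truth table (for bout comparisons)
truth_states <- function(states_tbl) {
  out <- dplyr::mutate(states_tbl, residual = 0)
  class(out) <- c("tm_states", class(tibble::tibble()))
  out
}
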