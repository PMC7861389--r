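#' Apriori frequent-itemset mining
#'
#' Level-wise candidate generation with the downward-closure prune: a
#' k-itemset is a candidate only if every (k-1)-subset is frequent, and
#' exactly the itemsets with support `>= min_sup` are returned. Supports are
#' exact rationals `count / D` reported as doubles.
#'
#' @param tset A [transaction_set()].
#' @param min_sup Minimum support as a fraction in (0, 1].
#' @return A tibble of class `tm_itemsets`: `items` (list column of sorted
#'   character vectors), `size`, `count`, `support`; attribute `D`.
#' @export
apriori <- function(tset, min_sup = 0.01) {
  stopifnot(inherits(tset, "tm_transactions"), min_sup > 0, min_sup <= 1)
  D <- tset$D
  if (D < 1L) stop("empty transaction set")
  items <- sort(unique(unlist(tset$items)))
  # membership matrix: transactions x items
  M <- vapply(items, function(it) purrr::map_lgl(tset$items, \(t) it %in% t),
              logical(D))
  M <- matrix(M, nrow = D, dimnames = list(NULL, items))

  min_count <- min_sup * D
  counts1 <- colSums(M)
  frequent <- list()
  Lk <- as.list(items[counts1 >= min_count - 1e-9])
  counts_k <- counts1[counts1 >= min_count - 1e-9]
  if (length(Lk)) {
    frequent[[1L]] <- tibble::tibble(items = Lk, size = 1L,
                                     count = as.integer(counts_k))
  }
  k <- 1L
  while (length(Lk) > 1L) {
    cand <- apriori_candidates(Lk)
    if (!length(cand)) break
    cnt <- purrr::map_int(cand, function(s) {
      sum(rowSums(M[, s, drop = FALSE]) == length(s))
    })
    keep <- cnt >= min_count - 1e-9
    Lk <- cand[keep]
    k <- k + 1L
    if (length(Lk)) {
      frequent[[k]] <- tibble::tibble(items = Lk, size = k,
                                      count = as.integer(cnt[keep]))
    }
  }
  out <- dplyr::bind_rows(frequent)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(items = list(), size = integer(),
                          count = integer())
  }
  out$support <- out$count / D
  structure(out, D = D, scope = tset$scope,
            class = c("tm_itemsets", class(out)))
}

# Join step: merge frequent (k-1)-itemsets sharing their first k-2 items,
# then prune candidates with any infrequent (k-1)-subset.
apriori_candidates <- function(Lk) {
  k <- length(Lk[[1L]]) + 1L
  keys <- purrr::map_chr(Lk, paste, collapse = "\r")
  cand <- list()
  for (i in seq_along(Lk)) {
    for (j in seq_along(Lk)) {
      if (j <= i) next
      a <- Lk[[i]]; b <- Lk[[j]]
      if (k == 2L || identical(a[-(k - 1L)], b[-(k - 1L)])) {
        new <- sort(unique(c(a, b)))
        if (length(new) != k) next
        subs_ok <- all(purrr::map_lgl(seq_len(k), function(drop) {
          paste(new[-drop], collapse = "\r") %in% keys
        }))
        if (subs_ok) cand[[length(cand) + 1L]] <- new
      }
    }
  }
  unique(cand)
}

#' Generate single-antecedent association rules with interestingness measures
#'
#' From every frequent item pair \{A, B\}, both directed rules `A -> B` and
#' `B -> A` are formed and kept when their confidence reaches `min_conf`.
#' Measures: `sup_a = count(A)/D`, `sup_b = count(B)/D`,
#' `sup = count(A,B)/D`, `conf = sup / sup_a`, `lift = conf / sup_b`
#' (`> 1` positive dependence, `< 1` negative, `= 1` independence), and the
#' phi coefficient ([phi_coefficient()]) with its correlation band
#' ([classify_phi()]).
#'
#' @param frequents Output of [apriori()] on the same transaction set.
#' @param tset The [transaction_set()] the itemsets were mined from.
#' @param min_conf Minimum confidence in (0, 1].
#' @return A tibble of class `tm_rules`: `antecedent`, `consequent`, `scope`,
#'   `sup_a`, `sup_b`, `sup`, `conf`, `lift`, `phi`, `phi_band`, `count`.
#' @export
generate_rules <- function(frequents, tset, min_conf = 0.5) {
  stopifnot(min_conf > 0, min_conf <= 1)
  D <- attr(frequents, "D")
  singles <- frequents[frequents$size == 1L, ]
  sup1 <- setNames(singles$count, purrr::map_chr(singles$items, identity))
  pairs <- frequents[frequents$size == 2L, ]
  if (nrow(pairs) == 0L) return(empty_rules(tset$scope))
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ab <- pairs$items[[i]]
    n_ab <- pairs$count[i]
    purrr::map(list(ab, rev(ab)), function(d) {
      a <- d[1]; b <- d[2]
      sup_a <- sup1[[a]] / D
      sup_b <- sup1[[b]] / D
      sup <- n_ab / D
      conf <- sup / sup_a
      tibble::tibble(
        antecedent = a, consequent = b,
        sup_a = sup_a, sup_b = sup_b, sup = sup, conf = conf,
        lift = conf / sup_b,
        phi = phi_coefficient(sup_a, sup_b, sup),
        count = n_ab)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$conf >= min_conf - 1e-12) |>
    dplyr::mutate(phi_band = classify_phi(.data$phi),
                  scope = tset$scope %||% NA_character_) |>
    dplyr::select("antecedent", "consequent", "scope", "sup_a", "sup_b",
                  "sup", "conf", "lift", "phi", "phi_band", "count") |>
    dplyr::arrange(.data$antecedent, .data$consequent)
  structure(out, D = D, class = c("tm_rules", class(out)))
}

empty_rules <- function(scope = NULL) {
  structure(
    tibble::tibble(antecedent = character(), consequent = character(),
                   scope = character(), sup_a = numeric(), sup_b = numeric(),
                   sup = numeric(), conf = numeric(), lift = numeric(),
                   phi = numeric(), phi_band = character(),
                   count = integer()),
    class = c("tm_rules", class(tibble::tibble())))
}

#' Mine association rules from a transaction set in one call
#'
#' [apriori()] followed by [generate_rules()].
#'
#' @inheritParams apriori
#' @inheritParams generate_rules
#' @return A `tm_rules` tibble.
#' @export
mine_rules <- function(tset, min_sup = 0.01, min_conf = 0.5) {
  generate_rules(apriori(tset, min_sup = min_sup), tset, min_conf = min_conf)
}

#' Phi coefficient of an item pair from its supports
#'
#' The 2x2 correlation coefficient between the presence indicators of the
#' antecedent and consequent:
#' `(sup - sup_a * sup_b) / sqrt(sup_a * sup_b * (1 - sup_a) * (1 - sup_b))`.
#' Undefined (NA) exactly when the denominator is zero, i.e. when either
#' marginal support is 0 or 1 — an item present in every transaction (or
#' none) has a constant indicator with no correlation to measure.
#'
#' @param sup_a,sup_b Marginal supports in \[0, 1\].
#' @param sup Joint support, `<= min(sup_a, sup_b)`.
#' @return Phi in \[-1, 1\], or `NA` when undefined. Vectorized.
#' @export
phi_coefficient <- function(sup_a, sup_b, sup) {
  den2 <- sup_a * sup_b * (1 - sup_a) * (1 - sup_b)
  out <- ifelse(den2 <= 1e-15, NA_real_,
                (sup - sup_a * sup_b) / sqrt(den2))
  pmin(1, pmax(-1, out))
}

#' Correlation band of a phi coefficient
#'
#' Bands: exact -1 / +1 are "perfect"; `|phi| >= 0.68` strong;
#' `0.36 <= |phi| < 0.68` moderate; `|phi| < 0.36` weak or none. Band edges
#' are half-open toward the stronger class, and exact +-1 takes the perfect
#' label with precedence over the open strong band.
#'
#' @param phi Numeric vector of phi values (NA allowed).
#' @return Character vector of band labels ("undefined" for NA).
#' @export
classify_phi <- function(phi) {
  sign_lab <- ifelse(phi < 0, "negative", "positive")
  dplyr::case_when(
    is.na(phi) ~ "undefined",
    phi == 1 ~ "perfect positive",
    phi == -1 ~ "perfect negative",
    abs(phi) >= 0.68 ~ paste("strong", sign_lab),
    abs(phi) >= 0.36 ~ paste("moderate", sign_lab),
    TRUE ~ "weak or none")
}

#' Cramer's V association strength for a contingency table
#'
#' `sqrt(chi2 / (n * (min(r, c) - 1)))` with the Pearson chi-square statistic
#' (no continuity correction). Ranges from 0 (independence) to 1 (total
#' association).
#'
#' @param tab A matrix or table of non-negative counts with at least 2 rows
#'   and 2 columns and no all-zero marginal; degenerate tables return `NA`
#'   with a warning.
#' @return Cramer's V in \[0, 1\], or `NA` for a degenerate table.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n <= 0 || any(dim(tab) < 2L) ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table; Cramer's V undefined")
    return(NA_real_)
  }
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (n * (min(dim(tab)) - 1L)))
}

#' Animal-pair contingency table of co-occurrence events
#'
#' Cross-tabulates the month's events by the identities of the two pair
#' members (pairs in canonical alphabetical order, so rows are `animal_a`
#' and columns `animal_b`). Tables with fewer than two distinct rows or
#' columns are flagged degenerate: Cramer's V is undefined on them.
#'
#' @param events A `tm_events` tibble (typically one month's events).
#' @return A count matrix with attribute `degenerate` (logical).
#' @export
pair_contingency <- function(events) {
  if (nrow(events) == 0L) stop("no events to tabulate")
  tab <- table(animal_a = events$animal_a, animal_b = events$animal_b)
  tab <- as.matrix(unclass(tab))
  attr(tab, "degenerate") <- any(dim(tab) < 2L)
  tab
}

#' Monthly Cramer's V validation of pairwise co-occurrence
#'
#' Convenience wrapper mirroring the contingency validation layer: per
#' calendar month, builds the [pair_contingency()] table and computes
#' [cramers_v()] (NA where degenerate).
#'
#' @param events A `tm_events` tibble.
#' @return A tibble with `year`, `month`, `n_events`, `cramers_v`.
#' @export
cramer_by_month <- function(events) {
  by_month <- partition_by_month(events)
  purrr::imap(by_month, function(df, key) {
    tab <- pair_contingency(df)
    v <- if (attr(tab, "degenerate")) NA_real_ else cramers_v(tab)
    tibble::tibble(year = df$year[1], month = df$month[1],
                   n_events = nrow(df), cramers_v = v)
  }) |> dplyr::bind_rows()
}
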