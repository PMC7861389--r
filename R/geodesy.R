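#' Vincenty inverse geodesic distance on the WGS84 ellipsoid
#'
#' Iterative inverse solution for the ellipsoidal distance between coordinate
#' pairs (a = 6378137 m, f = 1/298.257223563), converged to a change in
#' longitude difference below `tol` radians. The handful of near-antipodal
#' pairs for which Vincenty's iteration does not converge (irrelevant at
#' telemetry scales) fall back to the spherical great-circle distance with a
#' warning; the affected indices are returned in `attr(, "fallback")`.
#'
#' All arguments are recycled to a common length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @param tol Convergence tolerance in radians (default 1e-12).
#' @param max_iter Iteration cap before declaring non-convergence.
#' @return Numeric vector of distances in meters. Exactly 0 for coincident
#'   points; symmetric in its arguments.
#' @export
#' @examples
#' vincenty_distance(0, 0, 0, 1)  # one degree along the equator
vincenty_distance <- function(lat1, lon1, lat2, lon2,
                              tol = 1e-12, max_iter = 200L) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 180), all(abs(lon2) <= 180))
  # canonical endpoint order makes symmetry exact to the last bit
  sw <- lat1 > lat2 | (lat1 == lat2 & lon1 > lon2)
  if (any(sw)) {
    tmp <- lat1[sw]; lat1[sw] <- lat2[sw]; lat2[sw] <- tmp
    tmp <- lon1[sw]; lon1[sw] <- lon2[sw]; lon2[sw] <- tmp
  }

  a <- 6378137
  f <- 1 / 298.257223563
  b <- a * (1 - f)
  rad <- pi / 180

  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  L <- (lon2 - lon1) * rad
  U1 <- atan((1 - f) * tan(phi1))
  U2 <- atan((1 - f) * tan(phi2))
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinU2 <- sin(U2); cosU2 <- cos(U2)

  lambda <- L
  dist <- numeric(n)
  coincident <- lat1 == lat2 & lon1 == lon2
  active <- !coincident
  sigma <- sinSigma <- cosSigma <- cos2Alpha <- cos2SigmaM <- numeric(n)
  converged <- coincident

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    i <- which(active)
    sinL <- sin(lambda[i]); cosL <- cos(lambda[i])
    ss <- sqrt((cosU2[i] * sinL)^2 +
                 (cosU1[i] * sinU2[i] - sinU1[i] * cosU2[i] * cosL)^2)
    cs <- sinU1[i] * sinU2[i] + cosU1[i] * cosU2[i] * cosL
    sg <- atan2(ss, cs)
    sinAlpha <- ifelse(ss == 0, 0, cosU1[i] * cosU2[i] * sinL / ss)
    c2a <- 1 - sinAlpha^2
    c2sm <- ifelse(c2a == 0, 0, cs - 2 * sinU1[i] * sinU2[i] / c2a)
    C <- f / 16 * c2a * (4 + f * (4 - 3 * c2a))
    lamNew <- L[i] + (1 - C) * f * sinAlpha *
      (sg + C * ss * (c2sm + C * cs * (-1 + 2 * c2sm^2)))
    done <- abs(lamNew - lambda[i]) < tol | ss == 0
    lambda[i] <- lamNew
    sinSigma[i] <- ss; cosSigma[i] <- cs; sigma[i] <- sg
    cos2Alpha[i] <- c2a; cos2SigmaM[i] <- c2sm
    converged[i[done]] <- TRUE
    active[i[done]] <- FALSE
  }

  ok <- converged & !coincident
  if (any(ok)) {
    i <- which(ok)
    u2 <- cos2Alpha[i] * (a^2 - b^2) / b^2
    A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
    B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
    dSigma <- B * sinSigma[i] *
      (cos2SigmaM[i] + B / 4 * (cosSigma[i] * (-1 + 2 * cos2SigmaM[i]^2) -
        B / 6 * cos2SigmaM[i] * (-3 + 4 * sinSigma[i]^2) *
          (-3 + 4 * cos2SigmaM[i]^2)))
    dist[i] <- b * A * (sigma[i] - dSigma)
  }

  fallback <- which(!converged)
  if (length(fallback)) {
    warning(length(fallback),
            " near-antipodal pair(s) did not converge; ",
            "great-circle fallback used")
    dist[fallback] <- haversine_distance(lat1[fallback], lon1[fallback],
                                         lat2[fallback], lon2[fallback])
    attr(dist, "fallback") <- fallback
  }
  dist
}

#' Spherical great-circle (haversine) distance
#'
#' @inheritParams vincenty_distance
#' @param radius Sphere radius in meters (mean Earth radius).
#' @return Distances in meters.
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2, radius = 6371008.8) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  h <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * radius * asin(pmin(1, sqrt(h)))
}

#' Per-fix step lengths of each trajectory
#'
#' @param fixes A fix tibble (time-ordered per animal; see
#'   [build_trajectories()]).
#' @return The input with a `step_m` column: geodesic length of the step
#'   ending at each fix (NA for the first fix of each animal).
#' @export
step_lengths <- function(fixes) {
  fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(step_m = c(NA_real_, vincenty_distance(
      .data$lat[-dplyr::n()], .data$lon[-dplyr::n()],
      .data$lat[-1], .data$lon[-1]))) |>
    dplyr::ungroup()
}

# Local equirectangular projection (meters) about an origin; adequate for the
# sub-50-km extents residence and kernel computations operate on.
project_local <- function(lat, lon, origin) {
  m_per_deg <- pi / 180 * 6371008.8
  list(x = (lon - origin[["lon"]]) * m_per_deg * cos(origin[["lat"]] * pi / 180),
       y = (lat - origin[["lat"]]) * m_per_deg)
}

unproject_local <- function(x, y, origin) {
  m_per_deg <- pi / 180 * 6371008.8
  list(lat = origin[["lat"]] + y / m_per_deg,
       lon = origin[["lon"]] + x / (m_per_deg * cos(origin[["lat"]] * pi / 180)))
}
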