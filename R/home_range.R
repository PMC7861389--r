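#' Kernel utilization distribution of a track
#'
#' Estimates the utilization distribution (UD) — the probability density of
#' the animal's space use — as a bivariate normal kernel estimate: around
#' each relocation a circular normal with standard deviation `bandwidth` is
#' placed, the `n` kernels are averaged over a regular grid and renormalized
#' so the gridded density integrates to one. Coordinates are projected to
#' meters with a local equirectangular projection about the grid origin
#' (default: the fix centroid).
#'
#' @param fixes A fix tibble for one animal (>= 5 fixes for a meaningful
#'   estimate; fewer raises an error, all-identical fixes give a delta-like
#'   UD with a warning).
#' @param bandwidth Kernel standard deviation in meters; `NULL` uses the
#'   ad-hoc reference rule `h = sigma * n^(-1/6)` with `sigma` the mean of
#'   the coordinate standard deviations.
#' @param spec Optional shared grid specification from [ud_grid_spec()]
#'   (needed when UDs of several animals must live on one grid for overlap).
#' @param cells Grid cells per axis when no `spec` is given (default 100).
#' @param margin_factor Grid margin beyond the fix extent, in bandwidths
#'   (default 4).
#' @return An object of class `tm_ud`: list with cell-center coordinates
#'   `x`, `y` (meters), density matrix `z` (`length(x)` rows), `h`,
#'   `cell_area` (m^2), `origin` (lat/lon), `n`, `animal_id`.
#' @export
kernel_ud <- function(fixes, bandwidth = NULL, spec = NULL, cells = 100,
                      margin_factor = 4) {
  fixes <- tibble::as_tibble(fixes)
  n <- nrow(fixes)
  if (n < 5L) stop("kernel UD needs >= 5 fixes")
  origin <- if (!is.null(spec)) spec$origin else
    c(lat = mean(fixes$lat), lon = mean(fixes$lon))
  p <- project_local(fixes$lat, fixes$lon, origin)
  x <- p$x; y <- p$y

  h <- bandwidth
  if (is.null(h)) {
    sigma <- mean(c(sd(x), sd(y)))
    h <- sigma * n^(-1 / 6)
  }
  if (!is.finite(h) || h <= 0) {
    warning("degenerate fixes (zero spread); delta-like UD")
    h <- 1
  }

  if (!is.null(spec)) {
    gx <- spec$x; gy <- spec$y
  } else {
    xr <- range(x) + c(-1, 1) * margin_factor * h
    yr <- range(y) + c(-1, 1) * margin_factor * h
    gx <- seq(xr[1], xr[2], length.out = cells)
    gy <- seq(yr[1], yr[2], length.out = cells)
  }
  dx <- if (length(gx) > 1) gx[2] - gx[1] else 1
  dy <- if (length(gy) > 1) gy[2] - gy[1] else 1
  Kx <- exp(-outer(gx, x, "-")^2 / (2 * h^2))
  Ky <- exp(-outer(gy, y, "-")^2 / (2 * h^2))
  z <- (Kx %*% t(Ky)) / (n * 2 * pi * h^2)
  cell_area <- dx * dy
  total <- sum(z) * cell_area
  if (total <= 0) stop("zero UD mass on grid; grid does not cover the track")
  z <- z / total

  structure(list(x = gx, y = gy, z = z, h = h, cell_area = cell_area,
                 origin = origin, n = n,
                 animal_id = fixes$animal_id[1] %||% NA_character_),
            class = "tm_ud")
}

#' Shared UD grid specification for several tracks
#'
#' Builds one grid covering all supplied fixes so that per-animal UDs are
#' directly comparable cell by cell (required by [ud_overlap()]).
#'
#' @param fixes Fix tibble (any number of animals).
#' @param cells Cells per axis.
#' @param margin_m Margin beyond the joint extent, meters.
#' @return A list with `origin`, `x`, `y` usable as `spec` in [kernel_ud()].
#' @export
ud_grid_spec <- function(fixes, cells = 100, margin_m = 2000) {
  origin <- c(lat = mean(fixes$lat), lon = mean(fixes$lon))
  p <- project_local(fixes$lat, fixes$lon, origin)
  xr <- range(p$x) + c(-1, 1) * margin_m
  yr <- range(p$y) + c(-1, 1) * margin_m
  list(origin = origin,
       x = seq(xr[1], xr[2], length.out = cells),
       y = seq(yr[1], yr[2], length.out = cells))
}

#' Isopleth (core-area) mask of a utilization distribution
#'
#' The p-isopleth is the smallest set of highest-density cells whose summed
#' probability mass reaches `p` — the minimum area in which the animal is
#' found with probability `p`. Ties in density are resolved in row-major
#' cell order (deterministic). `p = 0.95` is the conventional home range,
#' `p = 0.50` the core area.
#'
#' @param ud A `tm_ud` object.
#' @param p Mass fraction in (0, 1).
#' @return A list of class `tm_isopleth`: logical `mask` (same shape as
#'   `ud$z`), `area_m2`, `area_km2`, `p`, `n_cells`.
#' @export
isopleth <- function(ud, p = 0.95) {
  stopifnot(p > 0, p < 1)
  mass <- as.vector(ud$z) * ud$cell_area
  ord <- order(mass, seq_along(mass), decreasing = c(TRUE, FALSE),
               method = "radix")
  k <- which(cumsum(mass[ord]) >= p)[1]
  if (is.na(k)) k <- length(mass)
  mask <- matrix(FALSE, nrow = nrow(ud$z), ncol = ncol(ud$z))
  mask[ord[seq_len(k)]] <- TRUE
  structure(list(mask = mask, area_m2 = k * ud$cell_area,
                 area_km2 = k * ud$cell_area / 1e6, p = p, n_cells = k),
            class = "tm_isopleth")
}

#' Home-range overlap between two utilization distributions
#'
#' Method `"hr"` (default): the directional pair of isopleth area overlaps —
#' the fraction of A's p-isopleth cells that also lie inside B's, and vice
#' versa. Method `"vi"`: the volume intersection
#' `sum(min(ud_a, ud_b)) * cell_area`, symmetric and in \[0, 1\].
#'
#' UDs estimated on different grids are bilinearly resampled onto a common
#' union grid first.
#'
#' @param ud_a,ud_b `tm_ud` objects.
#' @param p Isopleth level for method `"hr"`.
#' @param method `"hr"` or `"vi"`.
#' @return For `"hr"`, named numeric `c(a_in_b=, b_in_a=)`; for `"vi"`, a
#'   single numeric value.
#' @export
ud_overlap <- function(ud_a, ud_b, p = 0.95, method = c("hr", "vi")) {
  method <- match.arg(method)
  if (!same_grid(ud_a, ud_b)) {
    spec <- union_grid(ud_a, ud_b)
    ud_a <- resample_ud(ud_a, spec$x, spec$y)
    ud_b <- resample_ud(ud_b, spec$x, spec$y)
  }
  if (method == "vi") {
    return(sum(pmin(ud_a$z, ud_b$z)) * ud_a$cell_area)
  }
  ma <- isopleth(ud_a, p)$mask
  mb <- isopleth(ud_b, p)$mask
  c(a_in_b = sum(ma & mb) / sum(ma),
    b_in_a = sum(ma & mb) / sum(mb))
}

same_grid <- function(a, b) {
  length(a$x) == length(b$x) && length(a$y) == length(b$y) &&
    isTRUE(all.equal(a$x, b$x, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$y, b$y, tolerance = 1e-9)) &&
    isTRUE(all.equal(unname(a$origin), unname(b$origin), tolerance = 1e-12))
}

union_grid <- function(a, b, max_cells = 400L) {
  if (!isTRUE(all.equal(unname(a$origin), unname(b$origin),
                        tolerance = 1e-12))) {
    stop("UDs with different projection origins; rebuild with a shared ",
         "ud_grid_spec()")
  }
  dx <- min(a$x[2] - a$x[1], b$x[2] - b$x[1])
  dy <- min(a$y[2] - a$y[1], b$y[2] - b$y[1])
  xr <- range(c(a$x, b$x)); yr <- range(c(a$y, b$y))
  nx <- min(max_cells, max(2L, ceiling(diff(xr) / dx) + 1L))
  ny <- min(max_cells, max(2L, ceiling(diff(yr) / dy) + 1L))
  list(x = seq(xr[1], xr[2], length.out = nx),
       y = seq(yr[1], yr[2], length.out = ny))
}

#' Resample a UD onto a new grid by bilinear interpolation
#'
#' Cells outside the source grid get zero density. Bilinear interpolation
#' approximately conserves the integrated mass (no renormalization is
#' applied, so conservation can be verified directly).
#'
#' @param ud A `tm_ud` object.
#' @param x,y New cell-center coordinate vectors (meters, same projection).
#' @return A `tm_ud` on the new grid.
#' @export
resample_ud <- function(ud, x, y) {
  zi <- bilinear_grid(ud$x, ud$y, ud$z, x, y)
  structure(list(x = x, y = y, z = zi, h = ud$h,
                 cell_area = (x[2] - x[1]) * (y[2] - y[1]),
                 origin = ud$origin, n = ud$n, animal_id = ud$animal_id),
            class = "tm_ud")
}

bilinear_grid <- function(gx, gy, z, nx, ny) {
  ix <- findInterval(nx, gx)
  iy <- findInterval(ny, gy)
  out <- matrix(0, nrow = length(nx), ncol = length(ny))
  okx <- ix >= 1L & ix < length(gx)
  oky <- iy >= 1L & iy < length(gy)
  # include exact right/top edges
  edgex <- nx == gx[length(gx)]
  edgey <- ny == gy[length(gy)]
  ix[edgex] <- length(gx) - 1L; okx <- okx | edgex
  iy[edgey] <- length(gy) - 1L; oky <- oky | edgey
  wx <- (nx - gx[ix]) / (gx[ix + ifelse(okx, 1L, 0L)] - gx[ix])
  for (j in which(oky)) {
    jy <- iy[j]
    wy <- (ny[j] - gy[jy]) / (gy[jy + 1L] - gy[jy])
    i <- which(okx)
    z00 <- z[cbind(ix[i], jy)]; z10 <- z[cbind(ix[i] + 1L, jy)]
    z01 <- z[cbind(ix[i], jy + 1L)]; z11 <- z[cbind(ix[i] + 1L, jy + 1L)]
    out[i, j] <- (1 - wx[i]) * (1 - wy) * z00 + wx[i] * (1 - wy) * z10 +
      (1 - wx[i]) * wy * z01 + wx[i] * wy * z11
  }
  out
}

#' @export
print.tm_ud <- function(x, ...) {
  cat("<kernel UD", if (!is.na(x$animal_id)) paste0(" [", x$animal_id, "]"),
      ": ", length(x$x), "x", length(x$y), " cells, h = ",
      signif(x$h, 4), " m, n = ", x$n, ">\n", sep = "")
  invisible(x)
}

#' @export
tidy.tm_ud <- function(x, ...) {
  ud <- x
  grid <- tidyr::expand_grid(xi = seq_along(ud$x), yi = seq_along(ud$y))
  ll <- unproject_local(ud$x[grid$xi], ud$y[grid$yi], ud$origin)
  tibble::tibble(
    x = ud$x[grid$xi], y = ud$y[grid$yi],
    lat = ll$lat, lon = ll$lon,
    density = ud$z[cbind(grid$xi, grid$yi)])
}

#' @export
glance.tm_ud <- function(x, ...) {
  tibble::tibble(
    animal_id = x$animal_id, n = x$n, bandwidth_m = x$h,
    cells_x = length(x$x), cells_y = length(x$y),
    cell_area_m2 = x$cell_area,
    area95_km2 = isopleth(x, 0.95)$area_km2,
    area50_km2 = isopleth(x, 0.50)$area_km2)
}

#' Export a UD as an ESRI ASCII raster
#'
#' Writes the density grid in geographic coordinates (cell size taken from
#' the longitude spacing at the grid origin latitude).
#'
#' @param ud A `tm_ud` object.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ud_ascii <- function(ud, path) {
  m_per_deg <- pi / 180 * 6371008.8
  cs <- (ud$x[2] - ud$x[1]) / (m_per_deg * cos(ud$origin[["lat"]] * pi / 180))
  xll <- ud$origin[["lon"]] + (ud$x[1] - (ud$x[2] - ud$x[1]) / 2) /
    (m_per_deg * cos(ud$origin[["lat"]] * pi / 180))
  yll <- ud$origin[["lat"]] + (ud$y[1] - (ud$y[2] - ud$y[1]) / 2) / m_per_deg
  # rows north to south; z is x-major so transpose
  zz <- t(ud$z)[rev(seq_along(ud$y)), , drop = FALSE]
  hdr <- c(paste("ncols", length(ud$x)), paste("nrows", length(ud$y)),
           paste("xllcorner", format(xll, digits = 12)),
           paste("yllcorner", format(yll, digits = 12)),
           paste("cellsize", format(cs, digits = 12)),
           "NODATA_value -9999")
  body <- apply(zz, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
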