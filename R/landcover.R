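#' Construct a categorical land-cover grid
#'
#' A regular grid of integer class codes in geographic coordinates, with a
#' code-to-name legend. Row 1 of `codes` is the northernmost row (standard
#' raster orientation).
#'
#' @param codes Integer matrix (`nrows` x `ncols`), row 1 = north.
#' @param xll,yll Longitude/latitude of the lower-left corner of the grid.
#' @param cellsize Cell size in decimal degrees.
#' @param legend Named character vector mapping code (as character) to class
#'   name, e.g. `c("1" = "forest", "2" = "wetland")`. Codes without a legend
#'   entry resolve to `"unknown"`.
#' @param nodata Code treated as missing (default -9999).
#' @return An object of class `tm_landcover`.
#' @export
land_cover_grid <- function(codes, xll, yll, cellsize, legend = NULL,
                            nodata = -9999) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  present <- setdiff(unique(as.vector(codes)), nodata)
  if (!is.null(legend)) {
    missing <- setdiff(as.character(present), names(legend))
    if (length(missing)) {
      warning("no legend entry for code(s) ", paste(missing, collapse = ", "),
              '; resolved as "unknown"')
    }
  }
  structure(list(codes = codes, xll = xll, yll = yll, cellsize = cellsize,
                 nrows = nrow(codes), ncols = ncol(codes),
                 legend = legend, nodata = nodata),
            class = "tm_landcover")
}

#' @export
print.tm_landcover <- function(x, ...) {
  cat("<land-cover grid: ", x$nrows, "x", x$ncols, " cells of ", x$cellsize,
      " deg, ", length(setdiff(unique(as.vector(x$codes)), x$nodata)),
      " classes>\n", sep = "")
  invisible(x)
}

#' @export
tidy.tm_landcover <- function(x, ...) {
  counts <- table(as.vector(x$codes))
  counts <- counts[names(counts) != as.character(x$nodata)]
  tibble::tibble(
    code = as.integer(names(counts)),
    class = code_to_name(as.integer(names(counts)), x),
    n_cells = as.integer(counts),
    fraction = as.integer(counts) / sum(counts))
}

code_to_name <- function(code, grid) {
  if (is.null(grid$legend)) return(as.character(code))
  out <- unname(grid$legend[as.character(code)])
  out[is.na(out)] <- "unknown"
  out
}

#' Read an ESRI ASCII raster as a land-cover grid
#'
#' Plain-text rasters in geographic (lat/lon) coordinates: the standard
#' six-line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) followed by rows north to south.
#'
#' @param path Path to the `.asc` file.
#' @param legend Optional code-to-name legend (see [land_cover_grid()]).
#' @return A `tm_landcover` object.
#' @export
read_ascii_grid <- function(path, legend = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  repeat {
    i <- i + 1L
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      i <- i - 1L
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII raster (header incomplete): ", path)
  }
  cs <- hdr$cellsize
  xll <- hdr$xllcorner %||% (hdr$xllcenter - cs / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - cs / 2)
  if (is.null(xll) || is.null(yll)) stop("raster origin missing in ", path)
  vals <- scan(text = lines[-seq_len(i)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("raster body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  }
  codes <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  land_cover_grid(codes, xll = xll, yll = yll, cellsize = cs,
                  legend = legend,
                  nodata = hdr$nodata_value %||% -9999)
}

#' Write a land-cover grid as an ESRI ASCII raster
#'
#' @param grid A `tm_landcover` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  hdr <- c(paste("ncols", grid$ncols), paste("nrows", grid$nrows),
           paste("xllcorner", format(grid$xll, digits = 12)),
           paste("yllcorner", format(grid$yll, digits = 12)),
           paste("cellsize", format(grid$cellsize, digits = 12)),
           paste("NODATA_value", grid$nodata))
  body <- apply(grid$codes, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Land-cover class under a point
#'
#' Point-in-cell lookup with half-open cell ownership: each cell owns its
#' west and north edges, so a point on a shared edge belongs to exactly one
#' cell and the lookup is total and deterministic over the extent. Points
#' outside the extent (and nodata cells) return `NA`.
#'
#' @param grid A `tm_landcover` object.
#' @param lat,lon Coordinate vectors in decimal degrees.
#' @return Character vector of class names (`NA` off-grid).
#' @export
class_at <- function(grid, lat, lon) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1L
  yul <- grid$yll + grid$nrows * grid$cellsize
  row <- floor((yul - lat) / grid$cellsize) + 1L
  row[lat == yul] <- 1L  # north outer edge is inside
  ok <- col >= 1L & col <= grid$ncols & row >= 1L & row <= grid$nrows
  code <- rep(NA_integer_, length(lat))
  code[ok] <- grid$codes[cbind(row[ok], col[ok])]
  code[!is.na(code) & code == grid$nodata] <- NA_integer_
  out <- rep(NA_character_, length(lat))
  out[!is.na(code)] <- code_to_name(code[!is.na(code)], grid)
  out
}
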