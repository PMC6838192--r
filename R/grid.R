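#' Single-band raster grid
#'
#' Lightweight container for a square-celled, projected (planar, meters)
#' raster: a numeric matrix whose first row is the northernmost row, plus
#' cell size, lower-left corner origin and a nodata sentinel. All landscape
#' layers, resistance surfaces and current maps in the package are
#' `land_grid` objects.
#'
#' @param values numeric matrix; row 1 = north. `NA` entries are treated as
#'   nodata.
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, (x, y) of the lower-left corner of the
#'   lower-left cell.
#' @param nodata sentinel written to file for `NA` cells.
#' @return object of class `land_grid`.
#' @export
land_grid <- function(values, cell_size, origin = c(0, 0), nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L, is.finite(origin))
  if (any(is.infinite(values), na.rm = TRUE))
    stop("grid values must be finite or NA")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "land_grid")
}

#' @export
print.land_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<land_grid> %d x %d cells, cell size %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

#' Do two grids share shape, cell size and origin?
#' @param a,b `land_grid` objects.
#' @return logical scalar.
#' @export
same_georef <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

.check_georef <- function(grids) {
  for (g in grids[-1])
    if (!same_georef(grids[[1]], g))
      stop("grids do not share a common georeference (shape/cell size/origin)")
  invisible(TRUE)
}

#' Coordinates of every cell center
#'
#' @param grid a `land_grid`.
#' @return list with matrices `x` and `y` of the same shape as the grid.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  x <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  y <- grid$origin[2] + (nr - seq_len(nr) + 0.5) * cs   # row 1 = north
  list(x = matrix(x, nr, nc, byrow = TRUE), y = matrix(y, nr, nc))
}

#' Map planar coordinates to (row, col) cell indices
#'
#' Points outside the grid extent are an error; points on an internal cell
#' boundary belong to the higher-index cell, points on the outer edge are
#' clamped inward.
#'
#' @param grid a `land_grid`.
#' @param x,y coordinate vectors (meters).
#' @return integer matrix with columns `row`, `col`.
#' @export
locate_cells <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs) + 1L
  row <- nr - floor((y - grid$origin[2]) / cs)
  col <- pmin.int(pmax.int(col, 1L), nc)
  row <- pmin.int(pmax.int(row, 1L), nr)
  inside <- x >= grid$origin[1] & x <= grid$origin[1] + nc * cs &
            y >= grid$origin[2] & y <= grid$origin[2] + nr * cs
  if (!all(inside))
    stop("coordinates fall outside the grid extent: points ",
         paste(which(!inside), collapse = ", "))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @return a `land_grid`; nodata cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- sum(c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                 "nodata_value") %in% names(hdr))
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("value count does not match header dimensions in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  land_grid(m, cell_size = hdr$cellsize, origin = c(xll, yll), nodata = nodata)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' @param grid a `land_grid`.
#' @param path output path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, digits = 10) {
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(m, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a grid onto another georeference
#'
#' Nearest-neighbor for categorical layers, bilinear for continuous ones.
#' Cells of the target whose center falls outside the source extent become
#' nodata.
#'
#' @param grid source `land_grid`.
#' @param target `land_grid` (or list with `values`, `cell_size`, `origin`)
#'   supplying the output georeference.
#' @param method `"nearest"` or `"bilinear"`.
#' @return a `land_grid` on the target georeference.
#' @export
resample_grid <- function(grid, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  cc <- cell_centers(target)
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  # fractional (row, col) position of each target center in source cell units
  fc <- (cc$x - grid$origin[1]) / cs + 0.5
  fr <- nr - (cc$y - grid$origin[2]) / cs + 0.5
  out <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  inside <- fr >= 0.5 & fr <= nr + 0.5 & fc >= 0.5 & fc <= nc + 0.5
  if (method == "nearest") {
    r <- pmin.int(pmax.int(round(fr), 1L), nr)
    c <- pmin.int(pmax.int(round(fc), 1L), nc)
    out[inside] <- grid$values[cbind(r[inside], c[inside])]
  } else {
    r0 <- pmin.int(pmax.int(floor(fr), 1L), nr - 1L)
    c0 <- pmin.int(pmax.int(floor(fc), 1L), nc - 1L)
    wr <- pmin(pmax(fr - r0, 0), 1); wc <- pmin(pmax(fc - c0, 0), 1)
    v00 <- grid$values[cbind(r0, c0)];     v01 <- grid$values[cbind(r0, c0 + 1L)]
    v10 <- grid$values[cbind(r0 + 1L, c0)]; v11 <- grid$values[cbind(r0 + 1L, c0 + 1L)]
    v <- (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
    out[inside] <- v[inside]
  }
  land_grid(out, cell_size = target$cell_size, origin = target$origin,
            nodata = grid$nodata)
}
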