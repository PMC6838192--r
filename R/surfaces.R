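#' Reclassify a categorical grid
#'
#' Pure per-cell relabeling of class codes; nodata is preserved. Every class
#' present in the grid must appear in the mapping.
#'
#' @param grid a `land_grid` holding integer class codes.
#' @param mapping named numeric vector, `names` = old classes, values = new
#'   classes (e.g. `c("1" = 0, "2" = 0, "3" = 1, "4" = 2)`).
#' @return reclassified `land_grid`.
#' @export
reclassify <- function(grid, mapping) {
  v <- grid$values
  present <- unique(v[!is.na(v)])
  unmapped <- setdiff(as.character(present), names(mapping))
  if (length(unmapped))
    stop("classes present in grid but not in mapping: ",
         paste(unmapped, collapse = ", "))
  out <- v
  ok <- !is.na(v)
  out[ok] <- unname(mapping[as.character(v[ok])])
  land_grid(out, grid$cell_size, grid$origin, grid$nodata)
}

#' Distance of every cell to the nearest feature point
#'
#' Planar distance (meters) from each cell center to the nearest of a set of
#' point features (e.g. village centers).
#'
#' @param template `land_grid` supplying shape and georeference (values
#'   ignored except nodata pattern, which is preserved).
#' @param points data.frame with columns `x`, `y` (meters).
#' @return `land_grid` of distances; 0 at cells containing a feature center.
#' @export
distance_to_features <- function(template, points) {
  if (is.null(points) || nrow(points) < 1L)
    stop("need >= 1 feature point")
  cc <- cell_centers(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  ext_x <- template$origin[1] + c(0, nc * template$cell_size)
  ext_y <- template$origin[2] + c(0, nr * template$cell_size)
  if (!any(points$x >= ext_x[1] & points$x <= ext_x[2] &
           points$y >= ext_y[1] & points$y <= ext_y[2]))
    stop("no feature point inside the grid extent")
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(points)))
    d2 <- pmin(d2, (cc$x - points$x[k])^2 + (cc$y - points$y[k])^2)
  out <- sqrt(d2)
  out[is.na(template$values)] <- NA_real_
  land_grid(out, template$cell_size, template$origin, template$nodata)
}

#' Topographic position index (TPI)
#'
#' TPI of a cell is its elevation minus the mean elevation of its 3x3
#' neighborhood with the center excluded. Positive values are ridges,
#' negative values valleys. Edge cells use only their available neighbors;
#' nodata neighbors are excluded from the mean; a cell with no valid
#' neighbor becomes nodata.
#'
#' @param dem `land_grid` of elevations.
#' @return `land_grid` of TPI values.
#' @export
topographic_position_index <- function(dem) {
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3x3")
  z <- v; z[is.na(v)] <- 0
  w <- matrix(as.numeric(!is.na(v)), nr, nc)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    rs <- max(1, 1 + dr):min(nr, nr + dr)   # destination rows
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    s[rs, cs] <- s[rs, cs] + z[rs - dr, cs - dc]
    n[rs, cs] <- n[rs, cs] + w[rs - dr, cs - dc]
  }
  out <- v - s / n                # NaN where n == 0
  out[n == 0] <- NA_real_
  out[is.na(v)] <- NA_real_
  land_grid(out, dem$cell_size, dem$origin, dem$nodata)
}

# cells crossed by one segment, by Amanatides-Woo grid traversal on cell
# boundaries; returns integer matrix (row, col)
.traverse_segment <- function(grid, x0, y0, x1, y1) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  # work in cell units with origin at lower-left of the grid
  ax <- (x0 - grid$origin[1]) / cs; ay <- (y0 - grid$origin[2]) / cs
  bx <- (x1 - grid$origin[1]) / cs; by <- (y1 - grid$origin[2]) / cs
  # clip to grid extent [0, nc] x [0, nr] (Liang-Barsky)
  dx <- bx - ax; dy <- by - ay
  t0 <- 0; t1 <- 1
  for (p in list(c(-dx, ax - 0), c(dx, nc - ax), c(-dy, ay - 0), c(dy, nr - ay))) {
    if (p[1] == 0) { if (p[2] < 0) return(NULL) }
    else {
      t <- p[2] / p[1]
      if (p[1] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
    }
  }
  if (t0 > t1) return(NULL)
  ax2 <- ax + t0 * dx; ay2 <- ay + t0 * dy
  bx2 <- ax + t1 * dx; by2 <- ay + t1 * dy
  eps <- 1e-12
  cx <- floor(min(max(ax2, 0), nc - eps)); cy <- floor(min(max(ay2, 0), nr - eps))
  ex <- floor(min(max(bx2, 0), nc - eps)); ey <- floor(min(max(by2, 0), nr - eps))
  sx <- sign(dx); sy <- sign(dy)
  # parametrize along the clipped segment in t' in [0,1]
  lenx <- bx2 - ax2; leny <- by2 - ay2
  tdx <- if (lenx != 0) abs(1 / lenx) else Inf
  tdy <- if (leny != 0) abs(1 / leny) else Inf
  tmx <- if (lenx != 0) ((cx + (lenx > 0)) - ax2) / lenx else Inf
  tmy <- if (leny != 0) ((cy + (leny > 0)) - ay2) / leny else Inf
  cells <- matrix(0L, 0L, 2L)
  repeat {
    cells <- rbind(cells, c(cy, cx))
    if ((cx == ex && cy == ey) || nrow(cells) > nr * nc) break
    if (tmx < tmy) { cx <- cx + sx; tmx <- tmx + tdx }
    else if (tmy < tmx) { cy <- cy + sy; tmy <- tmy + tdy }
    else { cx <- cx + sx; cy <- cy + sy; tmx <- tmx + tdx; tmy <- tmy + tdy }
    if (cx < 0 || cx >= nc || cy < 0 || cy >= nr) break
  }
  # convert lower-left cell units (cy counted from south) to matrix indices
  cbind(row = nr - cells[, 1], col = cells[, 2] + 1L)
}

#' Rasterize polylines to a binary grid
#'
#' A cell is 1 if any polyline segment intersects it, else 0 (used for river
#' and road layers).
#'
#' @param template `land_grid` supplying shape and georeference.
#' @param polylines data.frame with columns `line`, `x`, `y`: consecutive
#'   vertices sharing a `line` id form segments.
#' @return binary `land_grid`.
#' @export
rasterize_lines <- function(template, polylines) {
  out <- matrix(0, nrow(template$values), ncol(template$values))
  if (is.null(polylines) || nrow(polylines) == 0L) {
    warning("empty polyline set; returning all-zero grid")
  } else {
    for (id in unique(polylines$line)) {
      v <- polylines[polylines$line == id, , drop = FALSE]
      if (nrow(v) < 2L) next
      for (s in seq_len(nrow(v) - 1L)) {
        cells <- .traverse_segment(template, v$x[s], v$y[s], v$x[s + 1L], v$y[s + 1L])
        if (!is.null(cells) && nrow(cells)) out[cells] <- 1
      }
    }
  }
  out[is.na(template$values)] <- NA_real_
  land_grid(out, template$cell_size, template$origin, template$nodata)
}
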