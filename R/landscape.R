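#' Landscape masks
#'
#' A landscape mask represents habitable space as a boolean raster: habitable
#' cells are `TRUE` (black pixels in a 1-bit image), uninhabitable cells
#' (oceans, barriers) are `FALSE`. Positions are continuous Cartesian
#' kilometres with the origin at the lower-left corner of the raster; raster
#' row 1 is the top of the map, so a position `(x, y)` falls in row
#' `floor((height_km - y) / cell_size) + 1` and column
#' `floor(x / cell_size) + 1`.
#'
#' @param raster a logical or 0/1 numeric matrix (`TRUE`/1 = habitable), or a
#'   path to a 1-bit PNG (black = habitable, white = uninhabitable) or to a
#'   CSV of 0/1 values.
#' @param cell_size km per raster cell.
#' @param overlays named list of dispersal-corridor overlays, each a list
#'   with elements `grid` (boolean matrix of the same shape) and `sigma`
#'   (`c(sigma_x, sigma_y)` in km used while travelling on the corridor).
#' @return Object of class `landscape_mask`.
#' @export
load_mask <- function(raster, cell_size, overlays = list()) {
  stopifnot(cell_size > 0)
  if (is.character(raster)) {
    if (grepl("\\.png$", raster, ignore.case = TRUE)) {
      img <- png::readPNG(raster)
      if (length(dim(img)) == 3) img <- img[, , 1]
      vals <- unique(round(as.vector(img), 6))
      if (!all(vals %in% c(0, 1)))
        stop("raster is not binary; threshold it explicitly upstream")
      grid <- img < 0.5  # black = habitable
    } else {
      grid <- as.matrix(utils::read.csv(raster, header = FALSE)) > 0.5
    }
  } else {
    if (!all(unique(as.vector(raster)) %in% c(0, 1, TRUE, FALSE)))
      stop("raster is not binary; threshold it explicitly upstream")
    grid <- matrix(as.logical(raster), nrow(raster), ncol(raster))
  }
  dimnames(grid) <- NULL
  if (!any(grid)) stop("raster has no habitable cells")
  for (ov in overlays) {
    stopifnot(identical(dim(ov$grid), dim(grid)), length(ov$sigma) == 2)
  }
  structure(list(grid = grid, cell_size = cell_size,
                 width_km = ncol(grid) * cell_size,
                 height_km = nrow(grid) * cell_size,
                 overlays = overlays, geo = NULL),
            class = "landscape_mask")
}

#' @export
print.landscape_mask <- function(x, ...) {
  cat(sprintf(
    "landscape_mask: %d x %d cells (%g km/cell), %.0f x %.0f km, %.1f%% habitable, %d overlay(s)\n",
    nrow(x$grid), ncol(x$grid), x$cell_size, x$width_km, x$height_km,
    100 * mean(x$grid), length(x$overlays)))
  invisible(x)
}

# Row/column indices of positions (vectorised); positions on the top/right
# edge are clamped into the last cell.
cell_index <- function(mask, x, y) {
  col <- pmin(pmax(floor(x / mask$cell_size) + 1, 1), ncol(mask$grid))
  row <- pmin(pmax(floor((mask$height_km - y) / mask$cell_size) + 1, 1),
              nrow(mask$grid))
  cbind(row, col)
}

#' Habitability of continuous positions
#'
#' @param mask a `landscape_mask`.
#' @param x,y position coordinates in km (vectorised).
#' @return Logical vector; `FALSE` for positions outside the bounding box or
#'   on uninhabitable cells.
#' @export
is_habitable <- function(mask, x, y) {
  inside <- x >= 0 & x <= mask$width_km & y >= 0 & y <= mask$height_km
  ok <- rep(FALSE, length(x))
  if (any(inside)) {
    idx <- cell_index(mask, x[inside], y[inside])
    ok[inside] <- mask$grid[idx]
  }
  ok
}

# Name of the overlay covering (x, y), or NA. When several overlap, the one
# with the larger sigma_x wins (the faster route dominates).
overlay_at <- function(mask, x, y) {
  hit <- NA_character_
  best <- -Inf
  for (nm in names(mask$overlays)) {
    ov <- mask$overlays[[nm]]
    if (ov$grid[cell_index(mask, x, y)] && ov$sigma[1] > best) {
      hit <- nm
      best <- ov$sigma[1]
    }
  }
  hit
}

#' Step-size standard deviations at a position
#'
#' Returns the overlay's `(sigma_x, sigma_y)` when the position lies on a
#' dispersal-corridor overlay (the overlay with the larger sigma wins when
#' corridors overlap), otherwise the base step size.
#'
#' @param x,y a single position (km).
#' @param mask a `landscape_mask`.
#' @param base base `c(sigma_x, sigma_y)` (km).
#' @return Numeric `c(sigma_x, sigma_y)`.
#' @export
step_sigma <- function(x, y, mask, base) {
  stopifnot(length(x) == 1, length(y) == 1, length(base) == 2)
  nm <- overlay_at(mask, x, y)
  if (is.na(nm)) base else mask$overlays[[nm]]$sigma
}

#' Sample yearly movement displacements
#'
#' Each position receives independent `Normal(0, sigma_x)` and
#' `Normal(0, sigma_y)` displacements; proposals landing outside the
#' habitable area are rejected and redrawn until a legitimate position is
#' found (up to `max_attempts`, after which the old position is kept). An
#' individual on a dispersal corridor first decides, with equal probability,
#' whether to continue along the corridor (corridor step size, new position
#' constrained to the corridor) or to leave it (base step size, new position
#' constrained off the corridor).
#'
#' @param x,y current positions (km), vectorised.
#' @param sigma base `c(sigma_x, sigma_y)` (km).
#' @param mask a `landscape_mask`.
#' @param max_attempts rejection cap per individual.
#' @return data.frame with columns `x`, `y`.
#' @export
sample_move <- function(x, y, sigma, mask, max_attempts = 1000) {
  stopifnot(length(sigma) == 2, all(sigma >= 0), length(x) == length(y))
  n <- length(x)
  if (all(sigma == 0) && length(mask$overlays) == 0)
    return(data.frame(x = x, y = y))
  newx <- x
  newy <- y
  has_ov <- length(mask$overlays) > 0
  for (i in seq_len(n)) {
    ov <- if (has_ov) overlay_at(mask, x[i], y[i]) else NA_character_
    if (!is.na(ov)) {
      stay <- stats::runif(1) < 0.5
      sg <- if (stay) mask$overlays[[ov]]$sigma else sigma
      ogrid <- mask$overlays[[ov]]$grid
      accept <- function(px, py) {
        if (!is_habitable(mask, px, py)) return(FALSE)
        on_ov <- ogrid[cell_index(mask, px, py)]
        if (stay) on_ov else !on_ov
      }
    } else {
      sg <- sigma
      accept <- function(px, py) is_habitable(mask, px, py)
    }
    if (all(sg == 0)) next
    for (a in seq_len(max_attempts)) {
      px <- x[i] + stats::rnorm(1, 0, sg[1])
      py <- y[i] + stats::rnorm(1, 0, sg[2])
      if (accept(px, py)) {
        newx[i] <- px
        newy[i] <- py
        break
      }
    }
  }
  data.frame(x = newx, y = newy)
}

#' Affine map-to-geography calibration
#'
#' Attaches an affine mapping between map kilometres and longitude/latitude,
#' defined by two anchor points (map position and its geographic
#' coordinates). Longitude is linear in `x` and latitude linear in `y`; this
#' is a deliberate flat-map approximation used only to compare simulated
#' individuals with georeferenced samples.
#'
#' @param mask a `landscape_mask`.
#' @param xy1,xy2 anchor map positions `c(x, y)` in km.
#' @param lonlat1,lonlat2 their geographic coordinates `c(lon, lat)`.
#' @return The mask with geographic calibration attached.
#' @export
calibrate_geography <- function(mask, xy1, lonlat1, xy2, lonlat2) {
  stopifnot(xy1[1] != xy2[1], xy1[2] != xy2[2])
  mask$geo <- list(
    lon_a = (lonlat2[1] - lonlat1[1]) / (xy2[1] - xy1[1]),
    lon_b = lonlat1[1], x0 = xy1[1],
    lat_a = (lonlat2[2] - lonlat1[2]) / (xy2[2] - xy1[2]),
    lat_b = lonlat1[2], y0 = xy1[2])
  mask
}

#' @rdname calibrate_geography
#' @param x,y map positions (km).
#' @return `map_to_lonlat`: data.frame with `lon`, `lat`.
#' @export
map_to_lonlat <- function(mask, x, y) {
  g <- mask$geo
  if (is.null(g)) stop("mask has no geographic calibration; see calibrate_geography()")
  data.frame(lon = g$lon_b + g$lon_a * (x - g$x0),
             lat = g$lat_b + g$lat_a * (y - g$y0))
}

#' @rdname calibrate_geography
#' @param lon,lat geographic coordinates (degrees).
#' @return `lonlat_to_map`: data.frame with `x`, `y` (km).
#' @export
lonlat_to_map <- function(mask, lon, lat) {
  g <- mask$geo
  if (is.null(g)) stop("mask has no geographic calibration; see calibrate_geography()")
  data.frame(x = g$x0 + (lon - g$lon_b) / g$lon_a,
             y = g$y0 + (lat - g$lat_b) / g$lat_a)
}
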