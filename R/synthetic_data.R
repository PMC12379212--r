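#' Synthetic age-at-death distribution
#'
#' A stylised Neolithic-like age-at-death probability mass function used as a
#' documented stand-in osteological table: geometrically decaying
#' infant/juvenile mortality (ages 0-11) plus a truncated-normal adult
#' component. The default shape is chosen so the balancing fertility rate
#' (see [balancing_fertility()]) is close to 0.1 per mature individual per
#' year.
#'
#' @param juv_mass total probability mass on ages 0-11.
#' @param juv_decay geometric decay of the juvenile masses.
#' @param adult_mode,adult_sd mode and spread (years) of the adult
#'   age-at-death component.
#' @param a_max maximum age (years).
#' @return Numeric pmf over ages `0:a_max`.
#' @export
default_mortality_pmf <- function(juv_mass = 0.45, juv_decay = 0.6,
                                  adult_mode = 26, adult_sd = 12, a_max = 80) {
  stopifnot(juv_mass > 0, juv_mass < 1, a_max > 12)
  juv <- juv_decay^(0:11)
  juv <- juv / sum(juv) * juv_mass
  ad <- stats::dnorm(12:a_max, adult_mode, adult_sd)
  ad <- ad / sum(ad) * (1 - juv_mass)
  d <- c(juv, ad)
  d / sum(d)
}

#' Generate a synthetic mortality table
#'
#' Writes (optionally) and returns a [default_mortality_pmf()]-shaped
#' age-at-death table in the CSV layout read by [read_mortality_table()].
#'
#' @param path optional CSV output path.
#' @param ... passed to [default_mortality_pmf()].
#' @return A `mortality_curve` (invisibly the path if written).
#' @export
generate_mortality_table <- function(path = NULL, ...) {
  curve <- equilibrium_hazard(default_mortality_pmf(...), source = "synthetic")
  if (!is.null(path)) write_mortality_table(curve, path)
  curve
}

#' Specification for a synthetic ancestry sample table
#'
#' Describes how to generate a pseudo-qpAdm table of ancient individuals with
#' known truth: a true ancestry cline (either an analytic
#' intercept/slope/floor form or any function of distance), per-sample
#' Gaussian estimation noise with sample-specific standard errors, and
#' uniform sampling in space and time.
#'
#' @param truth either a list `list(intercept=, slope=)` (per-km slope;
#'   values clamped to \[0, 1\]) or a function `f(distance_km) -> ancestry`.
#' @param n_samples number of individuals.
#' @param se_range `c(lo, hi)` for per-sample standard errors.
#' @param date_range years BP, `c(lo, hi)`.
#' @param geo_box `c(lon_min, lon_max, lat_min, lat_max)` within which
#'   samples are placed uniformly.
#' @param origin `c(lon, lat)` of the farming origin used for distances.
#' @return Object of class `synthetic_cline_spec`.
#' @export
synthetic_cline_spec <- function(truth = list(intercept = 0.95, slope = -7.5e-5),
                                 n_samples = 600,
                                 se_range = c(0.01, 0.02),
                                 date_range = c(5000, 8500),
                                 geo_box = c(-5, 30, 36, 55),
                                 origin = farming_origin()) {
  stopifnot(n_samples >= 1, se_range[1] > 0, se_range[2] >= se_range[1])
  truth_fun <- if (is.function(truth)) truth else {
    stopifnot(is.numeric(truth$intercept), is.numeric(truth$slope))
    function(d) pmin(pmax(truth$intercept + truth$slope * d, 0), 1)
  }
  structure(list(truth = truth_fun, n_samples = n_samples,
                 se_range = se_range, date_range = date_range,
                 geo_box = geo_box, origin = origin),
            class = "synthetic_cline_spec")
}

#' Generate a synthetic ancestry sample table
#'
#' Emulates the statistical structure of a qpAdm-style ancestry table: point
#' estimate = true cline value at the sample's distance from the farming
#' origin plus `Normal(0, se)` noise with a sample-specific standard error.
#' Steppe proportions are drawn small and model p-values above the
#' plausibility threshold so the table passes the standard filters; the
#' unobservable truth is retained in `ef_true` (and the unclipped noisy value
#' in `ef_raw`) for testing.
#'
#' @param spec a [synthetic_cline_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `id, lat, lon, date_bp, ef, ef_se, whg,
#'   whg_se, steppe, steppe_se, p_value, distance_km, ef_true, ef_raw`.
#' @export
generate_ancestry_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_cline_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_samples
  lon <- stats::runif(n, spec$geo_box[1], spec$geo_box[2])
  lat <- stats::runif(n, spec$geo_box[3], spec$geo_box[4])
  d <- haversine_km(lon, lat, spec$origin[1], spec$origin[2])
  truth <- spec$truth(d)
  se <- stats::runif(n, spec$se_range[1], spec$se_range[2])
  raw <- truth + stats::rnorm(n, 0, se)
  ef <- pmin(pmax(raw, 0), 1)
  steppe <- stats::runif(n, 0, 0.045)
  data.frame(
    id = sprintf("SYN%04d", seq_len(n)),
    lat = lat, lon = lon,
    date_bp = stats::runif(n, spec$date_range[1], spec$date_range[2]),
    ef = ef, ef_se = se,
    whg = pmin(pmax(1 - ef - steppe, 0), 1), whg_se = se,
    steppe = steppe, steppe_se = se / 2,
    p_value = stats::runif(n, 0.01, 1),
    distance_km = d, ef_true = truth, ef_raw = raw)
}

#' Generate landscape fixtures
#'
#' Stylised habitability rasters for tests and scaled-down experiments:
#' * `square` - a fully habitable square plane (default 3700 x 3700 km);
#' * `strip`  - a narrow fully habitable corridor for fast front-speed runs;
#' * `toy_continent` - a synthetic continent-like blob with an impassable
#'   ridge (pierced by a gap) and two dispersal-corridor overlays
#'   (`mediterranean` along the southern coast, `danube_rhine` inland), a
#'   stylised stand-in for a real European coastline map.
#'
#' @param kind `"square"`, `"strip"` or `"toy_continent"`.
#' @param cell_size km per cell.
#' @param width_km,height_km extents (defaults depend on `kind`).
#' @return A `landscape_mask`.
#' @export
generate_landscape_fixtures <- function(kind = c("square", "strip", "toy_continent"),
                                        cell_size = 5,
                                        width_km = NULL, height_km = NULL) {
  kind <- match.arg(kind)
  if (kind == "square") {
    w <- if (is.null(width_km)) 3700 else width_km
    h <- if (is.null(height_km)) w else height_km
    grid <- matrix(TRUE, round(h / cell_size), round(w / cell_size))
    return(load_mask(grid, cell_size))
  }
  if (kind == "strip") {
    w <- if (is.null(width_km)) 1000 else width_km
    h <- if (is.null(height_km)) 50 else height_km
    grid <- matrix(TRUE, round(h / cell_size), round(w / cell_size))
    return(load_mask(grid, cell_size))
  }
  # toy continent: 1000 x 800 km ellipse-ish landmass
  w <- if (is.null(width_km)) 1000 else width_km
  h <- if (is.null(height_km)) 800 else height_km
  nc <- round(w / cell_size)
  nr <- round(h / cell_size)
  cx <- (col(matrix(0, nr, nc)) - 0.5) / nc  # 0..1 across
  cy <- (row(matrix(0, nr, nc)) - 0.5) / nr
  blob <- ((cx - 0.5) / 0.48)^2 + ((cy - 0.5) / 0.42)^2 <= 1
  # impassable ridge: vertical band at ~60% across, with a gap near the south
  ridge <- cx > 0.58 & cx < 0.62 & cy < 0.75
  grid <- blob & !ridge
  # southern coastal corridor: lowest habitable band of the blob
  med <- blob & cy > 0.82
  # inland corridor: diagonal band (a stylised river valley), crossing the gap
  dr <- blob & abs(cy - (0.85 - 0.55 * cx)) < 0.05
  overlays <- list(
    mediterranean = list(grid = med & grid, sigma = c(30, 30)),
    danube_rhine = list(grid = dr & grid, sigma = c(15, 15)))
  load_mask(grid, cell_size, overlays = overlays)
}

#' Connectivity of the habitable region
#'
#' Flood-fills from the first habitable cell (4-neighbour adjacency) and
#' reports whether every habitable cell is reachable.
#'
#' @param mask a `landscape_mask`.
#' @return `TRUE` if the habitable region is a single connected component.
#' @export
connected_habitable <- function(mask) {
  g <- mask$grid
  nr <- nrow(g)
  nc <- ncol(g)
  seen <- matrix(FALSE, nr, nc)
  start <- which(g, arr.ind = TRUE)[1, ]
  seen[start[1], start[2]] <- TRUE
  repeat {  # iterative 4-neighbour dilation restricted to habitable cells
    grown <- seen
    grown[-1, ] <- grown[-1, ] | seen[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | seen[-1, ]
    grown[, -1] <- grown[, -1] | seen[, -nc]
    grown[, -nc] <- grown[, -nc] | seen[, -1]
    grown <- grown & g
    if (identical(grown, seen)) break
    seen <- grown
  }
  sum(seen) == sum(g)
}
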