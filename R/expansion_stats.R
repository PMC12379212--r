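#' Extent of the farming expansion along the X axis
#'
#' Computes the farmer proportion within `n_bins` equal X bins and returns
#' the centre of the farthest bin of the contiguous block of bins with
#' proportion >= 0.5 starting at the origin. The contiguity rule makes the
#' extent robust to isolated converted hunter-gatherers far ahead of the
#' front; setting `contiguous = FALSE` instead returns the farthest bin
#' anywhere with proportion >= 0.5. Returns 0 when no bin qualifies.
#'
#' @param snapshot a `sim_state` or a snapshot data.frame with `x` and
#'   `culture` (`"farmer"` / `"hunter_gatherer"` or 1/0).
#' @param width_km landscape width (taken from the state's mask when
#'   omitted).
#' @param n_bins number of X bins (20 bins of 185 km on the 3700 km square).
#' @param contiguous apply the contiguity rule (default) or not.
#' @return Extent in km.
#' @export
front_extent <- function(snapshot, width_km = NULL, n_bins = 20,
                         contiguous = TRUE) {
  if (inherits(snapshot, "sim_state")) {
    x <- snapshot$x
    cult <- snapshot$culture
    if (is.null(width_km)) width_km <- snapshot$mask$width_km
  } else {
    stopifnot(!is.null(width_km))
    x <- snapshot$x
    cult <- if (is.numeric(snapshot$culture)) snapshot$culture
            else as.integer(snapshot$culture == "farmer")
  }
  if (!length(x)) stop("empty snapshot")
  if (contiguous)
    return(cpp_front_extent(x, as.integer(cult), width_km, as.integer(n_bins)))
  bw <- width_km / n_bins
  b <- pmin(pmax(floor(x / bw), 0), n_bins - 1) + 1
  tot <- tabulate(b, n_bins)
  farm <- tabulate(b[cult == 1], n_bins)
  ok <- tot > 0 & farm / pmax(tot, 1) >= 0.5
  if (!any(ok)) 0 else (max(which(ok)) - 0.5) * bw
}

#' Front speed from a yearly extent series
#'
#' Ordinary least-squares slope of front extent against year. The first
#' `burn_in` fraction of the series (transient establishment of the front)
#' and the post-saturation plateau (years after the extent first reaches its
#' final maximum) are excluded from the regression.
#'
#' @param extents numeric vector of yearly extents (km), or a data.frame
#'   with columns `year` and `extent`.
#' @param years years matching `extents` (default `seq_along`).
#' @param burn_in fraction of the usable series dropped at the start.
#' @return list with `speed` (km/yr), `n_used`, and the fitted `lm`.
#' @export
front_speed <- function(extents, years = NULL, burn_in = 0.1) {
  if (is.data.frame(extents)) {
    years <- extents$year
    extents <- extents$extent
  }
  if (is.null(years)) years <- seq_along(extents)
  if (length(extents) < 3) stop("need at least 3 time points")
  if (max(extents) == min(extents)) {
    warning("constant extent series; front speed is 0")
    return(list(speed = 0, n_used = length(extents), fit = NULL))
  }
  sat <- which(extents == max(extents))[1]
  keep <- seq_along(extents) <= sat
  keep[seq_len(floor(burn_in * sum(keep)))] <- FALSE
  if (sum(keep) < 3) keep <- seq_along(extents) <= sat
  fit <- stats::lm(extents[keep] ~ years[keep])
  list(speed = unname(stats::coef(fit)[2]), n_used = sum(keep), fit = fit)
}

#' Cultural effect of learning on the front speed
#'
#' The percentage of the front speed attributable to cultural transmission,
#' relative to a purely demic run:
#' `(front_speed - demic_speed) / front_speed * 100`.
#'
#' @param front_speed front speed of the run with cultural transmission
#'   (km/yr, > 0).
#' @param demic_speed front speed of the matched demic run (km/yr).
#' @return Cultural effect in percent.
#' @export
cultural_effect <- function(front_speed, demic_speed) {
  if (!is.numeric(front_speed) || front_speed <= 0)
    stop("`front_speed` must be positive")
  (front_speed - demic_speed) / front_speed * 100
}

#' Binned ancestry cline
#'
#' Mean individual EF ancestry by distance. Two binning schemes mirror the
#' two landscape types: `"square"` bins all individuals into `n_bins` equal
#' X bins (farming progresses along the X axis); `"radial"` subsamples
#' `sample_n` individuals and bins them by Euclidean distance from `origin`
#' into bins of `bin_width` km.
#'
#' @param snapshot a `sim_state` or snapshot data.frame with `x`, `y`,
#'   `ancestry`.
#' @param scheme `"square"` or `"radial"`.
#' @param origin map position `c(x, y)` of the farming origin (radial
#'   scheme).
#' @param n_bins number of bins (20 for square, 100 for radial by default).
#' @param bin_width radial bin width in km (default 52.4).
#' @param sample_n radial subsample size (default 10000).
#' @param width_km landscape width for the square scheme.
#' @return Object of class `cline_profile`: data.frame with `bin_center`,
#'   `mean_ancestry` (NA for empty bins) and `n`.
#' @export
ancestry_cline <- function(snapshot, scheme = c("square", "radial"),
                           origin = c(0, 0), n_bins = NULL, bin_width = 52.4,
                           sample_n = 10000, width_km = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(snapshot, "sim_state")) {
    if (is.null(width_km)) width_km <- snapshot$mask$width_km
    snapshot <- as_snapshot(snapshot)
  }
  stopifnot(all(c("x", "ancestry") %in% names(snapshot)))
  if (scheme == "square") {
    if (is.null(n_bins)) n_bins <- 20
    stopifnot(!is.null(width_km))
    bw <- width_km / n_bins
    b <- pmin(pmax(floor(snapshot$x / bw), 0), n_bins - 1) + 1
    centers <- (seq_len(n_bins) - 0.5) * bw
  } else {
    if (is.null(n_bins)) n_bins <- 100
    if (nrow(snapshot) > sample_n)
      snapshot <- snapshot[sample.int(nrow(snapshot), sample_n), ]
    d <- sqrt((snapshot$x - origin[1])^2 + (snapshot$y - origin[2])^2)
    b <- pmin(floor(d / bin_width), n_bins - 1) + 1
    centers <- (seq_len(n_bins) - 0.5) * bin_width
  }
  n <- tabulate(b, n_bins)
  s <- vapply(seq_len(n_bins), function(k) sum(snapshot$ancestry[b == k]), 1)
  prof <- data.frame(bin_center = centers,
                     mean_ancestry = ifelse(n > 0, s / pmax(n, 1), NA_real_),
                     n = n)
  class(prof) <- c("cline_profile", "data.frame")
  attr(prof, "scheme") <- scheme
  prof
}

#' Interpolate an expected ancestry from a cline profile
#'
#' Linear interpolation between adjacent non-missing bin centres; distances
#' outside the profile's support return the nearest bin's value (flagged via
#' the `"extrapolated"` attribute).
#'
#' @param profile a `cline_profile`.
#' @param distance distances in km (vectorised).
#' @return Expected ancestry values with attribute `extrapolated`.
#' @export
interpolate_cline <- function(profile, distance) {
  ok <- !is.na(profile$mean_ancestry)
  if (!any(ok)) stop("cline profile has no non-missing bins")
  xs <- profile$bin_center[ok]
  ys <- profile$mean_ancestry[ok]
  if (length(xs) == 1) {
    out <- rep(ys, length(distance))
    attr(out, "extrapolated") <- rep(TRUE, length(distance))
    return(out)
  }
  out <- stats::approx(xs, ys, xout = distance, rule = 2)$y
  attr(out, "extrapolated") <- distance < min(xs) | distance > max(xs)
  out
}

#' Population-weighted mean ancestry of a snapshot
#'
#' @param snapshot a `sim_state` or snapshot data.frame with `ancestry`.
#' @return Mean individual EF ancestry in \[0, 1\].
#' @export
mean_ancestry <- function(snapshot) {
  if (inherits(snapshot, "sim_state"))
    return(mean(genome_ancestry(snapshot$genome)))
  mean(snapshot$ancestry)
}
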