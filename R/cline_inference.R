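#' Default farming origin
#'
#' Geographic location of the assumed origin of the farming expansion, just
#' east of Ankara, Turkey. Configurable in all functions that take an
#' `origin`.
#'
#' @return `c(lon, lat)` in degrees.
#' @export
farming_origin <- function() c(lon = 33.0, lat = 39.9)

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised).
#' @return Distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

required_sample_cols <- c("id", "lat", "lon", "date_bp", "ef", "ef_se",
                          "whg", "steppe", "p_value")

#' Read an ancestry sample table
#'
#' Reads a CSV of per-individual ancestry estimates (one row per ancient
#' individual: qpAdm-style point estimates, standard errors and model
#' p-value). Alternative column headers can be supplied through `mapping`
#' (`list(ours = "theirs")`).
#'
#' @param path CSV path.
#' @param mapping optional named list mapping package column names to the
#'   file's column names.
#' @return data.frame with at least the standard columns.
#' @export
read_ancestry_table <- function(path, mapping = NULL) {
  tab <- utils::read.csv(path)
  for (nm in names(mapping)) {
    if (!mapping[[nm]] %in% names(tab))
      stop("mapped column not found in file: ", mapping[[nm]])
    names(tab)[names(tab) == mapping[[nm]]] <- nm
  }
  miss <- setdiff(required_sample_cols, names(tab))
  if (length(miss))
    stop("ancestry table is missing required columns: ",
         paste(miss, collapse = ", "))
  tab
}

#' Filter an ancestry sample table
#'
#' Applies the standard retention filters for the Neolithic ancestry
#' analysis: sample age within `date_range` years BP, model p-value >=
#' `p_min`, all ancestry weights within \[0, 1\], EF standard error below
#' `se_max`, and Steppe ancestry below `steppe_max`.
#'
#' @param table a sample table (see [read_ancestry_table()]).
#' @param date_range years BP, inclusive.
#' @param p_min minimum model p-value.
#' @param se_max maximum EF standard error (exclusive).
#' @param steppe_max maximum Steppe proportion (exclusive).
#' @return The retained rows, with an `"exclusions"` attribute counting the
#'   rows removed by each filter (applied sequentially).
#' @export
filter_samples <- function(table, date_range = c(5000, 8500), p_min = 0.01,
                           se_max = 0.022, steppe_max = 0.05) {
  miss <- setdiff(required_sample_cols, names(table))
  if (length(miss))
    stop("sample table is missing required columns: ",
         paste(miss, collapse = ", "))
  excl <- c(date = 0, p_value = 0, weights = 0, se = 0, steppe = 0)
  keep <- table$date_bp >= date_range[1] & table$date_bp <= date_range[2]
  excl["date"] <- sum(!keep)
  tab <- table[keep, ]
  keep <- tab$p_value >= p_min
  excl["p_value"] <- sum(!keep)
  tab <- tab[keep, ]
  keep <- tab$ef >= 0 & tab$ef <= 1 & tab$whg >= 0 & tab$whg <= 1 &
    tab$steppe >= 0 & tab$steppe <= 1
  excl["weights"] <- sum(!keep)
  tab <- tab[keep, ]
  keep <- tab$ef_se < se_max & tab$ef_se > 0
  excl["se"] <- sum(!keep)
  tab <- tab[keep, ]
  keep <- tab$steppe < steppe_max
  excl["steppe"] <- sum(!keep)
  tab <- tab[keep, ]
  attr(tab, "exclusions") <- excl
  tab
}

#' Subset samples by Neolithic period
#'
#' Early: older than 6500 ybp; Middle: 5500-6500 ybp inclusive on both ends;
#' Late: younger than 5500 ybp.
#'
#' @param samples a filtered sample table.
#' @param period `"early"`, `"middle"` or `"late"`.
#' @return The subset of rows.
#' @export
period_subset <- function(samples, period = c("early", "middle", "late")) {
  period <- match.arg(period)
  keep <- switch(period,
                 early = samples$date_bp > 6500,
                 middle = samples$date_bp >= 5500 & samples$date_bp <= 6500,
                 late = samples$date_bp < 5500)
  samples[keep, ]
}

#' Split samples into continental and Mediterranean routes
#'
#' @param samples a sample table.
#' @param cutoff latitude cutoff in degrees (default 45: the continental
#'   route is north of it).
#' @return list with `north` (lat > cutoff) and `south` (lat <= cutoff).
#' @export
split_by_latitude <- function(samples, cutoff = 45) {
  list(north = samples[samples$lat > cutoff, ],
       south = samples[samples$lat <= cutoff, ])
}

#' Straight-line distance of samples from the farming origin
#'
#' Adds/overwrites `distance_km`, the great-circle distance from `origin`.
#'
#' @param samples a sample table with `lon` and `lat`.
#' @param origin `c(lon, lat)` (default [farming_origin()]).
#' @return The table with a `distance_km` column.
#' @export
distance_from_origin <- function(samples, origin = farming_origin()) {
  if (any(abs(samples$lat) > 90) || any(abs(samples$lon) > 180))
    stop("latitude/longitude out of range")
  samples$distance_km <- haversine_km(samples$lon, samples$lat,
                                      origin[1], origin[2])
  samples
}

#' Gaussian measurement-error log-likelihood of one sample
#'
#' Log density of the observed ancestry estimate under
#' `Normal(expected, se)`, the measurement-error model with the
#' sample-specific qpAdm standard error.
#'
#' @param observed observed EF ancestry point estimate(s).
#' @param se sample-specific standard error(s), > 0.
#' @param expected expected ancestry (interpolated from a simulated cline).
#' @return Log-likelihood value(s).
#' @export
sample_loglik <- function(observed, se, expected) {
  if (any(se <= 0)) stop("standard errors must be positive")
  stats::dnorm(observed, mean = expected, sd = se, log = TRUE)
}

#' Profile log-likelihood over a grid of transmission parameter values
#'
#' For each parameter value, interpolates the matching simulated cline at
#' every sample's distance from the farming origin and sums the Gaussian
#' measurement-error log-likelihoods across samples (estimation errors
#' assumed independent across sites).
#'
#' @param samples a filtered sample table with `distance_km`, `ef`, `ef_se`.
#' @param clines named list mapping parameter value (names coercible to
#'   numeric) to `cline_profile` objects.
#' @return Object of class `likelihood_profile`: data.frame with `param` and
#'   `loglik`.
#' @export
profile_likelihood <- function(samples, clines) {
  stopifnot(nrow(samples) >= 1, length(clines) >= 1)
  if (!"distance_km" %in% names(samples))
    stop("samples need a `distance_km` column; see distance_from_origin()")
  vals <- as.numeric(names(clines))
  if (anyNA(vals)) stop("cline list names must be the parameter values")
  ll <- vapply(clines, function(pr) {
    expected <- interpolate_cline(pr, samples$distance_km)
    sum(sample_loglik(samples$ef, samples$ef_se, expected))
  }, 1)
  out <- data.frame(param = vals, loglik = unname(ll))
  out <- out[order(out$param), ]
  rownames(out) <- NULL
  class(out) <- c("likelihood_profile", "data.frame")
  out
}

#' Quadratic maximum-likelihood estimate from a likelihood profile
#'
#' Fits a quadratic `a x^2 + b x + c` to the profile log-likelihood by least
#' squares; the MLE is the vertex `-b/(2a)`, the standard error is the
#' square root of the negative inverse second derivative `sqrt(-1/(2a))`,
#' and the 95% CI is `mle +/- 1.96 se`.
#'
#' @param profile a `likelihood_profile` (>= 3 grid points).
#' @param window if given, the number of grid points around the profile
#'   maximum used for the fit (odd, >= 3). The default fits all points; a
#'   local window is preferable when the profile is strongly peaked relative
#'   to the grid spacing, where a global quadratic misplaces the vertex.
#' @return list with `mle`, `se`, `ci95`, `quad_coeffs` (a, b, c) and the
#'   input `profile`.
#' @export
quadratic_mle <- function(profile, window = NULL) {
  stopifnot(nrow(profile) >= 3)
  if (!is.null(window)) {
    stopifnot(window >= 3)
    k <- which.max(profile$loglik)
    half <- floor(window / 2)
    lo <- max(1, k - half)
    hi <- min(nrow(profile), k + half)
    profile <- profile[lo:hi, ]
    if (nrow(profile) < 3) stop("window leaves fewer than 3 grid points")
  }
  fit <- stats::lm(loglik ~ I(param^2) + param, data = profile)
  a <- unname(stats::coef(fit)["I(param^2)"])
  b <- unname(stats::coef(fit)["param"])
  cc <- unname(stats::coef(fit)["(Intercept)"])
  if (!is.finite(a) || a >= 0) {
    stop("no interior maximum: fitted quadratic curvature is non-negative\n",
         paste(utils::capture.output(print(profile)), collapse = "\n"))
  }
  mle <- -b / (2 * a)
  se <- sqrt(-1 / (2 * a))
  list(mle = mle, se = se, ci95 = c(mle - 1.96 * se, mle + 1.96 * se),
       quad_coeffs = c(a = a, b = b, c = cc), profile = profile)
}

#' Estimate a cultural-transmission parameter from ancestry samples
#'
#' Sweeps a grid of parameter values, obtains the simulated ancestry cline
#' for each (through `cline_fun`, with optional CSV caching), and combines
#' [profile_likelihood()] with [quadratic_mle()]. `estimate_learning_rate`
#' sweeps the yearly learning rate with mating fixed at 100% within-group;
#' `estimate_mating_rate` sweeps the within-group mating probability with
#' zero learning. Each estimate is therefore an upper bound on its parameter
#' in a combined model of horizontal and vertical transmission.
#'
#' @param samples filtered sample table with `distance_km`.
#' @param grid parameter values to test.
#' @param cline_fun function(value) returning a `cline_profile`.
#' @param cache_dir optional directory for caching clines as CSV per value.
#' @return A [quadratic_mle()] result.
#' @export
estimate_transmission_parameter <- function(samples, grid, cline_fun,
                                            cache_dir = NULL, window = NULL) {
  clines <- lapply(grid, function(v) {
    if (!is.null(cache_dir)) {
      path <- file.path(cache_dir, sprintf("cline_%.6g.csv", v))
      if (file.exists(path)) {
        pr <- utils::read.csv(path)
        class(pr) <- c("cline_profile", "data.frame")
        return(pr)
      }
      pr <- cline_fun(v)
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame(pr), path, row.names = FALSE)
      return(pr)
    }
    cline_fun(v)
  })
  names(clines) <- as.character(grid)
  quadratic_mle(profile_likelihood(samples, clines), window = window)
}

#' @rdname estimate_transmission_parameter
#' @export
estimate_learning_rate <- function(samples, cline_fun,
                                   grid = seq(0, 0.0045, by = 0.0003),
                                   cache_dir = NULL) {
  estimate_transmission_parameter(samples, grid, cline_fun, cache_dir)
}

#' @rdname estimate_transmission_parameter
#' @export
estimate_mating_rate <- function(samples, cline_fun,
                                 grid = seq(0.7, 1, length.out = 10),
                                 cache_dir = NULL) {
  estimate_transmission_parameter(samples, grid, cline_fun, cache_dir)
}

#' Descriptive regression of ancestry on distance
#'
#' The robust fit is an MM-type regression (iteratively reweighted least
#' squares with a Tukey bisquare psi tuned for 95% efficiency,
#' [MASS::rlm()]); plain OLS is also available.
#'
#' @param samples filtered sample table with `distance_km` and `ef`.
#' @param method `"robust"` (default) or `"ols"`.
#' @return list with `slope` (per km), `intercept`, `r_squared` (OLS
#'   definition on the fitted line) and the fit object.
#' @export
regress_cline <- function(samples, method = c("robust", "ols")) {
  method <- match.arg(method)
  fit <- if (method == "robust")
    MASS::rlm(ef ~ distance_km, data = samples, method = "MM")
  else stats::lm(ef ~ distance_km, data = samples)
  co <- stats::coef(fit)
  pred <- stats::fitted(fit)
  r2 <- 1 - sum((samples$ef - pred)^2) / sum((samples$ef - mean(samples$ef))^2)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = r2, fit = fit)
}
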