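#' Parameters for the one-dimensional reaction-diffusion model
#'
#' Bundles the parameters of the three-population reaction-diffusion system:
#' farmers of Early Farmer (EF) ancestry (`u`), farmers of Western
#' Hunter-Gatherer (WHG) ancestry (`v`) and hunter-gatherers of WHG ancestry
#' (`w`). Each population diffuses with constant `D`, grows logistically at
#' rate `alpha` towards the group-specific carrying capacity (`K_F` for both
#' farmer groups, `K_HG` for hunter-gatherers, with all three groups
#' contributing equally to the population pressure), and hunter-gatherers are
#' converted to farming at a rate governed by the learning rate `f` and the
#' learning bias `gamma`.
#'
#' @param D diffusion constant (km^2/yr). The default is calibrated with
#'   [calibrate_diffusion()] so the purely demic front advances at 1 km/yr.
#' @param alpha logistic growth rate (1/yr).
#' @param K_F farmer carrying capacity (individuals/km).
#' @param K_HG hunter-gatherer carrying capacity (individuals/km); defaults to
#'   `K_F / 20` (a twenty-fold density difference).
#' @param f learning rate; units given by `f_units`.
#' @param gamma learning bias (dimensionless). `gamma = 1` is unbiased
#'   learning; the long-run ancestry outcome is governed by the ratio
#'   `f / gamma`.
#' @param f_units `"per_generation"` (default, converted internally using
#'   `gen_time`) or `"per_year"`.
#' @param L habitat length (km).
#' @param farmer_zone initial extent of the farmer population at the left end
#'   of the habitat (km).
#' @param T_gen total simulated time (generations).
#' @param gen_time years per generation.
#' @return An object of class `pde_params` (a list).
#' @export
pde_params <- function(D = calibrate_diffusion(alpha, 1), alpha = 0.03,
                       K_F = 1.28, K_HG = K_F / 20,
                       f = 0, gamma = 1, f_units = c("per_generation", "per_year"),
                       L = 3000, farmer_zone = 200, T_gen = 100, gen_time = 25) {
  f_units <- match.arg(f_units)
  stopifnot(D > 0, alpha > 0, K_F > 0, K_HG > 0, f >= 0, gamma > 0,
            L > farmer_zone, farmer_zone > 0, T_gen > 0, gen_time > 0)
  structure(list(D = D, alpha = alpha, K_F = K_F, K_HG = K_HG,
                 f = f, gamma = gamma, f_units = f_units,
                 L = L, farmer_zone = farmer_zone,
                 T_gen = T_gen, gen_time = gen_time),
            class = "pde_params")
}

#' Calibrate the diffusion constant to a target demic front speed
#'
#' Under purely demic dynamics the model reduces to a Fisher-KPP wave whose
#' asymptotic front speed is `2 * sqrt(D * alpha)`. This inverts that relation:
#' `D = target_speed^2 / (4 * alpha)`.
#'
#' @param alpha logistic growth rate (1/yr).
#' @param target_speed desired front speed (km/yr).
#' @return Diffusion constant `D` (km^2/yr).
#' @export
calibrate_diffusion <- function(alpha, target_speed) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be positive")
  if (!is.numeric(target_speed) || target_speed <= 0)
    stop("`target_speed` must be positive")
  target_speed^2 / (4 * alpha)
}

# Right-hand side of the method-of-lines discretisation. y = c(u, v, w) on an
# nx-point grid; zero-flux boundaries via ghost-node reflection. The
# transmission flux A = f*(u+v)*w / ((u+v) + gamma*w) moves density from w to
# v and conserves u+v+w pointwise.
pde_rhs <- function(t, y, p) {
  nx <- p$nx
  u <- y[seq_len(nx)]
  v <- y[nx + seq_len(nx)]
  w <- y[2 * nx + seq_len(nx)]
  lap <- function(z) {
    zl <- c(z[2], z[-nx])    # reflected ghost node at the left boundary
    zr <- c(z[-1], z[nx - 1])
    (zl - 2 * z + zr) / p$dx^2
  }
  tot <- u + v + w
  fz <- u + v
  denom <- fz + p$gamma * w
  A <- ifelse(denom > 0, p$f_yr * fz * w / denom, 0)
  du <- p$D * lap(u) + p$alpha * u * (1 - tot / p$K_F)
  dv <- p$D * lap(v) + p$alpha * v * (1 - tot / p$K_F) + A
  dw <- p$D * lap(w) + p$alpha * w * (1 - tot / p$K_HG) - A
  list(c(du, dv, dw))
}

#' Solve the three-population reaction-diffusion system
#'
#' Discretises space with second-order central differences (method of lines,
#' zero-flux Neumann boundaries at both ends) and integrates in time with a
#' stiff adaptive solver ([deSolve::ode()], `lsoda`). Initial condition:
#' EF-ancestry farmers at density `K_F` inside the left `farmer_zone` km,
#' hunter-gatherers at `K_HG` elsewhere, no WHG-ancestry farmers anywhere.
#'
#' @param params a [pde_params()] object.
#' @param nx number of spatial grid points (>= 100).
#' @param n_out number of output times (evenly spaced, including 0).
#' @return An object of class `pde_solution`: list with `x` (km), `t_yr`
#'   (years), `t_gen` (generations) and `nx x n_out` matrices `u`, `v`, `w`
#'   (individuals/km).
#' @export
solve_pde <- function(params, nx = 600, n_out = 101) {
  stopifnot(inherits(params, "pde_params"), nx >= 100, n_out >= 2)
  f_yr <- if (params$f_units == "per_generation")
    params$f / params$gen_time else params$f
  dx <- params$L / (nx - 1)
  x <- seq(0, params$L, length.out = nx)
  u0 <- ifelse(x <= params$farmer_zone, params$K_F, 0)
  w0 <- ifelse(x <= params$farmer_zone, 0, params$K_HG)
  y0 <- c(u0, rep(0, nx), w0)
  t_end <- params$T_gen * params$gen_time
  times <- seq(0, t_end, length.out = n_out)
  p <- list(nx = nx, dx = dx, D = params$D, alpha = params$alpha,
            K_F = params$K_F, K_HG = params$K_HG,
            f_yr = f_yr, gamma = params$gamma)
  sol <- deSolve::ode(y = y0, times = times, func = pde_rhs, parms = p,
                      method = "lsoda", rtol = 1e-7, atol = 1e-9 * params$K_HG)
  if (attr(sol, "istate")[1] < 0 || anyNA(sol))
    stop("PDE integration failed (instability or NaN); reduce dx or check parameters")
  get <- function(k) t(sol[, 1 + (k - 1) * nx + seq_len(nx), drop = FALSE])
  out <- list(x = x, t_yr = times, t_gen = times / params$gen_time,
              u = get(1), v = get(2), w = get(3), params = params)
  if (min(out$u, out$v, out$w) < -1e-6 * params$K_HG)
    stop("PDE solution developed significant negative densities")
  class(out) <- "pde_solution"
  out
}

#' @export
#' @describeIn solve_pde long-format gridded table with columns
#'   `x`, `t_yr`, `u`, `v`, `w`, suitable for CSV export.
as.data.frame.pde_solution <- function(x, ...) {
  data.frame(x = rep(x$x, times = length(x$t_yr)),
             t_yr = rep(x$t_yr, each = length(x$x)),
             u = as.vector(x$u), v = as.vector(x$v), w = as.vector(x$w))
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf("pde_solution: %d grid points over %g km, %d times to generation %g\n",
              length(x$x), max(x$x), length(x$t_yr), max(x$t_gen)))
  invisible(x)
}

# Index of the output time closest to `t` (generations by default).
time_index <- function(sol, t, units = c("generations", "years")) {
  units <- match.arg(units)
  tg <- if (units == "generations") sol$t_gen else sol$t_yr
  if (t < min(tg) - 1e-9 || t > max(tg) + 1e-9)
    stop("requested time outside the solved span")
  which.min(abs(tg - t))
}

#' Spatial profile of EF ancestry
#'
#' EF ancestry at each grid point is `u / (u + v + w)`. Positions where the
#' total density falls below `eps` (default `1e-8 * K_HG`) are returned as
#' `NA`.
#'
#' @param sol a `pde_solution`.
#' @param t time at which to evaluate (generations by default).
#' @param units `"generations"` or `"years"`.
#' @param eps emptiness threshold (individuals/km).
#' @return data.frame with columns `x` and `ancestry`.
#' @export
ef_ancestry_profile <- function(sol, t, units = c("generations", "years"),
                                eps = 1e-8 * sol$params$K_HG) {
  i <- time_index(sol, t, units)
  tot <- sol$u[, i] + sol$v[, i] + sol$w[, i]
  anc <- ifelse(tot < eps, NA_real_, sol$u[, i] / tot)
  data.frame(x = sol$x, ancestry = pmin(pmax(anc, 0), 1))
}

#' Spatially averaged EF ancestry
#'
#' Mean of `u/(u+v+w)` over the habitat at time `t`, by default weighted by
#' the total density `u+v+w` (i.e. the EF fraction of the whole population);
#' an unweighted spatial mean is also available.
#'
#' @inheritParams ef_ancestry_profile
#' @param weighted weight the mean by total density (default `TRUE`).
#' @return Scalar mean EF ancestry in \[0, 1\].
#' @export
mean_ef_ancestry <- function(sol, t = sol$params$T_gen,
                             units = c("generations", "years"),
                             weighted = TRUE,
                             eps = 1e-8 * sol$params$K_HG) {
  i <- time_index(sol, t, units)
  tot <- sol$u[, i] + sol$v[, i] + sol$w[, i]
  keep <- tot >= eps
  anc <- sol$u[keep, i] / tot[keep]
  if (!any(keep)) stop("habitat is empty at the requested time")
  if (weighted) sum(anc * tot[keep]) / sum(tot[keep]) else mean(anc)
}

#' Front position and speed of the farming wave in the PDE model
#'
#' The front position at each output time is the farthest `x` at which the
#' farmer density `u + v` exceeds half the local total (linearly interpolated
#' between grid points); the speed is the least-squares slope of position
#' against time over the central portion of the run (burn-in and saturation
#' excluded).
#'
#' @param sol a `pde_solution`.
#' @param burn_in fraction of the series dropped at the start.
#' @return list with `speed` (km/yr) and data.frame `series`.
#' @export
pde_front_speed <- function(sol, burn_in = 0.1) {
  pos <- vapply(seq_along(sol$t_yr), function(i) {
    fr <- (sol$u[, i] + sol$v[, i]) /
      pmax(sol$u[, i] + sol$v[, i] + sol$w[, i], .Machine$double.eps)
    above <- fr >= 0.5
    if (!above[1]) return(0)
    k <- match(FALSE, above)
    if (is.na(k)) return(max(sol$x))
    # interpolate the 50% crossing between grid points k-1 and k
    x0 <- sol$x[k - 1]; x1 <- sol$x[k]
    f0 <- fr[k - 1]; f1 <- fr[k]
    x0 + (0.5 - f0) / (f1 - f0) * (x1 - x0)
  }, numeric(1))
  series <- data.frame(t_yr = sol$t_yr, extent = pos)
  keep <- seq_along(pos) > burn_in * length(pos) & pos < max(sol$x) - 1e-9
  if (sum(keep) < 3) stop("too few usable time points for a speed estimate")
  fit <- stats::lm(extent ~ t_yr, data = series[keep, ])
  list(speed = unname(stats::coef(fit)[2]), series = series)
}
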