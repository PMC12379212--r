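#' Equilibrium age-specific mortality from an age-at-death distribution
#'
#' Converts an osteological age-at-death probability mass function into the
#' per-age yearly death hazard that reproduces it at demographic equilibrium:
#' `h(a) = d(a) / S(a)` with survivorship `S(a) = 1 - sum(d(a' < a))`. The
#' hazard at the last age with death mass is 1 (everyone reaching it dies).
#'
#' @param age_at_death numeric vector of probability masses for ages
#'   `0, 1, ..., length - 1`; must be non-negative and sum to 1.
#' @param source label recorded on the curve (`"standard"`, `"alternative"`,
#'   `"synthetic"`, ...).
#' @return Object of class `mortality_curve`: list with `ages`, `hazard`,
#'   `pmf`, `survivorship` and `source`.
#' @export
equilibrium_hazard <- function(age_at_death, source = "synthetic") {
  d <- as.numeric(age_at_death)
  if (any(d < 0)) stop("age-at-death masses must be non-negative")
  if (abs(sum(d) - 1) > 1e-9) stop("age-at-death masses must sum to 1")
  a_max <- max(which(d > 0)) - 1L
  d <- d[seq_len(a_max + 1L)]
  S <- 1 - cumsum(c(0, d[-length(d)]))
  if (any(S <= 0 & d > 0))
    stop("survivorship reaches zero before the last death mass")
  h <- ifelse(S > 0, d / S, 1)
  h <- pmin(pmax(h, 0), 1)
  h[length(h)] <- 1
  structure(list(ages = 0:a_max, hazard = h, pmf = d, survivorship = S,
                 source = source),
            class = "mortality_curve")
}

#' @export
print.mortality_curve <- function(x, ...) {
  cat(sprintf("mortality_curve (%s): ages 0-%d, life expectancy %.1f yr\n",
              x$source, max(x$ages), sum(x$ages * x$pmf)))
  invisible(x)
}

#' Stationary age distribution implied by a mortality curve
#'
#' In a stationary population with constant yearly births, the number of
#' individuals alive at age `a` is proportional to the survivorship `S(a)`.
#'
#' @param curve a [equilibrium_hazard()] mortality curve.
#' @return data.frame with `age` and `prob` (normalised `S(a)`).
#' @export
stationary_age_distribution <- function(curve) {
  stopifnot(inherits(curve, "mortality_curve"))
  data.frame(age = curve$ages, prob = curve$survivorship / sum(curve$survivorship))
}

#' Balancing fertility rate
#'
#' The yearly per-mature-individual Poisson offspring rate `b` such that, in
#' the stationary age structure implied by `curve`, yearly births equal
#' yearly deaths and a population at carrying capacity is stationary. With
#' `B` births per year, the stationary population holds `B * S(a)`
#' individuals of age `a`, all of whom eventually die, so deaths/yr = `B` and
#' `b = 1 / sum(S(a), a >= maturity_age)`.
#'
#' @param curve a mortality curve.
#' @param maturity_age first reproductive age in years (default 12,
#'   i.e. mature when older than 11).
#' @return Yearly fertility rate per mature individual.
#' @export
balancing_fertility <- function(curve, maturity_age = 12) {
  stopifnot(inherits(curve, "mortality_curve"))
  mature <- curve$ages >= maturity_age
  if (!any(mature)) stop("no mature age classes under this curve")
  1 / sum(curve$survivorship[mature])
}

#' Density-scaled experienced mortality
#'
#' Scales the equilibrium hazard by the local population pressure: the ratio
#' of the number of neighbours within the competition radius (all individuals,
#' regardless of cultural group) to the number expected at the focal
#' individual's group-specific carrying capacity. Capped at 1.
#'
#' @param base_hazard equilibrium hazard(s) `h(a)` for the focal
#'   individual(s).
#' @param n_local neighbour count(s) within the competition radius.
#' @param expected_at_K expected neighbour count at carrying capacity for the
#'   focal individual's group (see [expected_neighbours()]).
#' @return Yearly death probability (vectorised).
#' @export
experienced_hazard <- function(base_hazard, n_local, expected_at_K) {
  if (any(expected_at_K <= 0)) stop("`expected_at_K` must be positive")
  pmin(1, base_hazard * n_local / expected_at_K)
}

#' Expected neighbour count at carrying capacity
#'
#' `K * pi * radius^2 / downscale`, the number of individuals expected in the
#' full competition disk at the (downscaled) group carrying capacity. Coastal
#' truncation of the disk is ignored by default; the agent-based simulation
#' exposes an optional habitable-area correction.
#'
#' @param K carrying capacity (individuals/km^2).
#' @param radius competition radius (km).
#' @param downscale density divisor used to reduce simulation size.
#' @return Expected count (dimensionless).
#' @export
expected_neighbours <- function(K, radius = 30, downscale = 5) {
  stopifnot(K > 0, radius > 0, downscale >= 1)
  K * pi * radius^2 / downscale
}

#' Demographic and interaction parameters for the agent-based model
#'
#' @param K_F farmer carrying capacity (individuals/km^2).
#' @param K_HG hunter-gatherer carrying capacity (individuals/km^2).
#' @param fertility yearly Poisson offspring rate per mature individual; by
#'   default the balancing rate for `curve`.
#' @param maturity_age first reproductive age (mature when age >=
#'   `maturity_age`, i.e. "over the age of 11" with the default 12).
#' @param comp_radius competition radius (km).
#' @param mate_radius mate-search radius (km).
#' @param learn_radius learning radius (km).
#' @param downscale divisor applied to carrying capacities and initial
#'   density to reduce simulation size.
#' @param curve mortality curve used for age-dependent hazards.
#' @param edge_correction if `TRUE`, `expected_at_K` is scaled by the
#'   habitable fraction of each individual's competition disk, so coastal and
#'   narrow-habitat populations equilibrate at the same density as the bulk.
#' @return Object of class `demography_params`.
#' @export
demography_params <- function(K_F = 1.28, K_HG = 0.064,
                              curve = equilibrium_hazard(default_mortality_pmf()),
                              fertility = balancing_fertility(curve, maturity_age),
                              maturity_age = 12,
                              comp_radius = 30, mate_radius = 10,
                              learn_radius = 10, downscale = 5,
                              edge_correction = FALSE) {
  stopifnot(K_F > 0, K_HG > 0, fertility > 0, maturity_age > 0,
            comp_radius > 0, mate_radius > 0, learn_radius > 0, downscale >= 1,
            inherits(curve, "mortality_curve"))
  structure(list(K_F = K_F, K_HG = K_HG, fertility = fertility,
                 maturity_age = maturity_age, comp_radius = comp_radius,
                 mate_radius = mate_radius, learn_radius = learn_radius,
                 downscale = downscale, curve = curve,
                 edge_correction = isTRUE(edge_correction)),
            class = "demography_params")
}

#' Read / write an age-at-death table
#'
#' CSV with columns `age` and either `death_probability_mass` or `hazard`.
#' The loader validates normalisation of the mass column and fills skipped
#' ages with zero mass.
#'
#' @param path CSV file path.
#' @return A `mortality_curve`.
#' @export
read_mortality_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!"age" %in% names(tab)) stop("mortality table must have an `age` column")
  a_max <- max(tab$age)
  if ("death_probability_mass" %in% names(tab)) {
    d <- numeric(a_max + 1)
    d[tab$age + 1] <- tab$death_probability_mass
    if (abs(sum(d) - 1) > 1e-6) stop("death probability masses do not sum to 1")
    d <- d / sum(d)
    equilibrium_hazard(d, source = "file")
  } else if ("hazard" %in% names(tab)) {
    h <- numeric(a_max + 1)
    h[tab$age + 1] <- tab$hazard
    if (any(h < 0 | h > 1)) stop("hazards must lie in [0, 1]")
    h[a_max + 1] <- 1
    S <- cumprod(c(1, 1 - h[-length(h)]))
    d <- S * h
    equilibrium_hazard(d / sum(d), source = "file")
  } else {
    stop("mortality table needs a `death_probability_mass` or `hazard` column")
  }
}

#' @rdname read_mortality_table
#' @param curve a `mortality_curve` to write.
#' @export
write_mortality_table <- function(curve, path) {
  utils::write.csv(data.frame(age = curve$ages,
                              death_probability_mass = curve$pmf),
                   path, row.names = FALSE)
  invisible(path)
}

#' Simulate lifetimes under a mortality curve
#'
#' Draws ages at death by applying the yearly hazard from age 0 upward. Used
#' as a Monte-Carlo round-trip check that [equilibrium_hazard()] reproduces
#' its input age-at-death distribution.
#'
#' @param curve a mortality curve.
#' @param n number of lifetimes.
#' @return Integer vector of ages at death.
#' @export
simulate_lifetimes <- function(curve, n) {
  h <- curve$hazard
  ages <- integer(n)
  alive <- rep(TRUE, n)
  for (a in seq_along(h)) {
    die <- alive & (stats::runif(n) < h[a])
    ages[die] <- a - 1L
    alive <- alive & !die
  }
  ages[alive] <- length(h) - 1L
  ages
}
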