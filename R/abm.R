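#' @useDynLib neolexp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

N_LOCI <- 247L
N_MARKERS <- 494L

new_genomes <- function(n, value = 0L) {
  matrix(as.raw(value), nrow = N_MARKERS, ncol = n)
}

#' Per-individual EF ancestry
#'
#' Proportion of the 494 diploid marker loci (247 per haplotype, one per Mb
#' on a 247 Mb chromosome) carrying the Early Farmer allele.
#'
#' @param genome raw 494 x n marker matrix (1 = EF allele).
#' @return Numeric vector in \[0, 1\].
#' @export
genome_ancestry <- function(genome) {
  colSums(genome == as.raw(1)) / N_MARKERS
}

# Assemble the mask representation consumed by the C++ kernels.
mask_for_cpp <- function(mask, demog = NULL) {
  out <- list(grid_int = matrix(as.integer(mask$grid), nrow(mask$grid)),
              cell_size = mask$cell_size,
              width_km = mask$width_km, height_km = mask$height_km,
              route_int = NULL, route_sx = NULL, route_sy = NULL,
              habfrac = NULL)
  if (length(mask$overlays)) {
    rid <- matrix(0L, nrow(mask$grid), ncol(mask$grid))
    sx <- sy <- matrix(0, nrow(mask$grid), ncol(mask$grid))
    ord <- order(vapply(mask$overlays, function(o) o$sigma[1], 1))  # larger last
    for (k in ord) {
      ov <- mask$overlays[[k]]
      rid[ov$grid] <- k
      sx[ov$grid] <- ov$sigma[1]
      sy[ov$grid] <- ov$sigma[2]
    }
    out$route_int <- rid
    out$route_sx <- sx
    out$route_sy <- sy
  }
  if (!is.null(demog) && isTRUE(demog$edge_correction))
    out$habfrac <- disk_habitable_fraction(mask, demog$comp_radius)
  out
}

#' Habitable fraction of the competition disk
#'
#' For every raster cell, the fraction of a disk of radius `radius` centred
#' on the cell that falls on habitable cells inside the map. Used by the
#' optional edge correction of density-dependent mortality, so populations
#' near coasts and map borders equilibrate at the same density as the bulk.
#'
#' @param mask a `landscape_mask`.
#' @param radius disk radius (km).
#' @return Numeric matrix with the raster's shape.
#' @export
disk_habitable_fraction <- function(mask, radius) {
  g <- mask$grid * 1
  nr <- nrow(g)
  nc <- ncol(g)
  rc <- floor(radius / mask$cell_size)
  acc <- matrix(0, nr, nc)
  n_off <- 0
  for (dr in -rc:rc) for (dc in -rc:rc) {
    if ((dr^2 + dc^2) * mask$cell_size^2 > radius^2) next
    n_off <- n_off + 1
    src_r <- (1 + max(0, dr)):(nr + min(0, dr))
    dst_r <- src_r - dr
    src_c <- (1 + max(0, dc)):(nc + min(0, dc))
    dst_c <- src_c - dc
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + g[src_r, src_c]
  }
  acc / n_off
}

par_for_cpp <- function(state) {
  d <- state$demog
  list(f = state$f, m = state$m, fertility = d$fertility,
       maturity_age = as.integer(d$maturity_age),
       comp_radius = d$comp_radius, mate_radius = d$mate_radius,
       learn_radius = d$learn_radius,
       expectedF = expected_neighbours(d$K_F, d$comp_radius, d$downscale),
       expectedHG = expected_neighbours(d$K_HG, d$comp_radius, d$downscale),
       hazard = d$curve$hazard, sigma = state$sigma,
       offspring_random_culture = isTRUE(state$offspring_random_culture),
       max_attempts = 1000L)
}

#' Initialise an agent-based simulation state
#'
#' Populates the habitable area at the (downscaled) hunter-gatherer carrying
#' capacity: the total count is Poisson with mean `K_HG / downscale x
#' habitable area`, positions are uniform over habitable cells, and ages are
#' drawn from the stationary age distribution of the mortality curve.
#' Individuals for which `farmer_region` is `TRUE` start as farmers with
#' all-EF genomes; everyone else starts as a hunter-gatherer with an all-WHG
#' genome.
#'
#' @param mask a `landscape_mask`.
#' @param demog a [demography_params()] object.
#' @param f yearly learning rate.
#' @param m within-group mating probability.
#' @param sigma base step size `c(sigma_x, sigma_y)` (km); a scalar is
#'   recycled.
#' @param farmer_region predicate `function(x, y)` marking the initial
#'   farming area (default: the paper-style strip `x <= 74` km).
#' @param offspring_random_culture if `TRUE`, offspring of mixed matings
#'   adopt the culture of a random parent instead of always farming.
#' @param seed optional seed.
#' @return Object of class `sim_state`.
#' @export
initialize_state <- function(mask, demog, f = 0, m = 1, sigma = 5,
                             farmer_region = function(x, y) x <= 74,
                             offspring_random_culture = FALSE, seed = NULL) {
  stopifnot(inherits(mask, "landscape_mask"), inherits(demog, "demography_params"))
  if (!is.null(seed)) set.seed(seed)
  if (length(sigma) == 1) sigma <- c(sigma, sigma)
  hab_cells <- which(mask$grid)
  area <- length(hab_cells) * mask$cell_size^2
  dens <- demog$K_HG / demog$downscale
  n <- stats::rpois(1, dens * area)
  cells <- sample(hab_cells, n, replace = TRUE)
  row <- (cells - 1) %% nrow(mask$grid) + 1
  col <- (cells - 1) %/% nrow(mask$grid) + 1
  x <- (col - 1 + stats::runif(n)) * mask$cell_size
  y <- mask$height_km - (row - 1 + stats::runif(n)) * mask$cell_size
  agedist <- stationary_age_distribution(demog$curve)
  age <- sample(agedist$age, n, replace = TRUE, prob = agedist$prob)
  farmer <- farmer_region(x, y)
  if (!any(farmer)) warning("empty farmer region: pure hunter-gatherer run")
  genome <- new_genomes(n, 0L)
  genome[, farmer] <- as.raw(1)
  structure(list(x = x, y = y, age = as.integer(age),
                 culture = as.integer(farmer), genome = genome,
                 year = 0L, mask = mask, demog = demog,
                 f = f, m = m, sigma = sigma,
                 offspring_random_culture = offspring_random_culture),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: year %d, %d individuals (%d farmers, %d HGs), f=%g, m=%g\n",
              x$year, length(x$x), sum(x$culture == 1), sum(x$culture == 0),
              x$f, x$m))
  invisible(x)
}

#' Snapshot of a simulation state
#'
#' @param state a `sim_state`.
#' @return data.frame with `id, x, y, age, culture, ancestry`.
#' @export
as_snapshot <- function(state) {
  data.frame(id = seq_along(state$x), x = state$x, y = state$y,
             age = state$age,
             culture = ifelse(state$culture == 1, "farmer", "hunter_gatherer"),
             ancestry = genome_ancestry(state$genome))
}

#' Single yearly events (movement, learning, reproduction, mortality)
#'
#' These apply one event of the yearly cycle and return the updated state;
#' [run_simulation()] runs the full cycle for many years in compiled code.
#' `learning_step` converts each hunter-gatherer with probability `f x`
#' (farmers within the learning radius) / (all neighbours within the
#' radius), computed synchronously from the pre-step state; conversion
#' changes culture only, never the genome. `reproduction_step` lets every
#' mature individual seek a mate within the mate radius (same-culture with
#' probability `m`), drawing `Poisson(fertility)` offspring per successful
#' pairing; offspring receive one recombinant gamete from each parent, age 0
#' and the chooser's position, and farm if either parent farms (unless
#' `offspring_random_culture`). `mortality_step` kills each individual with
#' its density-scaled experienced hazard and ages survivors by one year.
#'
#' @param state a `sim_state`.
#' @return The updated `sim_state` (for `learning_step`, with attribute
#'   `"converted"` giving the converted ids).
#' @export
movement_step <- function(state) {
  out <- cpp_move(state$x, state$y, mask_for_cpp(state$mask), par_for_cpp(state))
  state$x <- out[, 1]
  state$y <- out[, 2]
  state
}

#' @rdname movement_step
#' @export
learning_step <- function(state) {
  prob <- cpp_learning_probs(state$x, state$y, state$culture,
                             state$mask$width_km, state$mask$height_km,
                             par_for_cpp(state))
  conv <- which(stats::runif(length(prob)) < prob)
  state$culture[conv] <- 1L
  attr(state, "converted") <- conv
  state
}

#' @rdname movement_step
#' @export
reproduction_step <- function(state) {
  off <- cpp_reproduction(state$x, state$y, state$age, state$culture,
                          state$genome, state$mask$width_km,
                          state$mask$height_km, par_for_cpp(state))
  state$x <- c(state$x, off$x)
  state$y <- c(state$y, off$y)
  state$age <- c(state$age, off$age)
  state$culture <- c(state$culture, off$culture)
  state$genome <- cbind(state$genome, off$genome)
  attr(state, "n_offspring") <- length(off$x)
  state
}

#' @rdname movement_step
#' @export
mortality_step <- function(state) {
  prob <- cpp_mortality_probs(state$x, state$y, state$age, state$culture,
                              mask_for_cpp(state$mask, state$demog),
                              par_for_cpp(state))
  keep <- stats::runif(length(prob)) >= prob
  state$x <- state$x[keep]
  state$y <- state$y[keep]
  state$age <- state$age[keep] + 1L
  state$culture <- state$culture[keep]
  state$genome <- state$genome[, keep, drop = FALSE]
  state
}

#' Probability that a hunter-gatherer learns farming this year
#'
#' `f x` local farmer proportion within the learning radius (focal excluded);
#' zero for farmers and for hunter-gatherers with no neighbours.
#'
#' @param state a `sim_state`.
#' @return Numeric vector, one probability per individual.
#' @export
learning_probabilities <- function(state) {
  cpp_learning_probs(state$x, state$y, state$culture,
                     state$mask$width_km, state$mask$height_km,
                     par_for_cpp(state))
}

#' Choose a mate for one individual
#'
#' With probability `m` the candidate set is restricted to mature same-culture
#' neighbours within the mate radius (excluding the focal individual),
#' otherwise mature neighbours of any culture; the mate is drawn uniformly.
#'
#' @param state a `sim_state`.
#' @param i focal individual index (must be mature).
#' @param restrict optionally force the within-group (`TRUE`) / any-culture
#'   (`FALSE`) decision instead of drawing it with probability `m`.
#' @return The chosen mate's index, or `NA` if no suitable mate exists.
#' @export
mate_choice <- function(state, i, restrict = NULL) {
  d <- state$demog
  if (state$age[i] < d$maturity_age) stop("focal individual is not mature")
  if (is.null(restrict)) restrict <- stats::runif(1) < state$m
  dist2 <- (state$x - state$x[i])^2 + (state$y - state$y[i])^2
  ok <- dist2 <= d$mate_radius^2 & state$age >= d$maturity_age
  ok[i] <- FALSE
  if (restrict) ok <- ok & state$culture == state$culture[i]
  cand <- which(ok)
  if (!length(cand)) return(NA_integer_)
  cand[sample.int(length(cand), 1)]
}

#' Meiosis: one recombinant gamete
#'
#' Builds a gamete from a parent's two haplotypes by walking the 247 Mb
#' marker map and switching source haplotype at crossover points drawn from a
#' Poisson process at 1 cM/Mb (expected 2.47 crossovers); the starting
#' haplotype is chosen uniformly.
#'
#' @param parent_genome raw vector of 494 markers (haplotype 1 then 2).
#' @return Raw vector of 247 gamete markers.
#' @export
meiosis <- function(parent_genome) {
  cpp_meiosis(as.raw(parent_genome))
}

#' Run the agent-based simulation
#'
#' Applies, each year, the event cycle movement -> learning -> reproduction
#' -> mortality (order configurable) in compiled code, recording the farming
#' front extent yearly. The run terminates early once no hunter-gatherers
#' remain (farming is ubiquitous) or every individual has died.
#'
#' @param state a `sim_state` from [initialize_state()].
#' @param years maximum number of yearly steps.
#' @param order event order, a permutation of
#'   `c("move", "learn", "reproduce", "die")`.
#' @param front_bins number of X-axis bins used for the yearly front extent.
#' @param settle_years extra years simulated after the last hunter-gatherer
#'   disappears.
#' @return The final `sim_state`, with a `history` element: `front_extents`
#'   (km per year), `completion_year` (NA if farming never became ubiquitous),
#'   `years_run` and `extinct`.
#' @export
run_simulation <- function(state, years,
                           order = c("move", "learn", "reproduce", "die"),
                           front_bins = 20, settle_years = 0) {
  stopifnot(years >= 1)
  codes <- match(order, c("move", "learn", "reproduce", "die"))
  if (anyNA(codes)) stop("unknown event in `order`")
  res <- cpp_run_abm(state$x, state$y, state$age, state$culture, state$genome,
                     mask_for_cpp(state$mask, state$demog), par_for_cpp(state),
                     as.integer(years), as.integer(codes),
                     as.integer(front_bins), as.integer(settle_years))
  state$x <- res$x
  state$y <- res$y
  state$age <- res$age
  state$culture <- res$culture
  state$genome <- res$genome
  state$year <- state$year + res$years_run
  state$history <- list(front_extents = res$front_extents,
                        completion_year = res$completion_year,
                        years_run = res$years_run, extinct = res$extinct)
  state
}
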