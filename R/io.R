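#' Default run configuration
#'
#' The full set of tunable parameters with their default values and units.
#' Scenarios mirror the landscape variants explored in the analyses:
#' `square` (uniform plane), `uniform_complex` (continent-shaped mask),
#' `ew_biased` (sigma_x 6 km, sigma_y 4 km), `coastal` and `corridors`
#' (dispersal-corridor overlays with a reduced 3 km base step).
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    scenario = "square",
    seed = 1L,
    pde = list(D = NULL, alpha = 0.03, K_F = 1.28, K_HG = 0.064,
               f = 0, f_units = "per_generation", gamma = 1,
               L = 3000, farmer_zone = 200, T_gen = 100, gen_time = 25,
               nx = 600),
    demography = list(K_F = 1.28, K_HG = 0.064, fertility = NULL,
                      maturity_age = 12, comp_radius = 30, mate_radius = 10,
                      learn_radius = 10, downscale = 5,
                      edge_correction = FALSE),
    abm = list(f = 0, m = 1, sigma_x = 5, sigma_y = 5, years = 4000,
               farmer_zone = 74, front_bins = 20,
               offspring_random_culture = FALSE),
    landscape = list(kind = "square", cell_size = 5,
                     width_km = 3700, height_km = 3700),
    inference = list(origin_lon = 33.0, origin_lat = 39.9,
                     date_min = 5000, date_max = 8500,
                     p_min = 0.01, se_max = 0.022, steppe_max = 0.05,
                     lat_cutoff = 45,
                     learning_grid = seq(0, 0.0045, by = 0.0003),
                     mating_grid = seq(0.7, 1, length.out = 10))
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", key)
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", key, " must be a section")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  with(cfg$demography, {
    if (K_F <= 0 || K_HG <= 0) stop("carrying capacities must be positive")
    if (downscale < 1) stop("downscale must be >= 1")
  })
  with(cfg$abm, {
    if (f < 0) stop("learning rate must be non-negative")
    if (m < 0 || m > 1) stop("within-group mating probability must be in [0, 1]")
    if (sigma_x < 0 || sigma_y < 0) stop("step sizes must be non-negative")
  })
  if (!cfg$scenario %in% c("square", "uniform_complex", "ew_biased",
                           "coastal", "corridors"))
    stop("unknown scenario: ", cfg$scenario)
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, applies defaults and
#' validates values. An empty file yields the full defaults.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a results bundle
#'
#' Writes every data.frame in `bundle` as CSV, every other element into a
#' JSON summary (together with the seed, package version and resolved
#' configuration), and the configuration as YAML.
#'
#' @param bundle named list of data.frames and summary values.
#' @param dir output directory (created if needed).
#' @param config resolved configuration list (optional).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  summary <- list(package_version = as.character(utils::packageVersion("neolexp")))
  if (!is.null(config)) {
    summary$seed <- config$seed
    cfg_path <- file.path(dir, "config.yaml")
    yaml::write_yaml(config, cfg_path)
    paths <- c(paths, cfg_path)
  }
  for (nm in names(bundle)) {
    el <- bundle[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(el, p, row.names = FALSE)
      paths <- c(paths, p)
    } else {
      summary[[nm]] <- el
    }
  }
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sp))
}
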