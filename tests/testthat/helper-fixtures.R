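# Shared small fixtures. ABM tests use short strips and the default
# demography unless stated; problem sizes are kept small so the whole suite
# runs quickly.

tiny_demog <- function(...) {
  demography_params(edge_correction = TRUE, ...)
}

tiny_strip <- function(width_km = 300, height_km = 50, cell_size = 5) {
  generate_landscape_fixtures("strip", cell_size = cell_size,
                              width_km = width_km, height_km = height_km)
}

open_mask <- function(size_km = 1000, cell_size = 10) {
  load_mask(matrix(TRUE, size_km / cell_size, size_km / cell_size), cell_size)
}

# dense cluster state for reproduction/mortality kernels: n individuals
# uniformly on a small square patch of an open mask
cluster_state <- function(n, patch_km = 100, demog = tiny_demog(),
                          culture = rep(1L, n), age = rep(20L, n), seed = 1) {
  set.seed(seed)
  mask <- open_mask(patch_km, cell_size = 10)
  st <- suppressWarnings(
    initialize_state(mask, demog, f = 0, m = 1, sigma = 5, seed = seed))
  st$x <- runif(n, 0, patch_km)
  st$y <- runif(n, 0, patch_km)
  st$age <- as.integer(age)
  st$culture <- as.integer(culture)
  st$genome <- neolexp:::new_genomes(n, 0L)
  st$genome[, culture == 1L] <- as.raw(1)
  st
}
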