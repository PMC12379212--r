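test_that("initialisation matches density, genomes and age structure", {
  mask <- tiny_strip(500, 100)
  dem <- tiny_demog()
  st <- initialize_state(mask, dem, seed = 1)
  lambda <- 500 * 100 * dem$K_HG / dem$downscale
  expect_lt(abs(length(st$x) - lambda), 3 * sqrt(lambda))
  expect_true(all(is_habitable(mask, st$x, st$y)))
  # farmers in the left 74 km with all-EF genomes, HGs all-WHG
  farmers <- st$culture == 1
  expect_true(all(st$x[farmers] <= 74))
  expect_true(all(colSums(st$genome[, farmers] == as.raw(1)) == 494))
  expect_true(all(colSums(st$genome[, !farmers] == as.raw(1)) == 0))
})

test_that("initial ages follow the stationary age distribution", {
  dem <- demography_params(K_HG = 6.4, downscale = 1, edge_correction = TRUE)
  mask <- open_mask(100, cell_size = 10)
  st <- initialize_state(mask, dem, seed = 2)  # ~64k individuals
  stat <- stationary_age_distribution(dem$curve)
  emp <- tabulate(st$age + 1, length(stat$prob)) / length(st$age)
  tv <- 0.5 * sum(abs(emp - stat$prob))
  expect_lt(tv, 0.015)
})

test_that("meiosis preserves homozygous genomes and marker bounds", {
  all1 <- as.raw(rep(1, 494))
  expect_true(all(meiosis(all1) == as.raw(1)))
  all0 <- as.raw(rep(0, 494))
  expect_true(all(meiosis(all0) == as.raw(0)))
  set.seed(3)
  for (k in 1:50) {
    parent <- as.raw(rbinom(494, 1, 0.5))
    gam <- meiosis(parent)
    # every gamete locus is copied from one of the two parental haplotypes
    expect_true(all(gam == parent[1:247] | gam == parent[248:494]))
  }
})

test_that("crossover frequency matches the 1 cM/Mb map", {
  # heterozygous parent: haplotype switches along the gamete occur between
  # adjacent markers with P(odd number of crossovers in 1 Mb), so the mean
  # number of switches is 246 * (1 - exp(-2 * 0.01)) / 2
  het <- as.raw(c(rep(1, 247), rep(0, 247)))
  set.seed(4)
  n <- 2e4
  switches <- vapply(seq_len(n), function(i) {
    g <- as.integer(meiosis(het))
    sum(abs(diff(g)))
  }, 1)
  expected <- 246 * (1 - exp(-2 * 0.01)) / 2
  expect_equal(mean(switches), expected, tolerance = 0.03)
})

test_that("offspring of an F1 x pure-EF cross average 75% EF ancestry", {
  f1 <- as.raw(c(rep(1, 247), rep(0, 247)))
  pure <- as.raw(rep(1, 494))
  set.seed(5)
  anc <- vapply(seq_len(5000), function(i) {
    (sum(meiosis(f1) == as.raw(1)) + sum(meiosis(pure) == as.raw(1))) / 494
  }, 1)
  expect_equal(mean(anc), 0.75, tolerance = 0.01)
})

test_that("learning probability is the farmer share times the learning rate", {
  st <- cluster_state(40, patch_km = 10, culture = c(rep(1L, 39), 0L))
  st$f <- 0.001
  p <- learning_probabilities(st)
  expect_equal(p[40], 0.001, tolerance = 1e-12)  # all 39 neighbours farm
  expect_true(all(p[1:39] == 0))                 # farmers never learn
  # isolated HG: no farmers within reach
  st2 <- cluster_state(2, patch_km = 100, culture = c(0L, 1L))
  st2$x <- c(5, 95)
  st2$y <- c(5, 95)
  st2$f <- 0.5
  expect_equal(learning_probabilities(st2)[1], 0)
  # f = 0 converts nobody
  st$f <- 0
  st3 <- learning_step(st)
  expect_identical(st3$culture, st$culture)
})

test_that("learning changes culture but never the genome", {
  st <- cluster_state(60, patch_km = 10, culture = c(rep(1L, 30), rep(0L, 30)))
  st$f <- 0.9
  set.seed(6)
  st2 <- learning_step(st)
  expect_gt(length(attr(st2, "converted")), 0)
  expect_identical(st2$genome, st$genome)
  expect_true(all(st2$culture >= st$culture))  # transitions only HG -> farmer
})

test_that("mate choice respects radius, maturity and group restriction", {
  st <- cluster_state(6, patch_km = 10,
                      culture = c(1L, 1L, 1L, 1L, 0L, 0L),
                      age = c(20L, 20L, 20L, 5L, 20L, 20L))
  st$x <- c(5, 5, 5, 5, 5, 200)
  st$y <- c(5, 5.1, 4.9, 5, 5.2, 5)
  # focal farmer, restricted: only mature farmers 2 and 3 qualify
  set.seed(7)
  for (k in 1:20) expect_true(mate_choice(st, 1, restrict = TRUE) %in% 2:3)
  # unrestricted adds the near mature HG (5), never the far one (6)
  picks <- vapply(1:200, function(k) mate_choice(st, 1, restrict = FALSE), 1L)
  expect_setequal(sort(unique(picks)), c(2L, 3L, 5L))
  # lone mature individual with within-group mating finds nobody
  lone <- cluster_state(2, patch_km = 100, culture = c(0L, 1L))
  lone$x <- c(5, 95)
  lone$y <- c(5, 95)
  lone$m <- 1
  expect_true(is.na(mate_choice(lone, 1, restrict = TRUE)))
})

test_that("partner culture frequencies follow the within-group probability", {
  # focal farmer amid 3 mature farmers and 2 mature HGs, all in range:
  # P(farmer partner) = m + (1 - m) * 3/5
  st <- cluster_state(6, patch_km = 10, culture = c(1L, 1L, 1L, 1L, 0L, 0L))
  st$x <- rep(5, 6)
  st$y <- rep(5, 6)
  st$m <- 0.5
  set.seed(8)
  picks <- vapply(1:4000, function(k) mate_choice(st, 1), 1L)
  expect_equal(mean(st$culture[picks] == 1), 0.5 + 0.5 * 3 / 5,
               tolerance = 0.02)
})

test_that("offspring numbers are Poisson with the fertility rate", {
  dem <- tiny_demog()
  st <- cluster_state(20000, patch_km = 600, demog = dem)
  set.seed(9)
  st2 <- reproduction_step(st)
  n_off <- attr(st2, "n_offspring")
  lambda_hat <- n_off / 20000
  expect_lt(abs(lambda_hat - dem$fertility), 4 * sqrt(dem$fertility / 20000))
  expect_true(all(st2$age[20001:length(st2$x)] == 0))
})

test_that("mixed matings produce farmers unless the random rule is on", {
  pair <- cluster_state(2, patch_km = 10, culture = c(1L, 0L))
  pair$x <- c(5, 5)
  pair$y <- c(5, 5)
  pair$m <- 0
  pair$demog$fertility <- 3  # many offspring per year for counting
  set.seed(10)
  off_cult <- integer()
  for (k in 1:40) {
    st2 <- reproduction_step(pair)
    off_cult <- c(off_cult, st2$culture[-(1:2)])
  }
  expect_true(all(off_cult == 1L))
  pair$offspring_random_culture <- TRUE
  off_cult <- integer()
  for (k in 1:200) {
    st2 <- reproduction_step(pair)
    off_cult <- c(off_cult, st2$culture[-(1:2)])
  }
  expect_equal(mean(off_cult == 1L), 0.5, tolerance = 0.05)
})

test_that("mortality matches the closed-form experienced hazard", {
  dem <- tiny_demog()
  st <- cluster_state(400, patch_km = 200, demog = dem,
                      culture = rep(c(0L, 1L), 200),
                      age = sample(0:60, 400, replace = TRUE))
  probs <- neolexp:::cpp_mortality_probs(
    st$x, st$y, st$age, st$culture,
    neolexp:::mask_for_cpp(st$mask, demography_params(edge_correction = FALSE)),
    neolexp:::par_for_cpp(st))
  # independent R oracle: brute-force neighbour counts + experienced_hazard
  d2 <- as.matrix(dist(cbind(st$x, st$y)))^2
  n_local <- rowSums(d2 <= dem$comp_radius^2) - 1
  expK <- ifelse(st$culture == 1,
                 expected_neighbours(dem$K_F, dem$comp_radius, dem$downscale),
                 expected_neighbours(dem$K_HG, dem$comp_radius, dem$downscale))
  h <- ifelse(st$age < length(dem$curve$hazard), dem$curve$hazard[st$age + 1], 1)
  expect_equal(probs, experienced_hazard(h, n_local, expK), tolerance = 1e-12)
})

test_that("an isolated individual never dies of competition", {
  st <- cluster_state(1, patch_km = 100, age = 30L)
  probs <- neolexp:::cpp_mortality_probs(
    st$x, st$y, st$age, st$culture,
    neolexp:::mask_for_cpp(st$mask, st$demog), neolexp:::par_for_cpp(st))
  expect_equal(probs, 0)
})

test_that("a well-mixed population at carrying capacity stays stationary", {
  # large steps keep the spatial distribution near-uniform, isolating the
  # birth/death balance from spatial clumping
  dem <- tiny_demog()
  mask <- open_mask(200, cell_size = 10)
  st <- initialize_state(mask, dem, f = 0, m = 1, sigma = 40,
                         farmer_region = function(x, y) rep(TRUE, length(x)),
                         seed = 11)
  # start at the farmer carrying capacity
  target <- round(200 * 200 * dem$K_F / dem$downscale)
  idx <- sample.int(length(st$x), target, replace = TRUE)
  st$x <- runif(target, 0, 200)
  st$y <- runif(target, 0, 200)
  st$age <- st$age[idx]
  st$culture <- rep(1L, target)
  st$genome <- neolexp:::new_genomes(target, 1L)
  st2 <- run_simulation(st, 200, settle_years = 200)
  n_t <- length(st2$x)
  expect_gt(n_t, 0.85 * target)
  expect_lt(n_t, 1.2 * target)
})

test_that("a sparse well-mixed population grows towards carrying capacity", {
  dem <- tiny_demog()
  mask <- open_mask(200, cell_size = 10)
  st <- initialize_state(mask, dem, f = 0, m = 1, sigma = 40,
                         farmer_region = function(x, y) rep(TRUE, length(x)),
                         seed = 12)  # starts at K_HG/downscale = K_F/(20*downscale)
  st2 <- run_simulation(st, 400, settle_years = 400)
  target <- 200 * 200 * dem$K_F / dem$downscale
  expect_gt(length(st2$x), 0.6 * target)
  expect_lt(length(st2$x), 1.2 * target)
})

test_that("fixed seeds give bit-identical trajectories", {
  mask <- tiny_strip(300, 50)
  dem <- tiny_demog()
  run <- function() {
    st <- initialize_state(mask, dem, f = 0.002, m = 0.95, sigma = 5, seed = 13)
    run_simulation(st, 60)
  }
  a <- run()
  b <- run()
  expect_identical(a$x, b$x)
  expect_identical(a$genome, b$genome)
  expect_identical(a$history$front_extents, b$history$front_extents)
})

test_that("a fully demic run replaces all ancestry", {
  mask <- tiny_strip(300, 50)
  st <- initialize_state(mask, tiny_demog(), f = 0, m = 1, sigma = 5, seed = 14)
  st2 <- run_simulation(st, 500)
  expect_false(is.na(st2$history$completion_year))
  expect_true(all(genome_ancestry(st2$genome) == 1))
})

test_that("learning leaves a decreasing ancestry cline", {
  mask <- tiny_strip(400, 50)
  st <- initialize_state(mask, tiny_demog(), f = 0.008, m = 1, sigma = 5,
                         seed = 15)
  st2 <- run_simulation(st, 800)
  expect_false(is.na(st2$history$completion_year))
  anc <- mean_ancestry(st2)
  expect_gt(anc, 0)
  expect_lt(anc, 1)
  cl <- ancestry_cline(st2, "square", n_bins = 8)
  ok <- !is.na(cl$mean_ancestry)
  expect_lt(cor(cl$bin_center[ok], cl$mean_ancestry[ok]), -0.5)
})

test_that("hunter-gatherers surrounded by farmers at K_F decline in expectation", {
  dem <- tiny_demog()
  # dense farmer neighbourhood at the (downscaled) farmer carrying capacity,
  # with a few HGs embedded: their pressure is ~20x and death outpaces birth
  set.seed(30)
  n_f <- round(200 * 200 * dem$K_F / dem$downscale)
  st <- cluster_state(n_f + 20, patch_km = 200, demog = dem,
                      culture = c(rep(1L, n_f), rep(0L, 20)),
                      age = sample(12:40, n_f + 20, replace = TRUE))
  probs <- neolexp:::cpp_mortality_probs(
    st$x, st$y, st$age, st$culture,
    neolexp:::mask_for_cpp(st$mask, st$demog), neolexp:::par_for_cpp(st))
  hg <- st$culture == 0
  # central HGs (full disks): yearly death probability far above the
  # balancing birth rate, so the HG population declines deterministically
  central <- hg & st$x > 30 & st$x < 170 & st$y > 30 & st$y < 170
  expect_gt(mean(probs[central]), 3 * dem$fertility)
  expect_gt(mean(probs[central]), 10 * mean(probs[!hg & st$x > 30 &
                                                    st$x < 170 &
                                                    st$y > 30 & st$y < 170]))
})

test_that("headline statistics are insensitive to the yearly event order", {
  dem <- tiny_demog()
  mask <- tiny_strip(500, 50)
  speed_for <- function(ord) {
    st <- initialize_state(mask, dem, f = 0, m = 1, sigma = 5, seed = 31)
    st <- run_simulation(st, 1500, order = ord)
    front_speed(st$history$front_extents)$speed
  }
  v1 <- speed_for(c("move", "learn", "reproduce", "die"))
  v2 <- speed_for(c("reproduce", "move", "learn", "die"))
  expect_lt(abs(v1 - v2), 0.3)
})

test_that("PDE solutions export as a gridded long table", {
  sol <- solve_pde(pde_params(), nx = 100, n_out = 5)
  tab <- as.data.frame(sol)
  expect_equal(nrow(tab), 100 * 5)
  expect_named(tab, c("x", "t_yr", "u", "v", "w"))
  expect_equal(tab$u[tab$t_yr == 0 & tab$x == 0], 1.28)
})

test_that("vertical and horizontal transmission leave equivalent clines", {
  # between-group mating at m = 0.97 (no learning) and learning at
  # f = 0.001/yr (full within-group mating) should both leave decreasing
  # clines with final mean ancestry of the same order
  dem <- tiny_demog()
  mask <- tiny_strip(800, 50)
  run_mode <- function(f, m, seed) {
    st <- initialize_state(mask, dem, f = f, m = m, sigma = 5, seed = seed)
    st <- run_simulation(st, 3000)
    expect_false(is.na(st$history$completion_year))
    st
  }
  vert <- run_mode(0, 0.97, 32)
  horiz <- run_mode(0.001, 1, 33)
  for (st in list(vert, horiz)) {
    cl <- ancestry_cline(st, "square", n_bins = 10)
    ok <- !is.na(cl$mean_ancestry)
    expect_lt(cor(cl$bin_center[ok], cl$mean_ancestry[ok]), 0)
    a <- mean_ancestry(st)
    expect_gt(a, 0)
    expect_lt(a, 1)
  }
  expect_lt(abs(mean_ancestry(vert) - mean_ancestry(horiz)), 0.25)
})

test_that("final ancestry falls as within-group mating weakens", {
  dem <- tiny_demog()
  mask <- tiny_strip(600, 50)
  anc <- vapply(c(1, 0.9, 0.8), function(m) {
    st <- initialize_state(mask, dem, f = 0, m = m, sigma = 5, seed = 34)
    st <- run_simulation(st, 2500)
    mean_ancestry(st)
  }, 1)
  expect_true(all(diff(anc) < 0))
})
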