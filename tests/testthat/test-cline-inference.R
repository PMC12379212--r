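make_table <- function(n = 10, ...) {
  tab <- data.frame(id = paste0("S", seq_len(n)), lat = 45, lon = 20,
                    date_bp = 6000, ef = 0.8, ef_se = 0.015, whg = 0.18,
                    steppe = 0.02, p_value = 0.5)
  args <- list(...)
  for (nm in names(args)) tab[[nm]] <- args[[nm]]
  tab
}

test_that("sample filters apply the published thresholds", {
  tab <- rbind(make_table(1),
               make_table(1, ef_se = 0.03),       # SE filter
               make_table(1, steppe = 0.06),      # Steppe filter
               make_table(1, date_bp = 4500),     # date filter
               make_table(1, p_value = 0.005),    # plausibility filter
               make_table(1, ef = -0.02, whg = 1.02))  # weight filter
  kept <- filter_samples(tab)
  expect_equal(nrow(kept), 1)
  excl <- attr(kept, "exclusions")
  expect_equal(unname(excl["se"]), 1)
  expect_equal(unname(excl["steppe"]), 1)
  expect_equal(unname(excl["date"]), 1)
  expect_equal(unname(excl["p_value"]), 1)
  expect_equal(unname(excl["weights"]), 1)
  expect_error(filter_samples(make_table(2)[, -5]), "missing required")
})

test_that("period boundaries assign 6500 and 5500 to the Middle Neolithic", {
  tab <- make_table(5, date_bp = c(6501, 6500, 6000, 5500, 5499))
  expect_equal(period_subset(tab, "early")$date_bp, 6501)
  expect_equal(period_subset(tab, "middle")$date_bp, c(6500, 6000, 5500))
  expect_equal(period_subset(tab, "late")$date_bp, 5499)
})

test_that("great-circle distances match closed forms", {
  expect_equal(haversine_km(33, 39.9, 33, 39.9), 0)
  # antipodal points: half the circumference of a 6371 km sphere
  expect_equal(haversine_km(0, 0, 180, 0), pi * 6371, tolerance = 0.01)
  # one degree of longitude at 40 N
  expected <- 2 * 6371 * asin(cos(40 * pi / 180) * sin(0.5 * pi / 180))
  expect_equal(haversine_km(33, 40, 34, 40), expected, tolerance = 1e-6)
  expect_equal(expected, 85.2, tolerance = 0.05)
})

test_that("distance_from_origin georeferences and validates", {
  tab <- make_table(2, lon = c(33, 34), lat = c(39.9, 39.9))
  out <- distance_from_origin(tab)
  expect_equal(out$distance_km[1], 0)
  expect_gt(out$distance_km[2], 80)
  expect_error(distance_from_origin(make_table(1, lat = 120)), "out of range")
})

test_that("sample log-likelihood has the Gaussian shape", {
  se <- 0.015
  peak <- sample_loglik(0.8, se, 0.8)
  expect_equal(peak, log(1 / (se * sqrt(2 * pi))), tolerance = 1e-12)
  expect_equal(sample_loglik(0.8 + se, se, 0.8), peak - 0.5, tolerance = 1e-12)
  expect_equal(sample_loglik(0.8, se / 2, 0.8), peak + log(2), tolerance = 1e-12)
  expect_error(sample_loglik(0.8, 0, 0.8), "positive")
})

analytic_clines <- function(slopes, L = 4000) {
  out <- lapply(slopes, function(s) {
    pr <- data.frame(bin_center = seq(25, L, by = 50),
                     mean_ancestry = pmax(0.95 - s * seq(25, L, by = 50), 0))
    pr$n <- 100
    class(pr) <- c("cline_profile", "data.frame")
    pr
  })
  names(out) <- slopes
  out
}

test_that("the profile likelihood peaks at the generating cline", {
  clines <- analytic_clines(c(1e-5, 5e-5, 1e-4, 2e-4))
  samples <- data.frame(distance_km = c(500, 1500, 2500),
                        ef = pmax(0.95 - 5e-5 * c(500, 1500, 2500), 0),
                        ef_se = 0.01)
  prof <- profile_likelihood(samples, clines)
  expect_equal(prof$param[which.max(prof$loglik)], 5e-5)
  # duplicating samples doubles every log-likelihood
  prof2 <- profile_likelihood(rbind(samples, samples), clines)
  expect_equal(prof2$loglik, 2 * prof$loglik, tolerance = 1e-9)
  # permutation invariance
  prof3 <- profile_likelihood(samples[c(3, 1, 2), ], clines)
  expect_equal(prof3$loglik, prof$loglik, tolerance = 1e-12)
})

test_that("quadratic MLE recovers vertex and curvature exactly", {
  grid <- seq(0, 0.002, length.out = 9)
  ll <- -(grid - 0.001)^2 / (2 * 1e-6) + 5
  prof <- data.frame(param = grid, loglik = ll)
  est <- quadratic_mle(prof)
  expect_equal(est$mle, 0.001, tolerance = 1e-12)
  expect_equal(est$se, 1e-3, tolerance = 1e-9)
  expect_equal(est$ci95, 0.001 + c(-1.96, 1.96) * 1e-3, tolerance = 1e-9)
  # symmetric profile peaks at the central grid point
  ll_sym <- -abs(grid - 0.001)^2
  est2 <- quadratic_mle(data.frame(param = grid, loglik = ll_sym))
  expect_equal(est2$mle, 0.001, tolerance = 1e-12)
  # convex profiles have no interior maximum
  expect_error(quadratic_mle(data.frame(param = grid, loglik = grid^2)),
               "no interior maximum")
})

test_that("estimation reuses cached clines", {
  calls <- 0
  cline_fun <- function(v) {
    calls <<- calls + 1
    analytic_clines(v)[[1]]
  }
  samples <- data.frame(distance_km = seq(200, 3000, by = 200))
  samples$ef <- pmax(0.95 - 8e-5 * samples$distance_km, 0) +
    rnorm(nrow(samples), 0, 0.01)
  samples$ef_se <- 0.01
  cache <- withr::local_tempdir()
  grid <- seq(2e-5, 1.6e-4, by = 2e-5)
  est1 <- estimate_transmission_parameter(samples, grid, cline_fun, cache)
  expect_equal(calls, length(grid))
  est2 <- estimate_transmission_parameter(samples, grid, cline_fun, cache)
  expect_equal(calls, length(grid))  # no new simulations
  expect_equal(est2$mle, est1$mle, tolerance = 1e-9)
  expect_lt(abs(est1$mle - 8e-5), 2e-5)
})

test_that("estimates from noisy samples concentrate with sample size", {
  clines <- analytic_clines(seq(2e-5, 1.6e-4, by = 2e-5))
  truth <- 8e-5
  bias_at <- function(n, seed) {
    set.seed(seed)
    d <- runif(n, 100, 3500)
    samples <- data.frame(distance_km = d,
                          ef = pmax(0.95 - truth * d, 0) + rnorm(n, 0, 0.015),
                          ef_se = 0.015)
    quadratic_mle(profile_likelihood(samples, clines))$mle - truth
  }
  err_small <- mean(abs(vapply(1:8, function(s) bias_at(50, s), 1)))
  err_big <- mean(abs(vapply(1:8, function(s) bias_at(600, s + 100), 1)))
  expect_lt(err_big, err_small)
  expect_lt(err_big, 1e-5)
})

test_that("the latitude split partitions samples at 45 degrees", {
  tab <- make_table(3, lat = c(44, 45, 46))
  sp <- split_by_latitude(tab)
  expect_equal(sp$north$lat, 46)
  expect_equal(sort(sp$south$lat), c(44, 45))
})

test_that("robust and OLS cline regressions agree on clean data", {
  set.seed(22)
  n <- 300
  d <- runif(n, 0, 3000)
  tab <- data.frame(distance_km = d, ef = 0.9 - 8e-5 * d + rnorm(n, 0, 0.02))
  rob <- regress_cline(tab)
  ols <- regress_cline(tab, "ols")
  expect_lt(abs(rob$slope - (-8e-5)), 0.15 * 8e-5)
  expect_lt(abs(rob$slope - ols$slope), 0.05 * 8e-5)
  # a gross outlier moves OLS more than the robust fit
  tab2 <- rbind(tab, data.frame(distance_km = 100, ef = -5))
  expect_lt(abs(regress_cline(tab2)$slope - rob$slope),
            abs(regress_cline(tab2, "ols")$slope - ols$slope))
})

test_that("ancestry tables read with header mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- make_table(3)
  names(tab)[names(tab) == "ef"] <- "EF_weight"
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_ancestry_table(path), "missing required")
  out <- read_ancestry_table(path, mapping = list(ef = "EF_weight"))
  expect_true("ef" %in% names(out))
  expect_equal(nrow(out), 3)
})

test_that("the mating-rate estimator sweeps m with learning fixed at zero", {
  # analytic family: lower within-group mating gives steeper clines
  m_cline <- function(m) {
    pr <- data.frame(bin_center = seq(25, 3000, by = 50))
    pr$mean_ancestry <- pmax(0.95 - 3e-4 * (1 - m) * pr$bin_center, 0)
    pr$n <- 50
    class(pr) <- c("cline_profile", "data.frame")
    pr
  }
  truth_m <- 0.9
  set.seed(23)
  d <- runif(400, 100, 2800)
  samples <- data.frame(
    distance_km = d,
    ef = pmax(0.95 - 3e-4 * (1 - truth_m) * d, 0) + rnorm(400, 0, 0.015),
    ef_se = 0.015)
  est <- estimate_mating_rate(samples, m_cline,
                              grid = seq(0.7, 1, length.out = 10))
  expect_lt(abs(est$mle - truth_m), 0.02)
})
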