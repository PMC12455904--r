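test_that("below the Cd K-edge the response is a single full-energy Gaussian", {
  sensor <- sensor_config(noise_floor = 5)
  d <- recorded_energy_distribution(20, sensor)
  expect_equal(nrow(d$components), 1L)
  expect_equal(d$components$mean, 20)
  expect_equal(d$components$weight, 1)
  # above both edges: escape components appear, weights still sum to one
  d30 <- recorded_energy_distribution(35, sensor)
  expect_equal(nrow(d30$components), 3L)
  expect_equal(sum(d30$components$weight), 1)
  expect_true(all(d30$components$mean > 0))
})

test_that("a 750 um CdTe sensor stops nearly all photons up to 50 keV", {
  sensor <- sensor_config(noise_floor = 5)
  expect_gte(interaction_probability(sensor, 50), 0.95)
  # monotone decreasing above the last sensor K-edge (Te, 31.8 keV)
  expect_true(all(diff(interaction_probability(sensor, seq(33, 50, 1))) < 0))
})

test_that("noiseless gains reduce to threshold-interval indicators", {
  sensor <- sensor_config(noise_floor = 5, sigma_e = 0, escape_fraction = 0)
  cfg <- acquisition_config(30, c(12.5, 16, 22), 5)
  grid <- seq(6, 30, 0.25)
  r <- bin_gains(cfg, sensor, grid)
  eta <- interaction_probability(sensor, grid)
  expect_equal(r$gains[1, ], eta * as.numeric(grid >= 12.5 & grid < 16))
  expect_equal(r$gains[2, ], eta * as.numeric(grid >= 16 & grid < 22))
  expect_equal(r$gains[3, ], eta * as.numeric(grid >= 22))
})

test_that("bin gains partition the recorded-energy axis below eta", {
  sensor <- sensor_config(noise_floor = 10)
  cfg <- acquisition_config(40, c(12.5, 18, 26), 10)
  grid <- seq(6, 40, 0.5)
  r <- bin_gains(cfg, sensor, grid)
  eta <- interaction_probability(sensor, grid)
  expect_true(all(colSums(r$gains) <= eta + 1e-12))
  # summed gains equal eta times P(recorded >= E1), from the mixture CDF
  p_ge_e1 <- vapply(grid, function(E) {
    d <- recorded_energy_distribution(E, sensor)
    sum(d$components$weight *
          stats::pnorm((d$components$mean - 12.5) / sensor$sigma_e))
  }, numeric(1))
  expect_equal(colSums(r$gains), eta * p_ge_e1, tolerance = 1e-12)
})

test_that("a well-separated energy lands almost entirely in its own bin", {
  sensor <- sensor_config(noise_floor = 5, sigma_e = 0.2)
  cfg <- acquisition_config(30, c(12.5, 16, 24), 5)
  grid <- seq(6, 30, 0.25)
  r <- bin_gains(cfg, sensor, grid)
  i <- which(grid == 20)   # midway between E2 and E3, 20 sigma from both
  eta <- interaction_probability(sensor, 20)
  expect_equal(r$gains[2, i], eta, tolerance = 1e-6)
  expect_lt(r$gains[1, i], 1e-8)
  expect_lt(r$gains[3, i], 1e-8)
})

test_that("gains match a Monte-Carlo sample of the recorded-energy mixture", {
  sensor <- sensor_config(noise_floor = 5)   # sigma_e = 2.123 keV
  cfg <- acquisition_config(40, c(12.5, 16, 24), 5)
  grid <- c(18, 30)                          # one below, one above the Cd edge
  r <- bin_gains(cfg, sensor, c(10, grid, 40))
  n <- 1e6
  set.seed(42)
  for (E in grid) {
    d <- recorded_energy_distribution(E, sensor)
    comp <- sample.int(nrow(d$components), n, replace = TRUE,
                       prob = d$components$weight)
    rec <- stats::rnorm(n, d$components$mean[comp], d$components$sd[comp])
    th <- c(cfg$thresholds, Inf)
    p_emp <- vapply(1:3, function(i) mean(rec >= th[i] & rec < th[i + 1]), numeric(1))
    i <- which(r$energies == E)
    for (b in 1:3) {
      se <- sqrt(p_emp[b] * (1 - p_emp[b]) / n) + 1e-9
      expect_lt(abs(r$gains[b, i] / d$eta - p_emp[b]), 4 * se)
    }
  }
})

test_that("raising E3 moves weight from bin 3 to bin 2 at every energy", {
  sensor <- sensor_config(noise_floor = 5)
  grid <- seq(6, 40, 0.5)
  r1 <- bin_gains(acquisition_config(40, c(12.5, 16, 22), 5), sensor, grid)
  r2 <- bin_gains(acquisition_config(40, c(12.5, 16, 26), 5), sensor, grid)
  expect_true(all(r2$gains[3, ] <= r1$gains[3, ] + 1e-15))
  expect_true(all(r2$gains[2, ] >= r1$gains[2, ] - 1e-15))
  expect_equal(r1$gains[1, ], r2$gains[1, ])
})

test_that("acquisition configs enforce threshold ordering and the E1 policy", {
  expect_error(acquisition_config(30, c(16, 14, 20), 5), "E1 < E2 < E3")
  expect_error(acquisition_config(20, c(12.5, 16, 21), 5), "E1 < E2 < E3")
  expect_error(acquisition_config(30, c(11, 16, 20), 5), "E1 must be")
  expect_error(acquisition_config(30, c(13, 16, 20), 15), "E1 must be")
  expect_s3_class(acquisition_config(30, c(15, 19, 24), 15), "acquisition_config")
})
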