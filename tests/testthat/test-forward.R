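test_that("zero attenuation recovers the open-beam integral", {
  b <- fx_baseline()
  r <- fx_response()
  bc <- expected_counts(b$spectrum, r, b$attenuation, c(0, 0, 0))
  ref <- vapply(1:3, function(i)
    trapz(b$spectrum$energies, b$spectrum$fluence * r$gains[i, ]) * 0.05^2,
    numeric(1))
  expect_equal(bc$counts, ref, tolerance = 1e-12)
  expect_true(all(bc$transmission == 1))
})

test_that("a narrow-line spectrum matches the closed-form monochromatic counts", {
  toy <- fx_toy()
  a <- c(0, 0.2, 1.0)
  r <- bin_gains(toy$config, toy$sensor, toy$spectrum$energies)
  bc <- expected_counts(toy$spectrum, r, toy$attenuation, a)
  e0 <- 25
  i0 <- which(toy$spectrum$energies == e0)
  mu0 <- c(interpolate_mu(toy$attenuation$strontium, e0),
           interpolate_mu(toy$attenuation$cortical_bone, e0),
           interpolate_mu(toy$attenuation$soft_tissue, e0))
  phi_tot <- trapz(toy$spectrum$energies, toy$spectrum$fluence)
  closed <- phi_tot * r$gains[, i0] * exp(-sum(mu0 * a)) * 0.05^2
  expect_equal(bc$counts, unname(closed), tolerance = 1e-6)
})

test_that("attenuation composes exponentially for a monochromatic beam", {
  toy <- fx_toy()
  r <- bin_gains(toy$config, toy$sensor, toy$spectrum$energies)
  a <- c(0, 0.3, 0.5)
  c1 <- expected_counts(toy$spectrum, r, toy$attenuation, a)$counts
  c2 <- expected_counts(toy$spectrum, r, toy$attenuation, 2 * a)$counts
  c0 <- expected_counts(toy$spectrum, r, toy$attenuation, 0 * a)$counts
  expect_equal(c2 / c0, (c1 / c0)^2, tolerance = 1e-6)
})

test_that("the sensitivity matrix is the effective-spectrum mean of mu", {
  b <- fx_baseline()
  r <- fx_response()
  # constant mu: every entry equals the constant, for every bin
  fa <- flat_attn(grid = b$spectrum$energies)
  M <- sensitivity_matrix(b$spectrum, r, fa, c(0, 0.1, 0.5))
  expect_equal(unname(M), matrix(rep(c(3, 2, 0.5), each = 3), 3), tolerance = 1e-12)
  # monochromatic: M_ij = mu_j(E0) exactly
  toy <- fx_toy()
  rt <- bin_gains(toy$config, toy$sensor, toy$spectrum$energies)
  Mt <- sensitivity_matrix(toy$spectrum, rt, toy$attenuation, c(0, 0.2, 1))
  mu0 <- c(interpolate_mu(toy$attenuation$strontium, 25),
           interpolate_mu(toy$attenuation$cortical_bone, 25),
           interpolate_mu(toy$attenuation$soft_tissue, 25))
  for (i in 1:3) expect_equal(unname(Mt[i, ]), mu0, tolerance = 1e-4)
})

test_that("M respects the min/max mu bounds over each bin's effective support", {
  b <- fx_baseline()
  r <- fx_response()
  abar <- fx_abar()
  M <- sensitivity_matrix(b$spectrum, r, b$attenuation, abar)
  E <- b$spectrum$energies
  mu <- cbind(interpolate_mu(b$attenuation$strontium, E),
              interpolate_mu(b$attenuation$cortical_bone, E),
              interpolate_mu(b$attenuation$soft_tissue, E))
  t0 <- exp(-(mu %*% abar))
  for (i in 1:3) {
    wgt <- b$spectrum$fluence * r$gains[i, ] * as.numeric(t0)
    support <- wgt > 1e-6 * max(wgt)
    for (j in 1:3) {
      expect_gte(M[i, j], min(mu[support, j]))
      expect_lte(M[i, j], max(mu[support, j]))
    }
  }
  expect_true(all(M > 0))
})

test_that("a bin straddling the Sr K-edge sees a larger effective mu_Sr", {
  b <- fx_baseline()
  sensor <- sensor_config(noise_floor = 5, sigma_e = 0, escape_fraction = 0)
  cfg <- acquisition_config(24, c(14.6, 15.6, 16.6), 5, "W/Ag")
  r <- bin_gains(cfg, sensor, b$spectrum$energies)
  M <- sensitivity_matrix(b$spectrum, r, b$attenuation, c(0, 0.1, 0.3))
  # bin 1 (14.6-15.6) lies below the edge; bin 2 (15.6-16.6) straddles it
  expect_gt(M[2, "Sr"], M[1, "Sr"])
})

test_that("the linearized model tracks exact counts for small perturbations", {
  b <- fx_baseline()
  r <- fx_response()
  abar <- fx_abar()
  M <- sensitivity_matrix(b$spectrum, r, b$attenuation, abar)
  c0 <- expected_counts(b$spectrum, r, b$attenuation, abar)$counts
  da <- c(2e-4, 5e-3, 8e-3)
  expect_lt(max(abs(M %*% da)), 0.05)
  exact <- expected_counts(b$spectrum, r, b$attenuation, abar + da)$counts
  linear <- c0 * (1 - as.numeric(M %*% da))
  expect_equal(exact, linear, tolerance = 5e-3)
})

test_that("quadrature is converged at the default grid spacing", {
  kvp <- 24
  lib <- material_library()
  basis <- lib[c("strontium", "cortical_bone", "soft_tissue")]
  counts_at <- function(de) {
    g <- build_energy_grid(kvp, de = de)
    attn <- make_attenuation_set(basis, g)
    sp <- standard_beam("W/Ag", kvp, grid = attr(attn, "energies"), fluence_scale = 1e7)
    sensor <- sensor_config(noise_floor = 5, grid = sp$energies)
    cfg <- acquisition_config(kvp, c(12.5, 15.5, 20.5), 5, "W/Ag")
    expected_counts(sp, bin_gains(cfg, sensor, sp$energies), attn,
                    c(5e-5, 0.7, 0.9))$counts
  }
  expect_equal(counts_at(0.25), counts_at(0.125), tolerance = 1e-3)
})

test_that("count covariance is reciprocal-diagonal and matches Poisson sampling", {
  expect_equal(count_covariance(c(100, 400, 25)),
               diag(c(0.01, 0.0025, 0.04)))
  expect_equal(count_covariance(10 * c(100, 400, 25)),
               count_covariance(c(100, 400, 25)) / 10)
  expect_error(count_covariance(c(0, 1, 2)), "degenerate bin 1")
  c_bar <- c(50, 200, 80)
  x <- sample_counts(c_bar, 1e5, seed = 7)
  dc <- sweep(sweep(x, 2, c_bar, "-"), 2, c_bar, "/")
  emp <- stats::cov(dc)
  for (i in 1:3) {
    se <- (1 / c_bar[i]) * sqrt(2 / 1e5)
    expect_lt(abs(emp[i, i] - 1 / c_bar[i]), 3 * se)
    for (j in setdiff(1:3, i)) {
      se_off <- sqrt(1 / (c_bar[i] * c_bar[j]) / 1e5)
      expect_lt(abs(emp[i, j]), 3 * se_off)
    }
  }
})

test_that("grid mismatch between spectrum and response is rejected", {
  b <- fx_baseline()
  sensor <- sensor_config(noise_floor = 5)
  cfg <- b$config
  r_other <- bin_gains(cfg, sensor, seq(5, 24, 0.5))
  expect_error(expected_counts(b$spectrum, r_other, b$attenuation, c(0, 0, 0)),
               "share one energy grid")
})
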