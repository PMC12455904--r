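test_that("GLS covariance propagates identity and scaling exactly", {
  v <- c(0.02, 0.005, 0.0125)
  expect_equal(gls_covariance(diag(3), diag(v)), diag(v))
  M <- matrix(c(28, 5.7, 1.1, 27, 4.6, 0.94, 21, 3.5, 0.74), 3, byrow = TRUE)
  S1 <- gls_covariance(M, diag(v))
  Sk <- gls_covariance(M, 3 * diag(v))
  expect_equal(Sk, 3 * S1, tolerance = 1e-12)
  expect_equal(S1, t(S1))
  expect_true(all(eigen(S1, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("a rank-deficient sensitivity matrix names the collinear pair", {
  M <- cbind(c(1, 2, 3), c(2, 4, 6), c(1, 0, 1))
  colnames(M) <- c("Sr", "B", "ST")
  expect_error(gls_covariance(M, diag(3)), "Sr and B")
})

test_that("concentration statistics reduce correctly for homogeneous pixels", {
  n <- 5
  map <- tiny_map(a_Sr = rep(3e-5, n), a_B = rep(0.6, n), a_ST = rep(0.9, n),
                  weight = rep(10, n))
  S <- matrix(c(4e-4, 1e-5, 0, 1e-5, 9e-4, 0, 0, 0, 1e-3), 3)
  st <- concentration_stats(map, array(S, dim = c(3, 3, n)))
  r <- 3e-5 / 0.6
  v_pix <- S[1, 1] / 0.6^2 + 3e-5^2 * S[2, 2] / 0.6^4 - 2 * 3e-5 * S[1, 2] / 0.6^3
  expect_equal(st$C_hat, r)
  expect_equal(st$N, 50)
  expect_equal(st$sigma_C2, v_pix / 50)
})

test_that("the blank-sample variance uses the expanded ratio form", {
  n <- 4
  map <- tiny_map(a_Sr = rep(0, n), a_B = c(0.4, 0.5, 0.6, 0.7),
                  a_ST = rep(1, n), weight = rep(1, n))
  S <- diag(c(2e-4, 5e-4, 1e-3))
  st <- concentration_stats(map, array(S, dim = c(3, 3, n)))
  expect_equal(st$C_hat, 0)
  expect_equal(st$sigma_C2, sum(2e-4 / c(0.4, 0.5, 0.6, 0.7)^2) / n^2)
})

test_that("concentration statistics reject degenerate masks", {
  empty <- tiny_map(a_Sr = 0, a_B = 0, a_ST = 1)
  expect_error(concentration_stats(empty, diag(3)), "empty mask")
})

test_that("LOQ and minimum dose follow their defining formulas", {
  expect_equal(loq(10e-6), 100)
  expect_equal(loq(0), 0)
  # halving sigma halves the LOQ (4x dose)
  expect_equal(loq(5e-6), 50)
  # direct evaluation: 100 * 1e-10 / (1e-4)^2 = 1 Gy
  expect_equal(min_dose(1e-10, 100), 1)
  # halving the LOQ target quadruples the dose
  expect_equal(min_dose(1e-10, 50), 4)
  # round trip: if loq(sigma at dose D) = L then min_dose(sigma^2 D, L) = D
  D <- 3.7e-5; sigma <- 2.4e-6
  L <- loq(sigma)
  expect_equal(min_dose(sigma^2 * D, L), D, tolerance = 1e-12)
})

test_that("projected Fisher fractions match hand evaluation on a 2-bin toy", {
  # M rows e1, e2; sigma^2 = (1, 4); a = (1, 2, .)
  M <- rbind(c(1, 0, 0), c(0, 1, 0))
  Sg <- diag(c(1, 4))
  pf <- projected_fisher(M, Sg, c(1, 2, 0.5))
  # grad = (1/2, -1/4, 0); I1 = 0.25, I2 = 0.0625/4
  expect_equal(pf$projected, c(0.25, 0.015625))
  expect_equal(pf$fractions, c(0.25, 0.015625) / 0.265625)
  expect_equal(sum(pf$fractions), 1)
})

test_that("a bin row orthogonal to the concentration gradient contributes nothing", {
  a <- c(2e-5, 0.5, 1)
  M <- rbind(c(10, 3, 1),
             c(a[1] / a[2], 1, 0),   # orthogonal to (1/aB, -aSr/aB^2, 0)
             c(25, 4, 0.8))
  pf <- projected_fisher(M, diag(c(0.01, 0.01, 0.01)), a)
  expect_equal(pf$fractions[2], 0)
  expect_equal(sum(pf$fractions), 1, tolerance = 1e-12)
})

test_that("total projected information equals the quadratic form in the full FIM", {
  b <- fx_baseline()
  r <- fx_response()
  abar <- fx_abar()
  bc <- expected_counts(b$spectrum, r, b$attenuation, abar)
  M <- sensitivity_matrix(b$spectrum, r, b$attenuation, abar)
  Sdc <- count_covariance(bc)
  pf <- projected_fisher(M, Sdc, abar)
  grad <- c(1 / abar[2], -abar[1] / abar[2]^2, 0)
  expect_equal(pf$total,
               as.numeric(t(grad) %*% t(M) %*% solve(Sdc) %*% M %*% grad),
               tolerance = 1e-10)
})

test_that("the GLS decomposition recovers a 500 ppm concentration without bias", {
  b <- fx_baseline()
  r <- fx_response()
  geom <- b$geometry
  ph_b <- b$phantom; ph_b$C_trab <- 0
  ph_s <- b$phantom; ph_s$C_trab <- 500e-6
  a0 <- mean_areal_density(areal_density_map(ph_b, geom))
  a1 <- mean_areal_density(areal_density_map(ph_s, geom))
  scale_up <- 100   # raise counts so the linear regime is well sampled
  c0 <- expected_counts(b$spectrum, r, b$attenuation, a0)$counts * scale_up
  c1 <- expected_counts(b$spectrum, r, b$attenuation, a1)$counts * scale_up
  M <- sensitivity_matrix(b$spectrum, r, b$attenuation, a0)
  Sigma_a <- gls_covariance(M, count_covariance(c0))
  B <- -Sigma_a %*% t(M) %*% diag(c0)          # WLS estimator of delta-a
  reps <- sample_counts(c1, 200, seed = 11)
  dc <- sweep(sweep(reps, 2, c0, "-"), 2, c0, "/")
  da <- dc %*% t(B)
  C_hat <- (a0[1] + da[, 1]) / (a0[2] + da[, 2])
  C_true <- a1[1] / a1[2]
  se <- stats::sd(C_hat) / sqrt(length(C_hat))
  expect_lt(abs(mean(C_hat) - C_true), 2 * se)
})
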