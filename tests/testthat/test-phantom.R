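test_that("central-ray path lengths are the diameter chords", {
  ph <- finger_phantom()
  geom <- projection_geometry()
  pl <- path_lengths(ph, geom, 0, phalanx = 1)
  expect_equal(unname(pl["cortical"]), 2 * (4.5 - 3.0))
  expect_equal(unname(pl["core"]), 2 * 3.0)
  expect_equal(unname(pl["soft_tissue"]), 2 * 3.0)   # 3 mm layer, both sides
  # a ray far outside the soft-tissue envelope misses everything
  far <- path_lengths(ph, geom, 500, phalanx = 1)
  expect_identical(unname(far), c(0, 0, 0))
})

test_that("analytic chords agree with dense numerical ray marching", {
  ph <- finger_phantom()
  geom <- projection_geometry()
  march <- function(fan_index, r) {
    # walk the ray from source to detector; count length inside radius r
    x_d <- fan_index * geom$pitch_mm
    len <- sqrt(geom$sdd_mm^2 + x_d^2)
    t <- seq(0, 1, length.out = 400001)
    px <- t * x_d; py <- t * geom$sdd_mm
    inside <- (px - 0)^2 + (py - geom$sod_mm)^2 < r^2
    sum(inside) / length(t) * len
  }
  for (fi in c(10, 45, 80)) {
    pl <- path_lengths(ph, geom, fi, phalanx = 1)
    expect_equal(unname(pl["core"]), march(fi, 3.0), tolerance = 2e-3)
    expect_equal(unname(pl["core"] + pl["cortical"]), march(fi, 4.5), tolerance = 2e-3)
  }
})

test_that("the areal-density map is symmetric, non-negative and Sr-consistent", {
  map <- fx_map()
  expect_true(all(map$a_Sr >= 0 & map$a_B >= 0 & map$a_ST >= 0))
  expect_true(all(map$a_Sr[map$a_B == 0] == 0))
  for (k in unique(map$phalanx)) {
    m <- map[map$phalanx == k, ]
    rev_idx <- match(-m$fan_index, m$fan_index)
    expect_equal(m$a_B, m$a_B[rev_idx], tolerance = 1e-14)
    expect_equal(m$a_Sr, m$a_Sr[rev_idx], tolerance = 1e-14)
    expect_equal(m$a_ST, m$a_ST[rev_idx], tolerance = 1e-14)
  }
})

test_that("a blank phantom projects zero strontium everywhere", {
  map <- areal_density_map(finger_phantom(C_trab = 0))
  expect_true(all(map$a_Sr == 0))
  # and equals the Sr-free projection of a doped phantom's bone to first order
  map150 <- fx_map()
  expect_equal(map150$a_B, map$a_B, tolerance = 2e-4)
})

test_that("projection conserves total mass within discretization error", {
  ph <- finger_phantom(C_trab = 150e-6)
  geom <- projection_geometry()
  map <- areal_density_map(ph, geom)
  # pixel footprint at the object plane: fan direction is demagnified
  area_cm2 <- (geom$pitch_mm * geom$sod_mm / geom$sdd_mm) * geom$pitch_mm / 100
  d <- ph$densities
  mix_t <- mixture_densities(ph$C_trab, d)
  mix_c <- mixture_densities(ph$C_trab / 4, d)
  vol <- function(r, L) pi * r^2 * L / 1000   # mm^3 -> cm^3
  bone_true <- sr_true <- st_true <- 0
  for (k in 1:3) {
    v_cort <- vol(ph$r_outer_mm[k], ph$lengths_mm[k]) - vol(ph$r_inner_mm[k], ph$lengths_mm[k])
    v_core <- vol(ph$r_inner_mm[k], ph$lengths_mm[k])
    v_soft <- vol(ph$r_outer_mm[k] + 3, ph$lengths_mm[k]) - vol(ph$r_outer_mm[k], ph$lengths_mm[k])
    bone_true <- bone_true + v_cort * mix_c$rho_tilde_B + v_core * 0.2 * mix_t$rho_tilde_B
    sr_true <- sr_true + v_cort * mix_c$rho_tilde_Sr + v_core * 0.2 * mix_t$rho_tilde_Sr
    st_true <- st_true + v_soft * 1.0 + v_core * 0.8 * 1.0
  }
  expect_equal(sum(map$a_B * map$weight) * area_cm2, unname(bone_true), tolerance = 0.01)
  expect_equal(sum(map$a_Sr * map$weight) * area_cm2, unname(sr_true), tolerance = 0.01)
  expect_equal(sum(map$a_ST * map$weight) * area_cm2, unname(st_true), tolerance = 0.01)
})

test_that("doubling the pixel pitch preserves projected mass", {
  ph <- finger_phantom(C_trab = 150e-6)
  g1 <- projection_geometry(pitch_mm = 0.05)
  g2 <- projection_geometry(pitch_mm = 0.10)
  tot <- function(map, g) {
    area <- (g$pitch_mm * g$sod_mm / g$sdd_mm) * g$pitch_mm / 100
    sum(map$a_B * map$weight) * area
  }
  expect_equal(tot(areal_density_map(ph, g1), g1), tot(areal_density_map(ph, g2), g2),
               tolerance = 0.01)
})

test_that("the projected outer diameter is magnified by SDD/SOD", {
  ph <- finger_phantom()
  geom <- projection_geometry()
  map <- areal_density_map(ph, geom)
  m1 <- map[map$phalanx == 1 & map$a_ST > 0, ]
  proj_mm <- (max(m1$fan_index) - min(m1$fan_index) + 1) * geom$pitch_mm
  phys_mm <- 2 * (ph$r_outer_mm[1] + ph$soft_tissue_mm)
  expect_equal(proj_mm, phys_mm * geom$sdd_mm / geom$sod_mm, tolerance = 0.01)
})

test_that("trabecular enrichment raises the Sr/bone ratio on core-dominated rays", {
  map <- fx_map()
  m1 <- map[map$phalanx == 1 & map$mask, ]
  central <- m1[m1$fan_index == 0, ]
  graze_idx <- max(abs(m1$fan_index[m1$a_B > 1e-3])) - 2
  graze <- m1[m1$fan_index == graze_idx, ]   # cortical-graze: little core path
  expect_gt(central$a_Sr / central$a_B, graze$a_Sr / graze$a_B)
  # both ratios lie between the cortical and trabecular concentrations
  C_t <- 150e-6
  for (r in c(central$a_Sr / central$a_B, graze$a_Sr / graze$a_B)) {
    expect_gte(r, C_t / 4)
    expect_lte(r, C_t * 1.001)
  }
})
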