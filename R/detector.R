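#' Acquisition configuration
#'
#' Tube voltage, the three energy-bin thresholds and the electronic noise
#' floor for one acquisition. The lowest threshold E1 must be at least
#' 12 keV for 5 and 10 keV noise floors and at least 15 keV for the 15 keV
#' floor (to stay clear of electronic noise counts and double counting of
#' low-energy photons).
#'
#' @param kvp tube voltage, keV.
#' @param thresholds numeric `c(E1, E2, E3)`, keV, strictly increasing and
#'   below `kvp`.
#' @param noise_floor electronic noise floor, keV (5, 10 or 15).
#' @param anode_filter anode/filter label.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(kvp, thresholds, noise_floor, anode_filter = "W/Ag") {
  if (length(thresholds) != 3L) stop("need exactly three thresholds")
  if (any(diff(thresholds) <= 0) || thresholds[3] >= kvp)
    stop("thresholds must satisfy E1 < E2 < E3 < kvp")
  e1_min <- if (noise_floor <= 10) 12 else 15
  if (thresholds[1] < e1_min)
    stop(sprintf("E1 must be >= %g keV for a %g keV noise floor", e1_min, noise_floor))
  structure(list(kvp = kvp, thresholds = as.numeric(thresholds),
                 noise_floor = noise_floor, anode_filter = anode_filter),
            class = "acquisition_config")
}

#' CdTe sensor configuration
#'
#' A 750 um CdTe sensor with ideal analog charge summing. The energy
#' response per interacting photon is a mixture of a full-energy Gaussian
#' and K-fluorescence escape Gaussians (Cd K-alpha 23.17 keV, Te K-alpha
#' 27.47 keV), each with electronic-noise width sigma_e. The noise floor is
#' interpreted as the Gaussian FWHM, sigma_e = floor / 2.355; `sigma_e` can
#' be overridden directly. The escape fraction applies above the respective
#' K-edge (thin-pixel isotropic-emission approximation).
#'
#' @param noise_floor electronic noise floor, keV.
#' @param sigma_e optional Gaussian energy-noise sigma override, keV.
#' @param thickness_mm sensor thickness, mm.
#' @param density sensor density, g/cm^3.
#' @param escape_fraction total K-fluorescence escape probability above both
#'   edges (split evenly between Cd and Te when both are active).
#' @param grid energy grid on which to evaluate the sensor attenuation
#'   curve (default 5-60 keV).
#' @return object of class `sensor_config`.
#' @export
sensor_config <- function(noise_floor = 5, sigma_e = NULL, thickness_mm = 0.75,
                          density = 5.85, escape_fraction = 0.12,
                          grid = seq(5, 60, 0.25)) {
  if (is.null(sigma_e)) sigma_e <- noise_floor / 2.355
  if (sigma_e < 0) stop("sigma_e must be non-negative")
  structure(list(noise_floor = noise_floor, sigma_e = sigma_e,
                 thickness_mm = thickness_mm, density = density,
                 escape_fraction = escape_fraction,
                 curve = cdte_curve(grid),
                 escape_lines = data.frame(label = c("Cd", "Te"),
                                           fluor_keV = c(23.17, 27.47),
                                           edge_keV = c(26.711, 31.814))),
            class = "sensor_config")
}

#' Sensor interaction probability
#'
#' eta(E) = 1 - exp(-mu_CdTe(E) rho t).
#'
#' @param sensor a [sensor_config()].
#' @param E energies, keV.
#' @return interaction probabilities in (0, 1).
#' @export
interaction_probability <- function(sensor, E) {
  mu <- interpolate_mu(sensor$curve, E)
  1 - exp(-mu * sensor$density * sensor$thickness_mm / 10)
}

#' Recorded-energy distribution for a monoenergetic input
#'
#' Mixture of Gaussian components describing the energy recorded by the
#' (charge-summed) detector for an interacting photon of energy E: the
#' full-energy peak at E and, above each sensor K-edge, an escape peak at
#' E minus the fluorescence energy. Component weights sum to one; the
#' overall interaction probability eta(E) is reported separately.
#'
#' @param E incident photon energy, keV (scalar).
#' @param sensor a [sensor_config()].
#' @return list with `components` (data.frame: mean, sd, weight) and `eta`.
#' @export
recorded_energy_distribution <- function(E, sensor) {
  stopifnot(length(E) == 1L, E > 0)
  active <- sensor$escape_lines$edge_keV < E
  if (!any(active)) {
    comp <- data.frame(mean = E, sd = sensor$sigma_e, weight = 1)
  } else {
    f <- sensor$escape_fraction
    w_esc <- f / sum(active)
    comp <- rbind(
      data.frame(mean = E, sd = sensor$sigma_e, weight = 1 - f),
      data.frame(mean = E - sensor$escape_lines$fluor_keV[active],
                 sd = sensor$sigma_e,
                 weight = rep(w_esc, sum(active)))
    )
  }
  list(components = comp, eta = interaction_probability(sensor, E))
}

# P(recorded energy >= t) for every grid energy, vectorized over a vector of
# thresholds: returns length(t) x length(E) matrix. sigma_e = 0 falls back
# to step functions.
.p_record_ge <- function(E, sensor, t) {
  f <- sensor$escape_fraction
  s <- sensor$sigma_e
  tail_p <- function(mu) {
    # 1 - Phi((t - mu)/s), outer over t x E
    if (s > 0) {
      stats::pnorm(outer(t, mu, function(ti, mi) (mi - ti) / s))
    } else {
      outer(t, mu, function(ti, mi) as.numeric(mi >= ti))
    }
  }
  act1 <- E > sensor$escape_lines$edge_keV[1]
  act2 <- E > sensor$escape_lines$edge_keV[2]
  n_act <- act1 + act2
  w_main <- ifelse(n_act > 0, 1 - f, 1)
  p <- sweep(tail_p(E), 2, w_main, "*")
  w1 <- ifelse(act1, f / pmax(n_act, 1), 0)
  if (any(act1)) p <- p + sweep(tail_p(E - sensor$escape_lines$fluor_keV[1]), 2, w1, "*")
  w2 <- ifelse(act2, f / pmax(n_act, 1), 0)
  if (any(act2)) p <- p + sweep(tail_p(E - sensor$escape_lines$fluor_keV[2]), 2, w2, "*")
  p
}

#' Large-area energy-bin gains
#'
#' G_i(E) = eta(E) x P(recorded energy in \[E_i, E_{i+1})) with E_4 = Inf,
#' for bins i = 1..3, as dimensionless detection probabilities per incident
#' photon (the pixel aperture is applied once in [expected_counts()]).
#' Charge summing is treated as ideal: no lateral charge loss and each
#' interaction counted at most once, so the summed gains never exceed
#' eta(E).
#'
#' @param config an [acquisition_config()].
#' @param sensor a [sensor_config()].
#' @param grid energy grid, keV.
#' @return object of class `bin_response`: list with `energies`, `gains`
#'   (3 x nE matrix), `eta`, `config`.
#' @export
bin_gains <- function(config, sensor, grid) {
  stopifnot(inherits(config, "acquisition_config"), inherits(sensor, "sensor_config"))
  eta <- interaction_probability(sensor, grid)
  pge <- .p_record_ge(grid, sensor, config$thresholds)   # 3 x nE
  gains <- rbind(pge[1, ] - pge[2, ],
                 pge[2, ] - pge[3, ],
                 pge[3, ])
  gains <- sweep(pmax(gains, 0), 2, eta, "*")
  structure(list(energies = grid, gains = gains, eta = eta, config = config),
            class = "bin_response")
}

#' Write a bin response as four-column text (E, G1, G2, G3)
#' @param r a [bin_gains()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bin_response <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: energy_keV G1 G2 G3", con)
  writeLines(sprintf("%.17g %.17g %.17g %.17g",
                     r$energies, r$gains[1, ], r$gains[2, ], r$gains[3, ]), con)
  invisible(path)
}
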