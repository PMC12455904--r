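#' Lowest-threshold policy for a noise floor
#'
#' E1 = 12.5 keV for 5 and 10 keV noise floors, 15.0 keV for the 15 keV
#' floor (on the 0.5 keV threshold grid).
#'
#' @param noise_floor electronic noise floor, keV.
#' @return E1, keV.
#' @export
e1_policy <- function(noise_floor) if (noise_floor <= 10) 12.5 else 15.0

#' Evaluate one acquisition configuration
#'
#' Full-pipeline evaluation of a single (anode/filter, kVp, thresholds,
#' noise floor) node on the mask-averaged representative ray: expected bin
#' counts, sensitivity matrix, GLS covariance, concentration SNR, absorbed
#' dose per unit exposure, and the dose-normalized objective SNR/sqrt(D).
#' This routine goes through the generic [bin_gains()] /
#' [expected_counts()] / [gls_covariance()] path and is deliberately
#' independent of the tabulated fast path used by [grid_search()].
#'
#' @param anode_filter `"W/Ag"`, `"Rh/Rh"` or `"Mo/Mo"`.
#' @param kvp tube voltage, keV.
#' @param thresholds `c(E1, E2, E3)`, keV.
#' @param noise_floor electronic noise floor, keV.
#' @param phantom a [finger_phantom()] carrying the optimization
#'   concentration.
#' @param geom a [projection_geometry()].
#' @param fluence_scale exposure normalization.
#' @param beam,attn,abar optional precomputed beam, attenuation set and mean
#'   areal densities (to amortize setup across nodes sharing a kvp).
#' @return list with `snr`, `dose_Gy`, `objective`, `counts`, `M`,
#'   `Sigma_a`, `C`, `sigma_C2`.
#' @export
evaluate_configuration <- function(anode_filter, kvp, thresholds, noise_floor,
                                   phantom, geom = projection_geometry(),
                                   fluence_scale = 1e7,
                                   beam = NULL, attn = NULL, abar = NULL) {
  if (is.null(beam)) beam <- standard_beam(anode_filter, kvp, fluence_scale = fluence_scale)
  if (is.null(attn)) {
    lib <- material_library()
    attn <- make_attenuation_set(lib[c("strontium", "cortical_bone", "soft_tissue")],
                                 beam$energies)
  }
  if (is.null(abar)) abar <- mean_areal_density(areal_density_map(phantom, geom))
  cfg <- acquisition_config(kvp, thresholds, noise_floor, anode_filter)
  sensor <- sensor_config(noise_floor = noise_floor)
  resp <- bin_gains(cfg, sensor, beam$energies)
  bc <- expected_counts(beam, resp, attn, abar)
  M <- sensitivity_matrix(beam, resp, attn, abar)
  Sigma_a <- gls_covariance(M, count_covariance(bc))
  grad <- c(1 / abar[2], -abar[1] / abar[2]^2, 0)
  sigma_C2 <- as.numeric(t(grad) %*% Sigma_a %*% grad)
  C <- abar[1] / abar[2]
  snr <- C / sqrt(sigma_C2)
  # single-ray first-order dose
  E <- beam$energies
  edep <- trapz(E, beam$fluence * E * (1 - bc$transmission)) * .kev_to_joule
  mass <- sum(abar) / 100 * 1e-3
  D <- edep / mass
  list(snr = snr, dose_Gy = D, objective = snr / sqrt(D), counts = bc$counts,
       M = M, Sigma_a = Sigma_a, C = as.numeric(C), sigma_C2 = sigma_C2)
}

#' Exhaustive acquisition-parameter grid search
#'
#' Enumerates every (kVp, E2, E3) node — tube voltage in 1 kVp steps over
#' `kvp_range`, E1 fixed by the noise-floor policy, E2 from E1+2 keV to
#' kVp-2 keV and E3 from E2+2 keV to kVp-1 keV in 0.5 keV steps — and
#' returns the node maximizing the dose-normalized concentration SNR,
#' SNR/sqrt(D), evaluated on the mask-averaged areal densities of a finger
#' carrying the optimization concentration (default 150 ppm in trabecular
#' bone). Ties resolve to the first node in scan order (lowest kVp, then
#' lowest E2, then lowest E3).
#'
#' @param anode_filter `"W/Ag"`, `"Rh/Rh"` or `"Mo/Mo"`.
#' @param noise_floor electronic noise floor, keV (5, 10 or 15).
#' @param phantom optional [finger_phantom()]; defaults to the standard
#'   finger at `C_opt`. Its `C_trab` is overridden by `C_opt`.
#' @param geom a [projection_geometry()].
#' @param C_opt optimization concentration, mass fraction (150e-6).
#' @param kvp_range integer tube-voltage range, keV.
#' @param threshold_step threshold grid step, keV.
#' @param e2_range,e3_range optional explicit threshold sub-ranges, keV
#'   (intersected with the feasibility constraints).
#' @param fluence_scale exposure normalization (the objective is invariant
#'   to it).
#' @param keep_trace keep the full grid trace (kvp, E2, E3, objective).
#' @return object of class `optimal_config`: the argmax
#'   [acquisition_config()] parameters plus `objective`, `snr`, `dose_Gy`,
#'   `d_per_kair`, and `trace` (data.frame) when requested.
#' @export
grid_search <- function(anode_filter, noise_floor, phantom = NULL,
                        geom = projection_geometry(), C_opt = 150e-6,
                        kvp_range = c(20, 50), threshold_step = 0.5,
                        e2_range = NULL, e3_range = NULL,
                        fluence_scale = 1e7, keep_trace = TRUE) {
  if (!anode_filter %in% c("W/Ag", "Rh/Rh", "Mo/Mo"))
    stop(sprintf("unknown anode/filter combination '%s'", anode_filter))
  if (!noise_floor %in% c(5, 10, 15)) stop("noise floor must be 5, 10 or 15 keV")
  if (is.null(phantom)) phantom <- finger_phantom(C_trab = C_opt)
  else phantom$C_trab <- C_opt
  e1 <- e1_policy(noise_floor)
  sensor <- sensor_config(noise_floor = noise_floor)
  abar <- mean_areal_density(areal_density_map(phantom, geom))
  grad <- c(1 / abar[2], -abar[1] / abar[2]^2, 0)
  C <- abar[1] / abar[2]
  lib <- material_library()
  basis <- lib[c("strontium", "cortical_bone", "soft_tissue")]
  A <- geom$pitch_mm^2
  mag2 <- (geom$sdd_mm / geom$sod_mm)^2

  best <- NULL
  trace <- list()
  for (kvp in seq(kvp_range[1], kvp_range[2], by = 1)) {
    e2s <- seq(e1 + 2, kvp - 2, by = threshold_step)
    if (!is.null(e2_range)) e2s <- e2s[e2s >= e2_range[1] & e2s <= e2_range[2]]
    if (!length(e2s) || e2s[1] + 2 > kvp - 1) next
    beam <- standard_beam(anode_filter, kvp, fluence_scale = fluence_scale)
    E <- beam$energies
    attn <- make_attenuation_set(basis, E)
    mu <- .basis_mu(attn, E)
    t0 <- exp(-as.numeric(mu %*% abar))
    w <- trapz_weights(E)
    eta <- interaction_probability(sensor, E)
    f0 <- w * beam$fluence * t0 * eta
    t_all <- seq(e1, kvp - 1, by = threshold_step)
    pge <- .p_record_ge(E, sensor, t_all)
    S0 <- as.numeric(pge %*% f0)
    Sj <- pge %*% (f0 * mu)                       # nT x 3
    edep <- trapz(E, beam$fluence * E * (1 - t0)) * .kev_to_joule
    D <- edep / (sum(abar) / 100 * 1e-3)
    kair <- air_kerma(beam, fluence_scale = mag2)
    ti <- function(x) match(TRUE, abs(t_all - x) < 1e-9)
    i1 <- ti(e1)
    for (e2 in e2s) {
      i2 <- ti(e2)
      if (e2 + 2 > kvp - 1) next
      e3s <- seq(e2 + 2, kvp - 1, by = threshold_step)
      if (!is.null(e3_range)) e3s <- e3s[e3s >= e3_range[1] & e3s <= e3_range[2]]
      for (e3 in e3s) {
        i3 <- ti(e3)
        d <- c(S0[i1] - S0[i2], S0[i2] - S0[i3], S0[i3])
        if (any(d <= 0)) next
        counts <- A * d
        M <- rbind(Sj[i1, ] - Sj[i2, ], Sj[i2, ] - Sj[i3, ], Sj[i3, ]) / d
        info <- t(M) %*% (counts * M)
        sigma_C2 <- tryCatch(as.numeric(t(grad) %*% solve(info, grad)),
                             error = function(e) NA_real_)
        if (!is.finite(sigma_C2) || sigma_C2 <= 0) next
        obj <- (C / sqrt(sigma_C2)) / sqrt(D)
        if (keep_trace)
          trace[[length(trace) + 1L]] <- c(kvp, e2, e3, obj)
        if (is.null(best) || obj > best$objective) {
          best <- list(kvp = kvp, thresholds = c(e1, e2, e3), objective = obj,
                       snr = C / sqrt(sigma_C2), dose_Gy = D,
                       d_per_kair = dose_per_kerma(D, kair))
        }
      }
    }
  }
  if (is.null(best)) stop("empty feasible grid: no (kvp, E2, E3) node satisfies the constraints")
  tr <- if (keep_trace) {
    tt <- do.call(rbind, trace)
    data.frame(kvp = tt[, 1], E2 = tt[, 2], E3 = tt[, 3], objective = tt[, 4])
  } else NULL
  structure(c(best, list(anode_filter = anode_filter, noise_floor = noise_floor,
                         C_opt = C_opt, trace = tr)),
            class = "optimal_config")
}

#' @export
print.optimal_config <- function(x, ...) {
  cat(sprintf("<optimal_config> %s, %g keV noise floor\n", x$anode_filter, x$noise_floor))
  cat(sprintf("  kVp %g, thresholds %s keV\n", x$kvp,
              paste(format(x$thresholds), collapse = " / ")))
  cat(sprintf("  SNR/sqrt(D) = %.4g, SNR = %.4g, D = %.4g Gy, D/K_air = %.3g uGy/mGy\n",
              x$objective, x$snr, x$dose_Gy, x$d_per_kair))
  invisible(x)
}
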