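#' First-order absorbed dose through the finger
#'
#' Per masked pixel, the deposited energy is the pixel aperture times
#' \eqn{\int \phi_0(E) E (1 - T_0(E))\, dE} (complete local energy
#' deposition for every interacting photon), and the associated mass is the
#' aperture times the summed areal densities along the same ray. The scalar
#' dose is total deposited energy over total mass across the bone mask;
#' zero-mass pixels inside the mask are excluded and counted.
#'
#' @param s an [xray_spectrum()] (fluence incident on the detector).
#' @param map an [areal_density_map()].
#' @param attn attenuation set.
#' @param pixel_area_mm2 pixel aperture, mm^2.
#' @return object of class `dose_report`: list with `D_Gy`, `edep_J`,
#'   `mass_kg`, `n_excluded`, and per-pixel vectors `pixel_edep_J`,
#'   `pixel_mass_kg` (masked profile order, cone multiplicity in `weight`).
#' @export
absorbed_dose <- function(s, map, attn, pixel_area_mm2 = 0.05^2) {
  m <- map[map$mask, , drop = FALSE]
  E <- s$energies
  mu <- .basis_mu(attn, E)
  w <- trapz_weights(E)
  amat <- rbind(m$a_Sr, m$a_B, m$a_ST)
  tmat <- exp(-mu %*% amat)
  # J per pixel: aperture [mm^2] x integral of phi [mm^-2 keV^-1] E [keV] (1-T)
  edep <- pixel_area_mm2 * as.numeric((w * s$fluence * E) %*% (1 - tmat)) * .kev_to_joule
  a_tot <- m$a_Sr + m$a_B + m$a_ST                 # g/cm^2
  mass <- a_tot * pixel_area_mm2 / 100 * 1e-3      # kg (mm^2 -> cm^2, g -> kg)
  ok <- mass > 0
  if (!any(ok)) stop("no pixel in the mask carries mass")
  D <- sum(m$weight[ok] * edep[ok]) / sum(m$weight[ok] * mass[ok])
  structure(list(D_Gy = D,
                 edep_J = sum(m$weight[ok] * edep[ok]),
                 mass_kg = sum(m$weight[ok] * mass[ok]),
                 n_excluded = sum(!ok),
                 pixel_edep_J = edep, pixel_mass_kg = mass),
            class = "dose_report")
}

#' Air kerma of a spectrum
#'
#' \eqn{K_{air} = \int \phi(E)\, E\, (\mu_{en}/\rho)_{air}(E)\, dE} with
#' unit conversion to Gy. `fluence_scale` rescales the spectrum fluence to
#' the measurement plane (e.g. `(SDD/SOD)^2` for free-in-air kerma at the
#' object plane when the spectrum is specified at the detector).
#'
#' @param s an [xray_spectrum()].
#' @param air_curve air mass energy-absorption curve
#'   (default [air_energy_absorption_curve()] on the spectrum grid).
#' @param fluence_scale multiplicative fluence rescaling.
#' @return air kerma, Gy.
#' @export
air_kerma <- function(s, air_curve = NULL, fluence_scale = 1) {
  E <- s$energies
  if (is.null(air_curve)) air_curve <- air_energy_absorption_curve(E)
  if (min(air_curve$energies) > min(E) || max(air_curve$energies) < max(E))
    stop("air energy-absorption curve does not span the spectrum")
  mu_en <- interpolate_mu(air_curve, E)
  # phi [mm^-2 keV^-1] -> cm^-2: x100; mu_en [cm^2/g]; J/g -> J/kg: x1000
  trapz(E, s$fluence * fluence_scale * 100 * E * .kev_to_joule * mu_en * 1000)
}

#' Dose per unit air kerma
#'
#' Absorbed finger dose (uGy) per unit free-in-air kerma (mGy) at the
#' object plane, the exposure-normalized dosimetric figure of merit.
#'
#' @param D_Gy absorbed dose, Gy.
#' @param K_Gy air kerma, Gy.
#' @return D/K_air in uGy per mGy.
#' @export
dose_per_kerma <- function(D_Gy, K_Gy) (D_Gy * 1e6) / (K_Gy * 1e3)
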