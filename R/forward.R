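#' Expected energy-bin counts through an absorber
#'
#' Numerical quadrature of the forward count model
#' \deqn{c_i = A \int \phi_0(E)\, G_i(E)\, e^{-\mu_{Sr} a_{Sr} - \mu_B a_B -
#'   \mu_{ST} a_{ST}}\, dE}
#' on the shared spectrum/response grid (trapezoidal, with K-edge
#' breakpoints already present in the grid). The pixel aperture A (mm^2) is
#' applied here; gains are dimensionless probabilities.
#'
#' @param s an [xray_spectrum()].
#' @param r a [bin_gains()] response on the same grid.
#' @param attn attenuation set (named list with `strontium`,
#'   `cortical_bone`, `soft_tissue` curves).
#' @param a areal densities `c(a_Sr, a_B, a_ST)`, g/cm^2, non-negative.
#' @param pixel_area_mm2 pixel aperture, mm^2 (default 0.05 mm pitch squared).
#' @return object of class `bin_counts`: list with `counts` (3-vector),
#'   `transmission` (per grid energy), `energies`.
#' @export
expected_counts <- function(s, r, attn, a, pixel_area_mm2 = 0.05^2) {
  if (length(s$energies) != length(r$energies) ||
      any(abs(s$energies - r$energies) > 1e-9))
    stop("spectrum and bin response must share one energy grid")
  if (any(a < 0)) stop("areal densities must be non-negative")
  E <- s$energies
  mu <- .basis_mu(attn, E)
  transmission <- exp(-(mu[, 1] * a[1] + mu[, 2] * a[2] + mu[, 3] * a[3]))
  w <- trapz_weights(E)
  counts <- as.numeric(r$gains %*% (w * s$fluence * transmission)) * pixel_area_mm2
  structure(list(counts = counts, transmission = transmission, energies = E),
            class = "bin_counts")
}

# nE x 3 matrix of basis-material attenuation coefficients (Sr, B, ST)
.basis_mu <- function(attn, E) {
  cbind(interpolate_mu(attn$strontium, E),
        interpolate_mu(attn$cortical_bone, E),
        interpolate_mu(attn$soft_tissue, E))
}

#' Effective-attenuation sensitivity matrix
#'
#' The linearized forward model expresses normalized count perturbations as
#' -M times areal-density perturbations, where
#' \deqn{M_{ij} = \frac{\int \phi_0 G_i T_0\, \mu_j\, dE}
#'                     {\int \phi_0 G_i T_0\, dE}}
#' is the fluence-weighted mean attenuation coefficient of basis material j
#' over the transmitted effective spectrum of bin i.
#'
#' @param s an [xray_spectrum()].
#' @param r a [bin_gains()] response on the same grid.
#' @param attn attenuation set (see [expected_counts()]).
#' @param background_a background areal densities `c(a_Sr, a_B, a_ST)`,
#'   g/cm^2 (the linearization point).
#' @return 3 x 3 matrix (rows: bins; columns: Sr, B, ST), cm^2/g.
#' @export
sensitivity_matrix <- function(s, r, attn, background_a) {
  if (length(s$energies) != length(r$energies) ||
      any(abs(s$energies - r$energies) > 1e-9))
    stop("spectrum and bin response must share one energy grid")
  E <- s$energies
  mu <- .basis_mu(attn, E)
  t0 <- exp(-(mu[, 1] * background_a[1] + mu[, 2] * background_a[2] +
                mu[, 3] * background_a[3]))
  w <- trapz_weights(E)
  base <- w * s$fluence * t0
  den <- as.numeric(r$gains %*% base)
  if (any(den <= 0) || any(!is.finite(den)))
    stop(sprintf("degenerate bin %s: zero effective fluence",
                 paste(which(den <= 0 | !is.finite(den)), collapse = ", ")))
  M <- (r$gains %*% (base * mu)) / den
  dimnames(M) <- list(paste0("bin", 1:3), c("Sr", "B", "ST"))
  M
}

#' Covariance of normalized count perturbations
#'
#' Under Poisson counting with analog charge summing, normalized bin counts
#' (c_i - c_i0)/c_i0 are uncorrelated across bins with variance 1/c_i.
#'
#' @param c a [expected_counts()] result or a positive 3-vector of counts.
#' @return 3 x 3 diagonal covariance matrix.
#' @export
count_covariance <- function(c) {
  counts <- if (inherits(c, "bin_counts")) c$counts else as.numeric(c)
  if (any(counts <= 0))
    stop(sprintf("degenerate bin %s: zero expected count",
                 paste(which(counts <= 0), collapse = ", ")))
  diag(1 / counts)
}
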