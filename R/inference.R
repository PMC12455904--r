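#' GLS covariance of areal-density estimates
#'
#' Covariance of the unbiased generalized least-squares estimate of the
#' areal-density perturbation vector:
#' \deqn{\Sigma_a = (M^T \Sigma_{\Delta c}^{-1} M)^{-1}.}
#'
#' @param M 3 x 3 sensitivity matrix (rows: bins; columns: Sr, B, ST).
#' @param Sigma_dc covariance of normalized count perturbations
#'   (positive definite).
#' @return symmetric positive semi-definite 3 x 3 matrix, (g/cm^2)^2.
#' @export
gls_covariance <- function(M, Sigma_dc) {
  info <- t(M) %*% solve(Sigma_dc, M)
  out <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    # name the most collinear material pair for the error message
    W <- chol(solve(Sigma_dc))
    cols <- W %*% M
    cn <- sweep(cols, 2, sqrt(colSums(cols^2)), "/")
    cc <- abs(crossprod(cn)); diag(cc) <- 0
    idx <- sort(which(cc == max(cc), arr.ind = TRUE)[1, ])
    mats <- colnames(M)
    if (is.null(mats)) mats <- c("Sr", "B", "ST")
    stop(sprintf("sensitivity matrix is rank deficient: materials %s and %s are near-collinear",
                 mats[idx[1]], mats[idx[2]]))
  }
  (out + t(out)) / 2
}

#' Pixel-averaged concentration estimate and its variance
#'
#' The strontium-to-bone concentration averaged over the bone mask,
#' \eqn{C = (1/N) \sum_n a_{Sr,n}/a_{B,n}}, and its delta-method variance
#' \deqn{\sigma_C^2 = \frac{1}{N^2} \sum_n \left[
#'   \frac{\sigma_{Sr,n}^2}{a_{B,n}^2}
#'   + \frac{a_{Sr,n}^2 \sigma_{B,n}^2}{a_{B,n}^4}
#'   - \frac{2 a_{Sr,n} \sigma_{SrB,n}^2}{a_{B,n}^3} \right],}
#' the algebraically expanded ratio-variance form (well defined at
#' a_Sr = 0, the blank case). Pixels are independent (analog charge
#' summing); estimates of a_Sr and a_B within a pixel are correlated via
#' the per-pixel covariance.
#'
#' @param map an [areal_density_map()].
#' @param Sigma_a per-pixel 3x3 covariance array (3 x 3 x n_masked, in
#'   masked-row order) from [pixel_precision()], or a single 3 x 3 matrix
#'   reused for every pixel (fast approximation).
#' @return list with `C_hat`, `sigma_C2`, `N` (masked pixel count including
#'   cone multiplicity).
#' @export
concentration_stats <- function(map, Sigma_a) {
  m <- map[map$mask, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty mask: no rays traverse bone")
  if (any(m$a_B <= 0)) stop("masked pixel with non-positive bone areal density")
  n_prof <- nrow(m)
  if (is.matrix(Sigma_a)) Sigma_a <- array(Sigma_a, dim = c(3, 3, n_prof))
  if (dim(Sigma_a)[3] != n_prof)
    stop("Sigma_a must supply one covariance per masked profile pixel")
  v_sr <- Sigma_a[1, 1, ]
  v_b <- Sigma_a[2, 2, ]
  v_srb <- Sigma_a[1, 2, ]
  r <- m$a_Sr / m$a_B
  v <- v_sr / m$a_B^2 + m$a_Sr^2 * v_b / m$a_B^4 - 2 * m$a_Sr * v_srb / m$a_B^3
  N <- sum(m$weight)
  list(C_hat = sum(m$weight * r) / N,
       sigma_C2 = sum(m$weight * v) / N^2,
       N = N)
}

#' Per-pixel GLS precision over the areal-density map
#'
#' For every masked profile pixel, computes expected bin counts through that
#' pixel's background, the local sensitivity matrix, and the per-pixel GLS
#' covariance (counts, and hence variances, vary across the finger).
#'
#' @param s an [xray_spectrum()].
#' @param r a [bin_gains()] response on the same grid.
#' @param attn attenuation set.
#' @param map an [areal_density_map()] (its own densities serve as the local
#'   background / linearization point).
#' @param pixel_area_mm2 pixel aperture, mm^2.
#' @return list with `Sigma_a` (3 x 3 x n_masked array), `counts`
#'   (n_masked x 3), `M` (3 x 3 x n_masked).
#' @export
pixel_precision <- function(s, r, attn, map, pixel_area_mm2 = 0.05^2) {
  m <- map[map$mask, , drop = FALSE]
  E <- s$energies
  mu <- .basis_mu(attn, E)                       # nE x 3
  w <- trapz_weights(E)
  amat <- rbind(m$a_Sr, m$a_B, m$a_ST)           # 3 x n
  tmat <- exp(-mu %*% amat)                      # nE x n
  base <- tmat * (w * s$fluence)                 # nE x n
  den <- r$gains %*% base                        # 3 x n (per unit pixel area)
  counts <- t(den) * pixel_area_mm2
  num <- array(NA_real_, dim = c(3, 3, nrow(m)))
  for (j in 1:3) num[, j, ] <- r$gains %*% (base * mu[, j])
  Sigma_a <- array(NA_real_, dim = c(3, 3, nrow(m)))
  Mout <- array(NA_real_, dim = c(3, 3, nrow(m)))
  for (k in seq_len(nrow(m))) {
    if (any(den[, k] <= 0))
      stop(sprintf("degenerate bin at profile pixel %d: zero effective fluence", k))
    M <- num[, , k] / den[, k]
    Mout[, , k] <- M
    Sigma_a[, , k] <- gls_covariance(M, diag(1 / counts[k, ]))
  }
  list(Sigma_a = Sigma_a, counts = counts, M = Mout)
}

#' Limit of quantification
#'
#' LOQ = 10 x standard deviation of the blank-sample concentration
#' estimate, reported in ppm (mass fraction x 1e6).
#'
#' @param sigma_Cb standard deviation of the blank concentration estimate
#'   (mass fraction, dimensionless).
#' @return LOQ in ppm.
#' @export
loq <- function(sigma_Cb) {
  if (any(sigma_Cb < 0)) stop("sigma_Cb must be non-negative")
  10 * sigma_Cb * 1e6
}

#' Minimum dose to reach a target LOQ
#'
#' With the dose-independent blank variance
#' \eqn{\tilde\sigma^2_{Cb} = \sigma^2_{Cb} D_b} (Gy), the absorbed dose
#' needed to reach a target LOQ is
#' \deqn{D_{min} = 100\, \tilde\sigma^2_{Cb} / LOQ^2.}
#'
#' @param sigma_Cb2_tilde dose-scaled blank variance, (mass fraction)^2 Gy.
#' @param loq_target_ppm target LOQ, ppm.
#' @return minimum absorbed dose, Gy.
#' @export
min_dose <- function(sigma_Cb2_tilde, loq_target_ppm) {
  if (any(loq_target_ppm <= 0)) stop("LOQ target must be positive")
  100 * sigma_Cb2_tilde / (loq_target_ppm * 1e-6)^2
}

#' Per-bin projected Fisher information for the concentration
#'
#' Each bin contributes a rank-one Fisher matrix
#' \eqn{I_i = M_i^T M_i / \sigma_i^2} with \eqn{\sigma_i^2 = 1/\bar c_i};
#' projecting onto the gradient of C = a_Sr/a_B,
#' \eqn{\nabla C = (1/a_B, -a_{Sr}/a_B^2, 0)^T}, gives the scalar
#' information each bin carries about the concentration. Contributions are
#' normalized to fractions; their sum equals
#' \eqn{\nabla C^T (M^T \Sigma_{\Delta c}^{-1} M) \nabla C}.
#'
#' @param M sensitivity matrix (bins x 3 materials).
#' @param Sigma_dc diagonal covariance of normalized count perturbations.
#' @param a areal densities `c(a_Sr, a_B, a_ST)` with a_B > 0.
#' @return list with `fractions` (per bin, summing to 1), `projected`
#'   (per-bin scalar information), `total`.
#' @export
projected_fisher <- function(M, Sigma_dc, a) {
  if (a[2] <= 0) stop("bone areal density must be positive")
  grad <- c(1 / a[2], -a[1] / a[2]^2, 0)
  proj <- as.numeric(M %*% grad)^2 / diag(Sigma_dc)
  total <- sum(proj)
  if (total <= 0) stop("degenerate geometry: all bins carry zero projected information")
  list(fractions = proj / total, projected = proj, total = total)
}
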