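# Shared numerical helpers.

#' Trapezoidal quadrature
#' @param x strictly increasing abscissae.
#' @param y ordinates.
#' @return the trapezoidal integral.
#' @export
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Per-node trapezoidal weights so that sum(w * y) == trapz(x, y).
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

# keV -> joule
.kev_to_joule <- 1.602176634e-16
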