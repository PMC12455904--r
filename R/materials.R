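#' Mass-attenuation curve
#'
#' Container for a tabulated mass-attenuation coefficient curve
#' \eqn{\mu/\rho}(E) (cm\eqn{^2}/g) on a strictly increasing keV grid,
#' optionally carrying K-edge energies. Edges are represented as one-sided
#' grid breakpoints (a pair of nodes an infinitesimal step below and above
#' the edge energy), so interpolation never smears the discontinuity.
#'
#' @param material_id character label for the material.
#' @param energies numeric vector, keV, strictly increasing.
#' @param mu numeric vector of mass attenuation coefficients, cm^2/g,
#'   positive, same length as `energies`.
#' @param edges numeric vector of K-edge energies (keV) lying inside the
#'   grid span; may be empty.
#' @return An object of class `attenuation_curve`.
#' @export
attenuation_curve <- function(material_id, energies, mu, edges = numeric(0)) {
  if (!is.numeric(energies) || !is.numeric(mu) || length(energies) != length(mu))
    stop("energies and mu must be numeric vectors of equal length")
  if (length(energies) < 2L) stop("attenuation curve needs at least two nodes")
  if (any(diff(energies) <= 0)) stop("energies must be strictly increasing")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive and finite everywhere")
  edges <- sort(as.numeric(edges))
  if (length(edges) && (any(edges <= min(energies)) || any(edges >= max(energies))))
    stop("declared K-edge outside the energy grid span")
  structure(
    list(material_id = as.character(material_id),
         energies = as.numeric(energies),
         mu = as.numeric(mu),
         edges = edges),
    class = "attenuation_curve"
  )
}

#' @export
print.attenuation_curve <- function(x, ...) {
  cat(sprintf("<attenuation_curve> %s: %d nodes, %.3f-%.3f keV",
              x$material_id, length(x$energies), min(x$energies), max(x$energies)))
  if (length(x$edges)) cat(sprintf(", K-edge(s) at %s keV", paste(format(x$edges), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Interpolate a mass-attenuation curve
#'
#' Log-log linear interpolation between tabulated nodes. Because K-edges are
#' stored as one-sided breakpoints, interpolation is never carried across a
#' discontinuity. Queries exactly at a node return the tabulated value.
#'
#' @param curve an [attenuation_curve()].
#' @param E numeric vector of query energies (keV) inside the grid span.
#' @return numeric vector of mass attenuation coefficients (cm^2/g).
#' @export
interpolate_mu <- function(curve, E) {
  stopifnot(inherits(curve, "attenuation_curve"))
  x <- curve$energies
  if (any(E < x[1L]) || any(E > x[length(x)]))
    stop(sprintf("energy outside the span of curve '%s' (%.4f-%.4f keV)",
                 curve$material_id, x[1L], x[length(x)]))
  i <- findInterval(E, x, all.inside = TRUE)
  x0 <- x[i]; x1 <- x[i + 1L]
  y0 <- curve$mu[i]; y1 <- curve$mu[i + 1L]
  f <- (log(E) - log(x0)) / (log(x1) - log(x0))
  out <- exp((1 - f) * log(y0) + f * log(y1))
  # exact at nodes (guards against 0/0 on degenerate spacing near breakpoints)
  at0 <- E == x0
  out[at0] <- y0[at0]
  at1 <- E == x1
  out[at1] <- y1[at1]
  out
}

#' Bulk material densities and trabecular porosity
#'
#' Pure-material mass densities used by the finger model: strontium
#' 2.64 g/cm^3, cortical bone 1.65 g/cm^3, soft tissue modeled as water at
#' 1.0 g/cm^3, and the trabecular-core porosity (volume fraction occupied by
#' marrow/soft tissue, default 0.8).
#'
#' @param rho_Sr,rho_B,rho_ST mass densities, g/cm^3.
#' @param porosity trabecular porosity, in \[0, 1\].
#' @return An object of class `material_densities`.
#' @export
material_densities <- function(rho_Sr = 2.64, rho_B = 1.65, rho_ST = 1.0,
                               porosity = 0.8) {
  if (any(c(rho_Sr, rho_B, rho_ST) <= 0)) stop("densities must be positive")
  if (porosity < 0 || porosity > 1) stop("porosity must lie in [0, 1]")
  structure(list(rho_Sr = rho_Sr, rho_B = rho_B, rho_ST = rho_ST,
                 porosity = porosity),
            class = "material_densities")
}

#' Strontium/bone two-component mixture densities
#'
#' For a strontium mass fraction C in bone, the partial densities of
#' strontium and bone in the ideal (volume-additive) mixture are
#' \deqn{\tilde\rho_{Sr} = C\,[C/\rho_{Sr} + (1-C)/\rho_B]^{-1}, \qquad
#'       \tilde\rho_B = (1-C)\,[C/\rho_{Sr} + (1-C)/\rho_B]^{-1}.}
#' Their sum is the density of the ideal two-component mixture and their
#' ratio is C/(1-C).
#'
#' @param C strontium mass fraction, in \[0, 1).
#' @param densities a [material_densities()] object.
#' @return list with `rho_tilde_Sr`, `rho_tilde_B` (g/cm^3) and
#'   `concentration_C`, of class `mixture_densities`.
#' @export
mixture_densities <- function(C, densities = material_densities()) {
  stopifnot(inherits(densities, "material_densities"))
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C < 0 || C >= 1)
    stop("concentration C must lie in [0, 1)")
  inv <- 1 / (C / densities$rho_Sr + (1 - C) / densities$rho_B)
  structure(list(rho_tilde_Sr = C * inv,
                 rho_tilde_B = (1 - C) * inv,
                 concentration_C = C),
            class = "mixture_densities")
}

#' Effective densities of the trabecular core
#'
#' The trabecular core is a homogeneous mixture of bone and marrow-like soft
#' tissue with porosity p: the effective trabecular-bone density is
#' (1-p) rho_B and the effective core soft-tissue density is p times the
#' soft-tissue (water) density.
#'
#' @param densities a [material_densities()] object.
#' @return named numeric vector `c(trabecular_bone=, core_soft_tissue=)`, g/cm^3.
#' @export
effective_core_densities <- function(densities = material_densities()) {
  stopifnot(inherits(densities, "material_densities"))
  p <- densities$porosity
  c(trabecular_bone = (1 - p) * densities$rho_B,
    core_soft_tissue = p * densities$rho_ST)
}

#' Read an attenuation table from two-column text
#'
#' Format: comment header lines starting with `#` carrying
#' `# material: <id>` and optionally `# edges: <e1> <e2> ...`, followed by
#' whitespace-separated `energy_keV  mu_cm2_per_g` rows.
#'
#' @param path file path.
#' @return an [attenuation_curve()].
#' @export
read_attenuation <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  material_id <- sub(".*material:\\s*", "", grep("material:", hdr, value = TRUE)[1])
  if (is.na(material_id)) material_id <- "unknown"
  edge_line <- grep("edges:", hdr, value = TRUE)
  edges <- if (length(edge_line))
    as.numeric(strsplit(trimws(sub(".*edges:\\s*", "", edge_line[1])), "\\s+")[[1]])
  else numeric(0)
  edges <- edges[!is.na(edges)]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body, col.names = c("energy", "mu"))
  attenuation_curve(material_id, tab$energy, tab$mu, edges)
}

#' Write an attenuation table as two-column text
#'
#' @param curve an [attenuation_curve()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_attenuation <- function(curve, path) {
  stopifnot(inherits(curve, "attenuation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# material: %s", curve$material_id), con)
  if (length(curve$edges))
    writeLines(sprintf("# edges: %s", paste(sprintf("%.17g", curve$edges), collapse = " ")), con)
  writeLines("# columns: energy_keV mu_cm2_per_g", con)
  writeLines(sprintf("%.17g %.17g", curve$energies, curve$mu), con)
  invisible(path)
}
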