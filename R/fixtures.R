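#' Parametric material model
#'
#' A compact analytic stand-in for tabulated cross-section data: the mass
#' attenuation coefficient is modeled as a photoelectric power law plus a
#' flat Compton term,
#' \deqn{\mu(E) = c + k\,(E/10\,\mathrm{keV})^{-p} \times J^{1[E \ge E_K]},}
#' where the jump factor J > 1 multiplies the photoelectric component above
#' the K-edge. Constants are anchored to standard tabulations at a few
#' energies; the curves are qualitatively faithful (power-law slope, edge
#' position and jump, Compton plateau) rather than reference-accurate.
#'
#' @param label material name.
#' @param k photoelectric amplitude at 10 keV (below-edge), cm^2/g.
#' @param p photoelectric exponent (about 3).
#' @param compton flat Compton contribution, cm^2/g.
#' @param edge optional K-edge energy, keV.
#' @param jump photoelectric jump ratio at the edge (> 1); required with `edge`.
#' @param density bulk density, g/cm^3.
#' @return object of class `parametric_material`.
#' @export
parametric_material <- function(label, k, p, compton, edge = NULL, jump = NULL,
                                density = NA_real_) {
  if (k <= 0 || p <= 0 || compton < 0) stop("invalid parametric coefficients")
  if (!is.null(edge) && (is.null(jump) || jump <= 1)) stop("edge requires jump ratio > 1")
  structure(list(label = label, k = k, p = p, compton = compton,
                 edge = edge, jump = jump, density = density),
            class = "parametric_material")
}

#' Evaluate a parametric material's attenuation coefficient
#' @param mat a [parametric_material()].
#' @param E energies, keV.
#' @return mu, cm^2/g.
#' @export
parametric_mu <- function(mat, E) {
  stopifnot(inherits(mat, "parametric_material"))
  pe <- mat$k * (E / 10)^(-mat$p)
  if (!is.null(mat$edge)) pe <- pe * ifelse(E >= mat$edge, mat$jump, 1)
  mat$compton + pe
}

# Parametric constants anchored to standard attenuation tabulations
# (approximate values at 10-50 keV; see the methods vignette).
.parametric_library <- function() {
  list(
    strontium     = parametric_material("strontium",     25.7, 2.80, 0.16, edge = 16.105, jump = 6.2, density = 2.64),
    cortical_bone = parametric_material("cortical_bone", 28.3, 2.95, 0.17, density = 1.65),
    soft_tissue   = parametric_material("soft_tissue",    5.1, 3.05, 0.18, density = 1.00),
    cadmium       = parametric_material("cadmium",       120.0, 2.90, 0.15, edge = 26.711, jump = 6.0, density = 8.65),
    tellurium     = parametric_material("tellurium",     150.0, 2.90, 0.15, edge = 31.814, jump = 5.5, density = 6.24),
    silver        = parametric_material("silver",        115.0, 2.90, 0.15, edge = 25.514, jump = 5.8, density = 10.49),
    rhodium       = parametric_material("rhodium",        95.0, 2.90, 0.16, edge = 23.220, jump = 5.7, density = 12.41),
    molybdenum    = parametric_material("molybdenum",     80.0, 2.90, 0.16, edge = 20.000, jump = 5.6, density = 10.22)
  )
}

#' Parametric material registry
#'
#' Named list of the built-in [parametric_material()] definitions used by the
#' fixtures: strontium (K-edge 16.105 keV), cortical bone, soft tissue
#' (water), cadmium, tellurium, silver, rhodium and molybdenum.
#'
#' @return named list of `parametric_material` objects.
#' @export
material_library <- function() .parametric_library()

#' K-edge energies of all registry materials
#' @return sorted numeric vector of edge energies, keV.
#' @export
registry_edges <- function() {
  e <- unlist(lapply(.parametric_library(), function(m) m$edge))
  sort(unique(as.numeric(e)))
}

#' Evaluate a parametric material onto a grid as an attenuation curve
#'
#' The grid is augmented with one-sided breakpoints straddling the
#' material's K-edge (if it lies inside the span), so the discontinuity is
#' preserved by [interpolate_mu()].
#'
#' @param mat a [parametric_material()].
#' @param grid energy grid, keV.
#' @return an [attenuation_curve()].
#' @export
parametric_curve <- function(mat, grid) {
  grid <- insert_edge_breakpoints(grid, if (is.null(mat$edge)) numeric(0) else mat$edge)
  edges <- if (!is.null(mat$edge) && mat$edge > min(grid) && mat$edge < max(grid))
    mat$edge else numeric(0)
  attenuation_curve(mat$label, grid, parametric_mu(mat, grid), edges)
}

# Insert E-delta / E+delta node pairs at each in-span edge so that tabulated
# curves carry one-sided edge values. delta = 5e-7 keV.
insert_edge_breakpoints <- function(grid, edges, delta = 5e-7) {
  for (e in edges) {
    if (e > min(grid) && e < max(grid)) {
      grid <- grid[abs(grid - e) > delta / 2]
      grid <- c(grid, e - delta, e + delta)
    }
  }
  sort(unique(grid))
}

#' CdTe sensor attenuation curve
#'
#' Mass-weighted sum of the cadmium and tellurium parametric curves
#' (mass fractions 0.468 / 0.532), carrying both K-edges in span.
#'
#' @param grid energy grid, keV.
#' @return an [attenuation_curve()] labeled `"CdTe"`.
#' @export
cdte_curve <- function(grid) {
  lib <- .parametric_library()
  w_cd <- 112.41 / (112.41 + 127.60)
  edges <- c(lib$cadmium$edge, lib$tellurium$edge)
  g <- insert_edge_breakpoints(grid, edges)
  mu <- w_cd * parametric_mu(lib$cadmium, g) + (1 - w_cd) * parametric_mu(lib$tellurium, g)
  attenuation_curve("CdTe", g, mu, edges[edges > min(g) & edges < max(g)])
}

#' Air mass energy-absorption curve
#'
#' Parametric \eqn{(\mu_{en}/\rho)_{air}}(E) used for air-kerma computation:
#' 4.74 (E/10)^-3.13 + 0.010 cm^2/g, anchored to standard tabulations at
#' 10-50 keV.
#'
#' @param grid energy grid, keV.
#' @return an [attenuation_curve()] labeled `"air_en"`.
#' @export
air_energy_absorption_curve <- function(grid) {
  attenuation_curve("air_en", grid, 4.74 * (grid / 10)^(-3.13) + 0.010)
}

#' Build a shared-grid attenuation set
#'
#' Evaluates a list of parametric materials onto a common grid (augmented
#' with one-sided breakpoints at every in-span K-edge of the listed
#' materials). K-edges falling outside the grid span are simply absent from
#' the evaluated curves.
#'
#' @param materials named list of [parametric_material()] objects.
#' @param grid energy grid, keV (should span the spectral range in use).
#' @return named list of [attenuation_curve()] objects sharing one grid,
#'   with the grid attached as attribute `"energies"`.
#' @export
make_attenuation_set <- function(materials, grid) {
  edges <- unlist(lapply(materials, function(m) m$edge))
  g <- insert_edge_breakpoints(grid, as.numeric(edges))
  out <- lapply(materials, function(m) {
    e <- if (!is.null(m$edge) && m$edge > min(g) && m$edge < max(g)) m$edge else numeric(0)
    attenuation_curve(m$label, g, parametric_mu(m, g), e)
  })
  attr(out, "energies") <- g
  out
}

#' Poisson count replicates for a bin-count vector
#'
#' @param c_bar numeric vector of expected counts (>= 0).
#' @param n_reps number of replicates.
#' @param seed integer seed; identical seeds give identical tables.
#' @return `n_reps` x `length(c_bar)` integer matrix.
#' @export
sample_counts <- function(c_bar, n_reps, seed) {
  if (any(c_bar < 0)) stop("expected counts must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  matrix(stats::rpois(n_reps * length(c_bar), rep(c_bar, each = n_reps)),
         nrow = n_reps)
}

#' Complete consistent input sets for end-to-end testing
#'
#' Scenarios:
#' * `"blank"`: strontium-free finger, W/Ag 24 kVp, 5 keV noise floor,
#'   thresholds 12.5/15.5/20.5 keV.
#' * `"baseline-150ppm"`: as blank with 150 ppm Sr in trabecular bone.
#' * `"high-1000ppm"`: as blank with 1000 ppm.
#' * `"monochromatic-toy"`: a narrow 25 keV line spectrum on a fine grid
#'   with thresholds 12.5/20/30 keV, for closed-form count checks.
#'
#' @param scenario scenario label.
#' @param fluence_scale spectrum normalization (photons/mm^2 scale).
#' @return list with `spectrum`, `attenuation`, `phantom`, `geometry`,
#'   `config`, `sensor`.
#' @export
end_to_end_fixture <- function(scenario = c("blank", "baseline-150ppm",
                                            "high-1000ppm", "monochromatic-toy"),
                               fluence_scale = 1e7) {
  scenario <- match.arg(scenario)
  lib <- .parametric_library()
  basis <- lib[c("strontium", "cortical_bone", "soft_tissue")]
  geom <- projection_geometry()
  if (scenario == "monochromatic-toy") {
    e0 <- 25
    grid <- sort(unique(c(seq(5, 40, 0.25), seq(e0 - 0.008, e0 + 0.008, 2e-4))))
    attn <- make_attenuation_set(basis, grid)
    g <- attr(attn, "energies")
    sigma_line <- 0.001
    fl <- stats::dnorm(g, e0, sigma_line)
    fl <- fl / trapz(g, fl) * fluence_scale
    sp <- xray_spectrum(g, fl, kvp = 40, anode = "mono")
    cfg <- acquisition_config(kvp = 40, thresholds = c(12.5, 20, 30), noise_floor = 5,
                              anode_filter = "mono")
    phantom <- finger_phantom(C_trab = 0)
  } else {
    C_t <- switch(scenario, "blank" = 0, "baseline-150ppm" = 150e-6,
                  "high-1000ppm" = 1000e-6)
    phantom <- finger_phantom(C_trab = C_t)
    kvp <- 24
    grid <- build_energy_grid(kvp)
    attn <- make_attenuation_set(basis, grid)
    sp <- standard_beam("W/Ag", kvp, grid = attr(attn, "energies"),
                        fluence_scale = fluence_scale)
    cfg <- acquisition_config(kvp = kvp, thresholds = c(12.5, 15.5, 20.5),
                              noise_floor = 5, anode_filter = "W/Ag")
  }
  sensor <- sensor_config(noise_floor = cfg$noise_floor, grid = sp$energies)
  list(spectrum = sp, attenuation = attn, phantom = phantom, geometry = geom,
       config = cfg, sensor = sensor)
}
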