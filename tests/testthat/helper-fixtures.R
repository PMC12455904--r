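# Shared lazily-built fixtures (memoized across tests within one run).

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, .fx_cache)) assign(name, build(), .fx_cache)
  get(name, .fx_cache)
}

fx_baseline <- function() fx("baseline", function() end_to_end_fixture("baseline-150ppm"))
fx_blank <- function() fx("blank", function() end_to_end_fixture("blank"))
fx_toy <- function() fx("toy", function() end_to_end_fixture("monochromatic-toy"))

fx_basis_attn <- function() fx("basis_attn", function() fx_baseline()$attenuation)

# response for the baseline acquisition
fx_response <- function() fx("response", function() {
  b <- fx_baseline()
  bin_gains(b$config, b$sensor, b$spectrum$energies)
})

fx_map <- function() fx("map", function() {
  b <- fx_baseline()
  areal_density_map(b$phantom, b$geometry)
})

fx_abar <- function() fx("abar", function() mean_areal_density(fx_map()))

# flat (energy-independent) basis attenuation set, for constant-mu checks
flat_attn <- function(vals = c(strontium = 3, cortical_bone = 2, soft_tissue = 0.5),
                      grid = seq(5, 40, 0.25)) {
  out <- lapply(names(vals), function(nm)
    attenuation_curve(nm, grid, rep(vals[[nm]], length(grid))))
  names(out) <- names(vals)
  out
}

# hand-built single-pixel areal-density map
tiny_map <- function(a_Sr, a_B, a_ST, weight = 1) {
  df <- data.frame(phalanx = 1L, fan_index = 0L, a_Sr = a_Sr, a_B = a_B,
                   a_ST = a_ST, weight = weight)
  df$mask <- df$a_B > 1e-6
  structure(df, class = c("areal_density_map", "data.frame"),
            n_pixels = sum(df$weight[df$mask]))
}
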