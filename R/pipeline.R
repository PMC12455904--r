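# Configuration handling, orchestration and table emission.

.config_schema <- list(
  phantom = c("lengths_mm", "r_outer_mm", "r_inner_mm", "soft_tissue_mm",
              "C_trab_ppm", "trab_cort_ratio", "porosity"),
  geometry = c("sdd_mm", "sod_mm", "pitch_mm"),
  sensor = c("noise_floor_keV", "sigma_e_keV", "thickness_mm",
             "density_g_cm3", "escape_fraction"),
  spectrum = c("anode_filter", "kvp", "fluence_scale"),
  acquisition = c("thresholds_keV"),
  grid = c("kvp_range", "threshold_step"),
  scenario = c("seed", "loq_target_ppm", "snr_dose_uGy",
               "loq_targets_ppm", "concentrations_ppm"),
  output = c("dir")
)

#' Default run configuration
#'
#' The study conditions: standard finger phantom with 150 ppm Sr in
#' trabecular bone (4:1 trabecular:cortical), SDD/SOD 150/100 mm at 50 um
#' pitch, 750 um CdTe sensor at a 5 keV noise floor, W/Ag beam at 24 kVp
#' with thresholds 12.5/15.5/20.5 keV.
#'
#' @return nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(lengths_mm = c(proximal = 30, middle = 25, distal = 20),
                   r_outer_mm = c(4.5, 4.0, 3.25),
                   r_inner_mm = c(3.0, 2.6, 2.0),
                   soft_tissue_mm = 3, C_trab_ppm = 150,
                   trab_cort_ratio = 4, porosity = 0.8),
    geometry = list(sdd_mm = 150, sod_mm = 100, pitch_mm = 0.05),
    sensor = list(noise_floor_keV = 5, thickness_mm = 0.75,
                  density_g_cm3 = 5.85, escape_fraction = 0.12),
    spectrum = list(anode_filter = "W/Ag", kvp = 24, fluence_scale = 1e7),
    acquisition = list(thresholds_keV = c(12.5, 15.5, 20.5)),
    grid = list(kvp_range = c(20, 50), threshold_step = 0.5),
    scenario = list(seed = 1, loq_target_ppm = 100, snr_dose_uGy = 20,
                    loq_targets_ppm = c(25, 50, 75, 100, 150, 200, 300),
                    concentrations_ppm = c(25, 50, 100, 150, 250, 500, 1000)),
    output = list(dir = ".")
  ), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Values present in the file override the defaults; unknown blocks or keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (blk in names(user)) {
    if (!blk %in% names(.config_schema))
      stop(sprintf("unknown config block '%s'", blk))
    for (key in names(user[[blk]])) {
      if (!key %in% .config_schema[[blk]])
        stop(sprintf("unknown config key '%s.%s'", blk, key))
      cfg[[blk]][[key]] <- user[[blk]][[key]]
    }
  }
  validate_run_config(cfg)
}

#' Validate a run configuration
#' @param cfg a `run_config` list.
#' @return `cfg`, invisibly on success.
#' @export
validate_run_config <- function(cfg) {
  .as_phantom(cfg); .as_geometry(cfg)   # constructors perform the checks
  if (!cfg$spectrum$anode_filter %in% c("W/Ag", "Rh/Rh", "Mo/Mo"))
    stop("spectrum.anode_filter must be one of W/Ag, Rh/Rh, Mo/Mo")
  invisible(cfg)
}

.as_phantom <- function(cfg, C_ppm = NULL) {
  p <- cfg$phantom
  if (is.null(C_ppm)) C_ppm <- p$C_trab_ppm
  finger_phantom(lengths_mm = unlist(p$lengths_mm),
                 r_outer_mm = unlist(p$r_outer_mm),
                 r_inner_mm = unlist(p$r_inner_mm),
                 soft_tissue_mm = p$soft_tissue_mm,
                 densities = material_densities(porosity = p$porosity),
                 C_trab = C_ppm * 1e-6,
                 trab_cort_ratio = p$trab_cort_ratio)
}

.as_geometry <- function(cfg) {
  g <- cfg$geometry
  projection_geometry(sdd_mm = g$sdd_mm, sod_mm = g$sod_mm, pitch_mm = g$pitch_mm)
}

.as_acquisition <- function(cfg) {
  acquisition_config(kvp = cfg$spectrum$kvp,
                     thresholds = unlist(cfg$acquisition$thresholds_keV),
                     noise_floor = cfg$sensor$noise_floor_keV,
                     anode_filter = cfg$spectrum$anode_filter)
}

# simple additive checksum of the resolved configuration (diffable header id)
.config_digest <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %% .Machine$integer.max)
}

#' Write a delimited report table with a unit-bearing header
#'
#' Plain tab-separated text preceded by `# key: value` comment lines
#' (including the resolved config checksum), re-parseable by
#' [read_report_table()].
#'
#' @param df data.frame.
#' @param path file path.
#' @param meta named character vector of header metadata.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_report_table()]
#' @param path file path.
#' @return data.frame with header metadata in attribute `"meta"`.
#' @export
read_report_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- if (length(hdr)) {
    kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
    stats::setNames(vapply(kv, `[`, character(1), 3),
                    trimws(vapply(kv, `[`, character(1), 2)))
  } else character(0)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Run a pipeline subcommand
#'
#' Orchestrates the simulation for one configuration and writes plain-text
#' report tables plus a resolved-parameter log. Subcommands:
#' * `precision`: full [precision_report()] for the configured acquisition.
#' * `optimize`: exhaustive [grid_search()] with the grid trace.
#' * `dose`: absorbed dose, air kerma and D/K_air.
#' * `loq-curve`: minimum dose versus LOQ target.
#' * `snr-curve`: SNR versus Sr concentration at the fixed scenario dose.
#' * `fisher`: per-bin projected Fisher fractions.
#' * `fixtures`: write the configured beam spectrum and attenuation tables.
#'
#' @param cfg a `run_config` (see [default_run_config()], [read_run_config()]).
#' @param subcommand one of the subcommands above.
#' @param out_dir output directory (overrides `cfg$output$dir`).
#' @param verbose echo resolved parameters and stage timing.
#' @return invisibly, a list with computed `result` and written `paths`.
#' @export
run_pipeline <- function(cfg, subcommand = c("precision", "optimize", "dose",
                                             "loq-curve", "snr-curve",
                                             "fisher", "fixtures"),
                         out_dir = NULL, verbose = FALSE) {
  subcommand <- match.arg(subcommand)
  validate_run_config(cfg)
  if (is.null(out_dir)) out_dir <- cfg$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  digest <- .config_digest(cfg)
  meta <- c(config = digest, subcommand = subcommand)
  phantom <- .as_phantom(cfg)
  geom <- .as_geometry(cfg)
  sensor <- sensor_config(noise_floor = cfg$sensor$noise_floor_keV,
                          sigma_e = cfg$sensor$sigma_e_keV,
                          thickness_mm = cfg$sensor$thickness_mm,
                          density = cfg$sensor$density_g_cm3,
                          escape_fraction = cfg$sensor$escape_fraction)
  paths <- character(0)
  log_path <- file.path(out_dir, sprintf("%s_params.yaml", gsub("-", "_", subcommand)))
  yaml::write_yaml(c(list(resolved_config = unclass(cfg)), list(digest = digest)), log_path)
  paths <- c(paths, log_path)
  if (verbose) message(sprintf("[%s] resolved config %s", subcommand, digest))

  result <- switch(
    subcommand,
    "precision" = {
      rep <- precision_report(.as_acquisition(cfg), phantom, geom, sensor,
                              fluence_scale = cfg$spectrum$fluence_scale,
                              loq_target_ppm = cfg$scenario$loq_target_ppm,
                              snr_dose_Gy = cfg$scenario$snr_dose_uGy * 1e-6)
      p <- file.path(out_dir, "precision.tsv")
      write_precision_report(rep, p)
      paths <- c(paths, p)
      rep
    },
    "optimize" = {
      opt <- grid_search(cfg$spectrum$anode_filter, cfg$sensor$noise_floor_keV,
                         phantom = phantom, geom = geom,
                         kvp_range = unlist(cfg$grid$kvp_range),
                         threshold_step = cfg$grid$threshold_step,
                         fluence_scale = cfg$spectrum$fluence_scale)
      p1 <- file.path(out_dir, "optimal.tsv")
      write_report_table(
        data.frame(anode_filter = opt$anode_filter, noise_floor_keV = opt$noise_floor,
                   kvp_keV = opt$kvp, E1_keV = opt$thresholds[1],
                   E2_keV = opt$thresholds[2], E3_keV = opt$thresholds[3],
                   objective_snr_per_sqrtGy = opt$objective,
                   d_per_kair_uGy_per_mGy = opt$d_per_kair),
        p1, meta)
      p2 <- file.path(out_dir, "grid_trace.tsv")
      write_report_table(opt$trace, p2,
                         c(meta, units = "kvp keV; E2 keV; E3 keV; objective 1/sqrt(Gy)"))
      paths <- c(paths, p1, p2)
      opt
    },
    "dose" = {
      beam <- standard_beam(cfg$spectrum$anode_filter, cfg$spectrum$kvp,
                            fluence_scale = cfg$spectrum$fluence_scale)
      lib <- material_library()
      attn <- make_attenuation_set(lib[c("strontium", "cortical_bone", "soft_tissue")],
                                   beam$energies)
      map <- areal_density_map(phantom, geom)
      dr <- absorbed_dose(beam, map, attn)
      kair <- air_kerma(beam, fluence_scale = (geom$sdd_mm / geom$sod_mm)^2)
      p <- file.path(out_dir, "dose.tsv")
      write_report_table(
        data.frame(dose_uGy = dr$D_Gy * 1e6, K_air_uGy = kair * 1e6,
                   d_per_kair_uGy_per_mGy = dose_per_kerma(dr$D_Gy, kair),
                   edep_J = dr$edep_J, mass_kg = dr$mass_kg,
                   n_excluded = dr$n_excluded),
        p, meta)
      paths <- c(paths, p)
      list(dose = dr, K_air_Gy = kair)
    },
    "loq-curve" = {
      rep <- precision_report(.as_acquisition(cfg), phantom, geom, sensor,
                              fluence_scale = cfg$spectrum$fluence_scale)
      targets <- unlist(cfg$scenario$loq_targets_ppm)
      df <- data.frame(loq_ppm = targets,
                       d_min_uGy = min_dose(rep$sigma_Cb2_tilde, targets) * 1e6)
      p <- file.path(out_dir, "loq_curve.tsv")
      write_report_table(df, p, c(meta, units = "loq ppm; d_min uGy"))
      paths <- c(paths, p)
      df
    },
    "snr-curve" = {
      conc <- unlist(cfg$scenario$concentrations_ppm)
      dose_Gy <- cfg$scenario$snr_dose_uGy * 1e-6
      snr <- vapply(conc, function(cp) {
        rep <- precision_report(.as_acquisition(cfg), .as_phantom(cfg, C_ppm = cp),
                                geom, sensor,
                                fluence_scale = cfg$spectrum$fluence_scale,
                                snr_dose_Gy = dose_Gy)
        rep$SNR
      }, numeric(1))
      df <- data.frame(concentration_ppm = conc, snr = snr)
      p <- file.path(out_dir, "snr_curve.tsv")
      write_report_table(df, p, c(meta, units = sprintf(
        "concentration ppm; snr dimensionless at %g uGy", cfg$scenario$snr_dose_uGy)))
      paths <- c(paths, p)
      df
    },
    "fisher" = {
      rep <- precision_report(.as_acquisition(cfg), phantom, geom, sensor,
                              fluence_scale = cfg$spectrum$fluence_scale)
      df <- data.frame(bin = 1:3, fraction = as.numeric(rep$fisher_fractions))
      p <- file.path(out_dir, "fisher.tsv")
      write_report_table(df, p, c(meta, units = "fraction dimensionless"))
      paths <- c(paths, p)
      df
    },
    "fixtures" = {
      beam <- standard_beam(cfg$spectrum$anode_filter, cfg$spectrum$kvp,
                            fluence_scale = cfg$spectrum$fluence_scale)
      p1 <- file.path(out_dir, "spectrum.txt")
      write_spectrum(beam, p1)
      lib <- material_library()
      attn <- make_attenuation_set(lib[c("strontium", "cortical_bone", "soft_tissue")],
                                   beam$energies)
      p2 <- vapply(names(attn), function(nm) {
        p <- file.path(out_dir, sprintf("attenuation_%s.txt", nm))
        write_attenuation(attn[[nm]], p)
        p
      }, character(1))
      paths <- c(paths, p1, p2)
      list(spectrum = p1, attenuation = p2)
    }
  )
  if (verbose) message(sprintf("[%s] done in %.2f s", subcommand,
                               as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(result = result, paths = paths))
}
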