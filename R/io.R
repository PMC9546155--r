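# Configuration loading and file I/O for the pipeline stages.

.config_known_keys <- list(
  site = c("lat", "elevation", "slope", "aspect", "tree_type", "height",
           "maxlai"),
  paths = c("meteo", "soil", "obs"),
  top = c("site", "paths", "ptf", "phenology", "plant", "flow",
          "calibration", "spinup_years"))

#' Load and validate a run configuration
#'
#' The configuration is structured text (YAML) with a `site` block
#' (latitude, elevation, slope, aspect, tree type, tree height, maximum
#' LAI), a `paths` block (meteo/soil/obs CSV files), the `ptf` choice,
#' optional `phenology`, `plant`, `flow` and `calibration` blocks, and
#' `spinup_years`. Unknown keys are errors (no silent typos); defaults
#' fill every optional value.
#'
#' @param path Path to the YAML configuration file.
#' @return Named list of class `run_config` with all defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_known_keys$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$site)) stop("config requires a 'site' block")
  us <- setdiff(names(cfg$site), .config_known_keys$site)
  if (length(us))
    stop("unknown site key(s): ", paste(us, collapse = ", "))
  for (req in c("lat", "tree_type", "height", "maxlai"))
    if (is.null(cfg$site[[req]]))
      stop("site block is missing required key: ", req)
  if (!cfg$site$tree_type %in% c("deciduous", "coniferous"))
    stop("tree_type must be one of: deciduous, coniferous (got '",
         cfg$site$tree_type, "')")
  cfg$site$elevation <- cfg$site$elevation %||% 500
  cfg$site$slope <- cfg$site$slope %||% 0
  cfg$site$aspect <- cfg$site$aspect %||% 180
  if (!is.null(cfg$paths)) {
    up <- setdiff(names(cfg$paths), .config_known_keys$paths)
    if (length(up)) stop("unknown paths key(s): ", paste(up, collapse = ", "))
    for (p in unlist(cfg$paths))
      if (!file.exists(p)) stop("referenced path does not exist: ", p)
  }
  cfg$ptf <- cfg$ptf %||% "wessolek"
  if (!cfg$ptf %in% c("wessolek", "puhlmann"))
    stop("ptf must be 'wessolek' or 'puhlmann'")
  cfg$spinup_years <- cfg$spinup_years %||% 1L
  if (cfg$spinup_years < 0) stop("spinup_years must be >= 0")
  cfg$phenology <- do.call(phenology_params, cfg$phenology %||% list())
  cfg$plant <- do.call(plant_params, cfg$plant %||% list())
  cfg$flow <- do.call(flow_params, cfg$flow %||% list())
  cfg$calibration <- utils::modifyList(
    list(n_samples = 5000L, n_behavioural = 30L, seed = 1L,
         threshold = 0.2), cfg$calibration %||% list())
  structure(cfg, class = "run_config")
}

#' Read a daily meteorology CSV
#'
#' Columns: `date` (ISO-8601), `tmin`, `tmean`, `tmax`, `prec`, `vp` or
#' `rh`, `globrad`, `wind`.
#'
#' @param path CSV file path.
#' @return Prepared meteorology data.frame (see [prepare_meteo()]).
#' @export
read_meteo_csv <- function(path) prepare_meteo(read.csv(path))

#' Read a soil profile CSV
#'
#' Columns: `top_m`, `bottom_m`, `sand_pct`, `silt_pct`, `clay_pct`,
#' `gravel_frac`, `bd_gcm3`, `corg_pct`; one row per horizon, ordered
#' top to bottom.
#'
#' @param path CSV file path.
#' @return Validated horizon table.
#' @export
read_profile_csv <- function(path) {
  prof <- read.csv(path)
  validate_profile(prof)
  prof
}

#' Read a sensor observation CSV
#'
#' Columns: `date`, `depth_m`, `psi_kpa` (empty for censored records).
#'
#' @param path CSV file path.
#' @return Observation data.frame.
#' @export
read_obs_csv <- function(path) {
  obs <- read.csv(path)
  need <- c("date", "depth_m", "psi_kpa")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("obs missing columns: ", paste(miss, collapse = ", "))
  obs$date <- as.Date(obs$date)
  obs$psi_kpa <- as.numeric(obs$psi_kpa)
  obs$depth_m <- as.numeric(obs$depth_m)
  obs
}

#' Write daily fluxes (and optionally per-layer potentials) to CSV
#'
#' @param run A [run_simulation()] result.
#' @param path Output CSV for the daily fluxes.
#' @param psi_path Optional CSV path for the days x layers matric
#'   potential matrix.
#' @return `path`, invisibly.
#' @export
write_fluxes_csv <- function(run, path, psi_path = NULL) {
  write.csv(format(run$fluxes, digits = 10), path, row.names = FALSE,
            quote = FALSE)
  if (!is.null(psi_path)) {
    m <- as.data.frame(run$psi)
    names(m) <- sprintf("psi_%03.0fcm",
                        100 * (run$column$layers$top_m +
                                 run$column$layers$bottom_m) / 2)
    m <- cbind(date = run$fluxes$date, m)
    write.csv(format(m, digits = 10), psi_path, row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}

#' Write a complete ready-to-run synthetic site bundle
#'
#' Writes `meteo.csv`, `soil.csv`, `obs.csv` and `site.yaml` for a
#' synthetic site with known truth into a directory.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param n_years Number of simulated years.
#' @param template Soil profile template, see [gen_profile()].
#' @param truth Truth parameters, see [recovery_truth_defaults()].
#' @return The directory path, invisibly.
#' @export
write_site_bundle <- function(dir, seed = 1L, n_years = 3,
                              template = "deep_loam",
                              truth = recovery_truth_defaults()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  site <- list(lat = 47, elevation = 600, slope = 0, aspect = 180,
               tree_type = "deciduous", height = 25, maxlai = 4.6)
  # dry end of the climate gradient so the sensors see real drydowns
  meteo <- gen_meteo(climate_spec(), n_years, seed = seed,
                     precip_scale = 0.6)
  profile <- gen_profile(template, seed = seed + 1000L)
  mvg <- apply_ptf(profile, "wessolek")
  cfg <- .apply_sample(as.data.frame(truth), plant_params(),
                       flow_params(), profile, mvg)
  run <- run_simulation(meteo, site, cfg$plant, cfg$flow, cfg$column,
                        spinup_years = 1)
  obs <- gen_observations(run, sensor_spec(), seed = seed + 2000L)
  out <- meteo[, c("date", "tmin", "tmean", "tmax", "prec", "vp",
                   "globrad", "wind")]
  write.csv(format(out, digits = 10), file.path(dir, "meteo.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(format(profile, digits = 10), file.path(dir, "soil.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(obs, file.path(dir, "obs.csv"), row.names = FALSE,
            quote = FALSE)
  yaml::write_yaml(c(list(site = site,
                          paths = list(meteo = file.path(dir, "meteo.csv"),
                                       soil = file.path(dir, "soil.csv"),
                                       obs = file.path(dir, "obs.csv"))),
                     list(ptf = "wessolek", spinup_years = 1L)),
                   file.path(dir, "site.yaml"))
  invisible(dir)
}
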