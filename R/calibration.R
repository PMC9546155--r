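# GLUE-style Monte-Carlo-filtering calibration against depth-resolved
# soil matric potential: efficiency metrics, combined objective,
# behavioural selection, Kolmogorov-Smirnov sensitivity screening and
# posterior summaries.

# valid measurement range of the matric potential sensors (kPa)
SENSOR_RANGE <- c(-1000, -9)

#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((sim - obs)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param obs,sim Equal-length numeric vectors (length >= 2).
#' @return Efficiency (<= 1; 1 is a perfect fit).
#' @export
nse <- function(obs, sim) {
  if (length(obs) != length(sim)) stop("obs and sim must have equal length")
  if (length(obs) < 2) stop("need at least 2 observations")
  denom <- sum((obs - mean(obs))^2)
  if (denom == 0) stop("NSE undefined for constant observations")
  1 - sum((sim - obs)^2) / denom
}

#' Kling-Gupta efficiency (2009 formulation)
#'
#' `1 - sqrt((r-1)^2 + (sd(sim)/sd(obs)-1)^2 + (mean(sim)/mean(obs)-1)^2)`.
#'
#' @param obs,sim Equal-length numeric vectors (length >= 2).
#' @return Efficiency (<= 1; 1 is a perfect fit).
#' @export
kge <- function(obs, sim) {
  if (length(obs) != length(sim)) stop("obs and sim must have equal length")
  if (length(obs) < 2) stop("need at least 2 observations")
  so <- sd(obs); mo <- mean(obs)
  if (so == 0 || mo == 0) stop("KGE undefined: zero variance or zero mean")
  ss <- sd(sim)
  r <- if (ss == 0) 0 else cor(obs, sim)
  1 - sqrt((r - 1)^2 + (ss / so - 1)^2 + (mean(sim) / mo - 1)^2)
}

#' Combined multi-depth objective function
#'
#' Euclidean distance of the per-depth (NSE, KGE) pairs from their
#' optimum of 1: `sqrt(sum_i (1-NSE_i)^2 + (1-KGE_i)^2)`. Lower is
#' better; 0 means a perfect fit at every depth.
#'
#' @param nse_depths,kge_depths Numeric vectors of per-depth
#'   efficiencies (same length, >= 1).
#' @param normalize If `TRUE`, divide by the number of depths.
#' @return Non-negative scalar.
#' @export
cof <- function(nse_depths, kge_depths, normalize = FALSE) {
  if (!length(nse_depths)) stop("empty depth range")
  if (length(nse_depths) != length(kge_depths))
    stop("per-depth NSE and KGE must align")
  v <- sqrt(sum((1 - nse_depths)^2 + (1 - kge_depths)^2))
  if (normalize) v <- v / length(nse_depths)
  v
}

#' Parameter specification table for the Monte-Carlo ensemble
#'
#' Default priors span the literature ranges for the plant, flow and
#' root parameters; soil-hydraulic parameters are sampled as
#' multiplicative factors within +/-30% of their pedotransfer value.
#'
#' @param tree_type `"deciduous"` or `"coniferous"` (affects the glmax
#'   prior).
#' @return data.frame with columns `name`, `low`, `high`, `kind`.
#' @export
default_parameter_specs <- function(tree_type = "deciduous") {
  glmax_rng <- if (tree_type == "coniferous") c(0.007, 0.013)
               else c(0.002, 0.018)
  rbind(
    data.frame(name = "glmax", low = glmax_rng[1], high = glmax_rng[2],
               kind = "plant"),
    data.frame(name = "mxkpl", low = 2, high = 30, kind = "plant"),
    data.frame(name = "psicr", low = -4.2, high = -0.9, kind = "plant"),
    data.frame(name = "r5", low = 50, high = 400, kind = "plant"),
    data.frame(name = "cvpd", low = 0.5, high = 4, kind = "plant"),
    data.frame(name = "fxylem", low = 0.2, high = 0.8, kind = "plant"),
    data.frame(name = "drain", low = 0, high = 1, kind = "flow"),
    data.frame(name = "ilayer", low = 1, high = 4, kind = "flow"),
    data.frame(name = "infexp", low = 0, high = 2, kind = "flow"),
    data.frame(name = "rssa", low = 200, high = 2000, kind = "flow"),
    data.frame(name = "betaroot", low = 0.9, high = 0.995, kind = "root"),
    data.frame(name = "maxrootdepth", low = 0.4, high = 2, kind = "root"),
    data.frame(name = "alpha_fac", low = 0.7, high = 1.3,
               kind = "soil_hydraulic"),
    data.frame(name = "npar_fac", low = 0.7, high = 1.3,
               kind = "soil_hydraulic"),
    data.frame(name = "ksat_fac", low = 0.7, high = 1.3,
               kind = "soil_hydraulic"),
    data.frame(name = "ths_fac", low = 0.7, high = 1.3,
               kind = "soil_hydraulic")
  )
}

#' Sample a Monte-Carlo parameter ensemble from uniform priors
#'
#' @param specs Parameter specification table (`name`, `low`, `high`,
#'   `kind`), e.g. [default_parameter_specs()].
#' @param n Number of parameter vectors (default 5000).
#' @param seed Integer RNG seed; the same seed reproduces the matrix
#'   bit for bit.
#' @return data.frame, one row per sample, one column per parameter.
#' @export
sample_parameters <- function(specs, n = 5000, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (any(specs$low >= specs$high)) stop("prior low must be < high")
  set.seed(seed)
  out <- as.data.frame(lapply(seq_len(nrow(specs)), function(i)
    runif(n, specs$low[i], specs$high[i])))
  names(out) <- specs$name
  out
}

#' Split scored runs into behavioural and non-behavioural sets
#'
#' The `k` runs with the lowest combined objective are behavioural;
#' ties are broken by run index (first come, first selected).
#'
#' @param cof_values Combined objective per run.
#' @param k Number of behavioural runs (default 30).
#' @return List with integer index vectors `behavioural` and
#'   `non_behavioural`.
#' @export
classify_behavioural <- function(cof_values, k = 30) {
  if (k > length(cof_values)) stop("k exceeds the number of runs")
  ord <- order(cof_values, seq_along(cof_values))
  list(behavioural = sort(ord[seq_len(k)]),
       non_behavioural = sort(ord[-seq_len(k)]))
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Sup-norm distance between the empirical cumulative distribution
#' functions of the two samples, evaluated at every sample point.
#'
#' @param x,y Non-empty numeric vectors.
#' @return `D_max` in `[0, 1]`.
#' @export
ks_dmax <- function(x, y) {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  fx <- ecdf(x)(pts)
  fy <- ecdf(y)(pts)
  max(abs(fx - fy))
}

#' Kolmogorov-Smirnov sensitivity screening of an ensemble
#'
#' For each parameter, `D_max` between its behavioural and
#' non-behavioural marginals; a parameter is sensitive when `D_max`
#' exceeds the threshold in any site group (max aggregation).
#'
#' @param params data.frame of sampled parameters (one row per run).
#' @param cof_values Combined objective per run, or a list of such
#'   vectors (one per site group).
#' @param k Number of behavioural runs per group.
#' @param threshold Sensitivity threshold on `D_max` (default 0.2).
#' @return data.frame with `parameter`, `dmax` (max over groups) and
#'   `sensitive`.
#' @export
sensitivity_screen <- function(params, cof_values, k = 30,
                               threshold = 0.2) {
  if (!is.list(cof_values) || is.data.frame(cof_values))
    cof_values <- list(cof_values)
  dmax <- rep(0, ncol(params))
  for (cv in cof_values) {
    cl <- classify_behavioural(cv, k)
    d <- vapply(params, function(p)
      ks_dmax(p[cl$behavioural], p[cl$non_behavioural]), numeric(1))
    dmax <- pmax(dmax, d)
  }
  data.frame(parameter = names(params), dmax = dmax,
             sensitive = dmax > threshold, row.names = NULL)
}

#' Posterior median parameter sets per group
#'
#' @param params data.frame of behavioural parameter vectors.
#' @param grouping Factor/character vector assigning each run to a group
#'   (e.g. deciduous/coniferous); a single group by default.
#' @return data.frame of per-parameter medians, one row per group.
#' @export
posterior_summary <- function(params, grouping = NULL) {
  if (!nrow(params)) stop("no behavioural runs")
  if (is.null(grouping)) grouping <- rep("all", nrow(params))
  if (any(table(grouping) == 0)) stop("empty group")
  agg <- aggregate(params, by = list(group = grouping), FUN = median)
  agg
}

#' Score a simulation against depth-resolved sensor observations
#'
#' Sensors are mapped to the computational layer whose midpoint is
#' nearest to the sensor depth. Only days with observations inside the
#' valid sensor range are scored; simulated values are clipped to the
#' range first so that states the sensor could not have seen are not
#' penalized.
#'
#' @param run An object from [run_simulation()], or a days x layers psi
#'   matrix.
#' @param obs Observation table with columns `date`, `depth_m`,
#'   `psi_kpa` (kPa; `NA` for censored records).
#' @param column The [soil_column()] used (required if `run` is a
#'   matrix).
#' @param dates Dates of the simulation rows (required if `run` is a
#'   matrix).
#' @param sensor_range Valid range (kPa), default c(-1000, -9).
#' @return List with per-depth `nse`, `kge`, `n` (scored days),
#'   `depths`, and the combined objective `cof`.
#' @export
score_against_sensors <- function(run, obs, column = NULL, dates = NULL,
                                  sensor_range = SENSOR_RANGE) {
  if (inherits(run, "svat_run")) {
    psim <- run$psi; column <- run$column; dates <- run$fluxes$date
    keep <- !run$fluxes$spinup
    psim <- psim[keep, , drop = FALSE]; dates <- dates[keep]
  } else {
    psim <- run
    if (is.null(column) || is.null(dates))
      stop("column and dates are required when run is a matrix")
  }
  mid <- (column$layers$top_m + column$layers$bottom_m) / 2
  depths <- sort(unique(obs$depth_m))
  nse_d <- kge_d <- n_d <- numeric(length(depths))
  for (j in seq_along(depths)) {
    lay <- which.min(abs(mid - depths[j]))
    od <- obs[obs$depth_m == depths[j], ]
    m <- match(as.Date(od$date), as.Date(dates))
    ok <- !is.na(m) & !is.na(od$psi_kpa) &
      od$psi_kpa >= sensor_range[1] & od$psi_kpa <= sensor_range[2]
    if (sum(ok) < 2)
      stop("no scoreable days at depth ", depths[j],
           " m (all observations censored or unmatched)")
    o <- od$psi_kpa[ok]
    s <- pmin(pmax(psim[m[ok], lay], sensor_range[1]), sensor_range[2])
    nse_d[j] <- nse(o, s)
    kge_d[j] <- kge(o, s)
    n_d[j] <- sum(ok)
  }
  list(depths = depths, nse = nse_d, kge = kge_d, n = n_d,
       cof = cof(nse_d, kge_d))
}

#' Score one parameter vector on calibration and validation years
#'
#' Computes the sensor objective independently on two disjoint sets of
#' years with the same simulation.
#'
#' @param run A [run_simulation()] result.
#' @param obs Observation table (see [score_against_sensors()]).
#' @param cal_years,val_years Disjoint integer year sets.
#' @return List with `calibration` and `validation` score lists.
#' @export
temporal_split <- function(run, obs, cal_years, val_years) {
  if (length(intersect(cal_years, val_years)))
    stop("calibration and validation years overlap")
  yr <- as.integer(format(as.Date(obs$date), "%Y"))
  have <- unique(yr)
  if (!all(cal_years %in% have) || !all(val_years %in% have))
    stop("requested years absent from the observations")
  sc <- function(years)
    score_against_sensors(run, obs[yr %in% years, , drop = FALSE])
  list(calibration = sc(cal_years), validation = sc(val_years))
}

# apply a sampled parameter row to (plant, flow, column-building inputs)
.apply_sample <- function(par, base_plant, base_flow, profile, mvg,
                          dz_max = 0.1) {
  plant <- base_plant; flow <- base_flow
  for (nm in c("glmax", "mxkpl", "psicr", "r5", "cvpd", "fxylem"))
    if (nm %in% names(par)) plant[[nm]] <- par[[nm]]
  for (nm in c("drain", "infexp", "rssa"))
    if (nm %in% names(par)) flow[[nm]] <- par[[nm]]
  if ("ilayer" %in% names(par)) flow$ilayer <- max(1L, round(par[["ilayer"]]))
  mvg2 <- lapply(mvg, function(p) {
    p <- .as_mvg(p)
    if ("alpha_fac" %in% names(par)) p$alpha <- p$alpha * par[["alpha_fac"]]
    if ("npar_fac" %in% names(par))
      p$n <- max(1.05, 1 + (p$n - 1) * par[["npar_fac"]])
    if ("ksat_fac" %in% names(par)) p$ksat <- p$ksat * par[["ksat_fac"]]
    if ("ths_fac" %in% names(par))
      p$theta_s <- min(0.95, max(p$theta_s * par[["ths_fac"]],
                                 p$theta_r + 0.05))
    p
  })
  column <- soil_column(profile, mvg2,
                        betaroot = if ("betaroot" %in% names(par))
                          par[["betaroot"]] else 0.95,
                        maxrootdepth = if ("maxrootdepth" %in% names(par))
                          par[["maxrootdepth"]] else 1,
                        dz_max = dz_max)
  list(plant = plant, flow = flow, column = column)
}

#' Monte-Carlo-filtering calibration of a site
#'
#' Samples `n` parameter vectors from uniform priors, runs the water
#' balance for each, scores it against the matric potential sensors,
#' selects the `k` best (lowest combined objective) as behavioural, and
#' summarizes sensitivity (`D_max`) and the behavioural posterior.
#'
#' @param meteo,site,profile,mvg Inputs as for [run_simulation()] /
#'   [soil_column()] (profile + per-horizon `mvg` are re-discretized per
#'   sample because root parameters are calibrated).
#' @param obs Sensor observations (see [score_against_sensors()]).
#' @param specs Prior table, default [default_parameter_specs()].
#' @param n Ensemble size (default 5000).
#' @param k Behavioural set size (default 30).
#' @param seed Integer RNG seed.
#' @param spinup_years Leading years excluded from scoring.
#' @param base_plant,base_flow Defaults for parameters not calibrated.
#' @return List of class `mc_calibration` with `samples` (parameters +
#'   per-depth scores + cof), `behavioural` indices, `sensitivity`
#'   table, `posterior` medians and `best` (index of the best run).
#' @export
calibrate_site <- function(meteo, site, profile, mvg, obs,
                           specs = NULL, n = 5000, k = 30, seed = 1L,
                           spinup_years = 1,
                           base_plant = plant_params(),
                           base_flow = flow_params()) {
  if (is.null(specs)) specs <- default_parameter_specs(site$tree_type)
  samples <- sample_parameters(specs, n, seed)
  cofs <- numeric(n)
  nse_list <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- tryCatch({
      cfg <- .apply_sample(samples[i, ], base_plant, base_flow, profile, mvg)
      run <- run_simulation(meteo, site, cfg$plant, cfg$flow, cfg$column,
                            spinup_years = spinup_years)
      score_against_sensors(run, obs)
    }, error = function(e) NULL)  # infeasible vector: non-behavioural
    if (is.null(sc)) {
      cofs[i] <- Inf
      nse_list[[i]] <- list(depths = numeric(0), nse = numeric(0),
                            kge = numeric(0))
    } else {
      cofs[i] <- sc$cof
      nse_list[[i]] <- sc
    }
  }
  cl <- classify_behavioural(cofs, k)
  sens <- sensitivity_screen(samples, cofs, k)
  post <- posterior_summary(samples[cl$behavioural, , drop = FALSE])
  depths <- sort(unique(obs$depth_m))
  empty <- setNames(rep(NA_real_, 2 * length(depths)),
                    c(paste0("nse_", depths), paste0("kge_", depths)))
  scores <- do.call(rbind, lapply(nse_list, function(s) {
    if (!length(s$depths)) return(empty)
    c(setNames(s$nse, paste0("nse_", s$depths)),
      setNames(s$kge, paste0("kge_", s$depths)))
  }))
  structure(list(samples = cbind(samples, scores, cof = cofs),
                 cof = cofs, behavioural = cl$behavioural,
                 sensitivity = sens, posterior = post,
                 best = which.min(cofs), specs = specs, seed = seed),
            class = "mc_calibration")
}
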