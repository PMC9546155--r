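test_that("efficiency metrics match hand-computed values", {
  expect_equal(nse(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(nse(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(nse(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(nse(rep(1, 5), rnorm(5)), "constant")
  expect_error(nse(1:3, 1:4), "equal length")

  expect_equal(kge(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(kge(c(1, 2, 3), c(2, 3, 4)), 0.5)   # r=1, sd ratio 1, bias 1.5
  expect_error(kge(rep(2, 4), 1:4), "undefined")
})

test_that("efficiency metrics agree with brute-force formulas on random cases", {
  set.seed(21)
  for (k in 1:200) {
    n <- sample(3:30, 1)
    obs <- rnorm(n, 10, 3)
    sim <- obs + rnorm(n, sample(c(-1, 0, 2), 1), runif(1, 0.1, 2))
    expect_equal(nse(obs, sim),
                 1 - sum((sim - obs)^2) / sum((obs - mean(obs))^2),
                 tolerance = 1e-12)
    r <- cor(obs, sim)
    expect_equal(kge(obs, sim),
                 1 - sqrt((r - 1)^2 + (sd(sim) / sd(obs) - 1)^2 +
                            (mean(sim) / mean(obs) - 1)^2),
                 tolerance = 1e-12)
  }
})

test_that("combined objective is a Euclidean distance over depths", {
  expect_equal(cof(c(1, 1), c(1, 1)), 0)
  expect_equal(cof(0, 1), 1)
  expect_equal(cof(c(0.5, 0.5), c(0.5, 0.5)), 1)   # sqrt(4 * 0.25)
  expect_error(cof(numeric(0), numeric(0)), "empty")
  set.seed(4)
  a <- runif(4); b <- runif(4)
  perm <- sample(4)
  expect_equal(cof(a, b), cof(a[perm], b[perm]), tolerance = 1e-12)
  worse <- a; worse[2] <- worse[2] - 0.3
  expect_gt(cof(worse, b), cof(a, b))
  expect_equal(cof(a, b, normalize = TRUE), cof(a, b) / 4)
})

test_that("parameter sampling respects bounds and seeds", {
  specs <- default_parameter_specs("deciduous")
  s1 <- sample_parameters(specs, 100, seed = 7)
  s2 <- sample_parameters(specs, 100, seed = 7)
  expect_identical(s1, s2)
  for (j in seq_len(ncol(s1))) {
    expect_true(all(s1[[j]] >= specs$low[j] & s1[[j]] <= specs$high[j]))
  }
  expect_false(identical(s1, sample_parameters(specs, 100, seed = 8)))
  # soil-hydraulic factors span +/-30% of the pedotransfer value
  fac <- specs[specs$kind == "soil_hydraulic", ]
  expect_true(all(fac$low == 0.7 & fac$high == 1.3))
})

test_that("behavioural selection is an order statistic with index tie-breaks", {
  cofs <- c(3, 1, 2, 1, 5)
  cl <- classify_behavioural(cofs, 2)
  expect_equal(cl$behavioural, c(2, 4))             # tie at 1 -> lower index
  expect_equal(sort(c(cl$behavioural, cl$non_behavioural)), 1:5)
  all_in <- classify_behavioural(cofs, 5)
  expect_equal(length(all_in$non_behavioural), 0)
  expect_lte(max(cofs[cl$behavioural]), min(cofs[cl$non_behavioural]))
  expect_error(classify_behavioural(cofs, 9), "exceeds")
})

test_that("KS distance matches ECDF enumeration and ks.test", {
  expect_equal(ks_dmax(1:5, 1:5), 0)
  expect_equal(ks_dmax(1:3, 4:6), 1)
  expect_equal(ks_dmax(c(1, 3), c(2, 4)), 0.5)
  set.seed(31)
  for (k in 1:100) {
    x <- round(rnorm(sample(3:20, 1)), 2)
    y <- round(rnorm(sample(3:20, 1), sample(0:1, 1)), 2)
    expect_equal(ks_dmax(x, y),
                 unname(suppressWarnings(ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  }
  expect_error(ks_dmax(numeric(0), 1:3), "non-empty")
})

test_that("sensitivity screening flags driving parameters and spares inert ones", {
  n <- 400
  set.seed(13)
  params <- data.frame(drives = runif(n), inert = runif(n))
  cofs <- abs(params$drives - 0.2) + rnorm(n, 0, 0.02)
  sens <- sensitivity_screen(params, cofs, k = 30)
  expect_true(sens$sensitive[sens$parameter == "drives"])
  expect_gt(sens$dmax[sens$parameter == "drives"],
            sens$dmax[sens$parameter == "inert"])
  # an inert parameter stays below the alpha = 0.05 KS critical value at
  # the nominal rate (95%, allowing binomial sampling noise over repeats)
  crit <- 1.36 * sqrt((30 + 370) / (30 * 370))
  hits <- 0
  for (s in 1:40) {
    set.seed(100 + s)
    p2 <- data.frame(inert = runif(n))
    c2 <- runif(n)
    d <- sensitivity_screen(p2, c2, k = 30)$dmax
    if (d <= crit) hits <- hits + 1
  }
  expect_gte(hits, 34)
})

test_that("posterior medians summarize behavioural runs per group", {
  p <- data.frame(a = c(1, 2, 3, 10), b = c(5, 6, 7, 20))
  one <- posterior_summary(p[1, , drop = FALSE])
  expect_equal(one$a, 1)
  g <- posterior_summary(p, grouping = c("x", "x", "x", "y"))
  expect_equal(g$a[g$group == "x"], 2)
  expect_equal(g$b[g$group == "y"], 20)
  expect_error(posterior_summary(p[0, , drop = FALSE]), "no behavioural")
})

test_that("sensor scoring clips to the valid range and maps depths", {
  run <- ref_run()
  # noise-free virtual sensors from the run itself: a perfect fit
  obs <- gen_observations(run, sensor_spec(noise_sd = 0), seed = 1)
  sc <- score_against_sensors(run, obs)
  expect_equal(sc$nse, rep(1, length(sc$nse)), tolerance = 1e-9)
  expect_equal(sc$kge, rep(1, length(sc$kge)), tolerance = 1e-9)
  expect_equal(sc$cof, 0, tolerance = 1e-6)

  # clipping: simulated values drier than the sensor floor score as the floor
  dates <- run$fluxes$date[!run$fluxes$spinup][1:5]
  col <- soil_column(ref_profile(0.4), list(ref_mvg()), 0.95, 0.4)
  psim <- matrix(0, 5, nrow(col$layers))
  psim[, 1] <- c(-2000, -950, -1500, -950, -1200)   # clips to the floor
  psim[, 4] <- c(-50, -100, -600, -900, -20)
  obs2 <- rbind(data.frame(date = dates, depth_m = 0.05,
                           psi_kpa = c(-1000, -950, -1000, -950, -1000)),
                data.frame(date = dates, depth_m = 0.35,
                           psi_kpa = psim[, 4]))
  sc2 <- score_against_sensors(psim, obs2, column = col, dates = dates)
  expect_equal(sc2$nse[1], 1)          # -2000 clipped to -1000 == obs
  # fully censored record is an error
  obs3 <- obs2
  obs3$psi_kpa <- -5                   # wetter than the valid range
  expect_error(score_against_sensors(psim, obs3, column = col,
                                     dates = dates), "censored")
})

test_that("temporal split scores disjoint periods with one simulation", {
  meteo <- gen_meteo(climate_spec(), 3, seed = 51, precip_scale = 0.6)
  profile <- gen_profile("deep_loam", seed = 51)
  col <- soil_column(profile, apply_ptf(profile, "wessolek"), 0.96, 1.2)
  run <- run_simulation(meteo, ref_site(), column = col, spinup_years = 1)
  obs <- gen_observations(run, sensor_spec(noise_sd = 0), seed = 52)
  yrs <- sort(unique(as.integer(format(as.Date(obs$date), "%Y"))))
  ts <- temporal_split(run, obs, cal_years = yrs[2], val_years = yrs[3])
  expect_equal(ts$calibration$nse, rep(1, 2), tolerance = 1e-9)
  expect_equal(ts$validation$nse, rep(1, 2), tolerance = 1e-9)
  expect_error(temporal_split(run, obs, yrs[2], yrs[2]), "overlap")
  expect_error(temporal_split(run, obs, yrs[2], 1999), "absent")
})

test_that("small Monte-Carlo calibration is reproducible and ranks the truth well", {
  meteo <- gen_meteo(climate_spec(), 2, seed = 61, precip_scale = 0.6)
  profile <- gen_profile("deep_loam", seed = 61)
  mvg <- apply_ptf(profile, "wessolek")
  site <- ref_site()
  truth <- recovery_truth_defaults()
  cfg <- svatdrought:::.apply_sample(as.data.frame(truth), plant_params(),
                                     flow_params(), profile, mvg)
  run <- run_simulation(meteo, site, cfg$plant, cfg$flow, cfg$column,
                        spinup_years = 1)
  obs <- gen_observations(run, sensor_spec(noise_sd = 0), seed = 62)
  cal1 <- calibrate_site(meteo, site, profile, mvg, obs, n = 40, k = 5,
                         seed = 63)
  cal2 <- calibrate_site(meteo, site, profile, mvg, obs, n = 40, k = 5,
                         seed = 63)
  expect_identical(cal1$samples, cal2$samples)
  expect_equal(length(cal1$behavioural), 5)
  expect_true(all(is.finite(cal1$cof[cal1$behavioural])))
  # noise-free observations: the truth parameters beat every sampled run
  sc_truth <- score_against_sensors(run, obs)
  expect_lt(sc_truth$cof, min(cal1$cof))
})
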