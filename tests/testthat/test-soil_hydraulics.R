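test_that("texture classification hits the triangle vertices and is deterministic", {
  expect_identical(classify_texture(100, 0, 0), "Ss")
  expect_identical(classify_texture(0, 0, 100), "Tt")
  expect_identical(classify_texture(33, 33, 34),
                   classify_texture(33, 33, 34))
  expect_error(classify_texture(50, 30, 30), "sum")
  expect_error(classify_texture(-5, 55, 50), "within")
})

test_that("texture classification agrees with an independent rectangle lookup and covers the triangle", {
  tab <- read.csv(system.file("extdata", "ka5_texture_classes.csv",
                              package = "svatdrought"))
  # independent first-match point-in-rectangle oracle over the shipped table
  oracle <- function(clay, silt) {
    hit <- tab$class[clay >= tab$clay_lo & clay <= tab$clay_hi &
                     silt >= tab$silt_lo & silt <= tab$silt_hi]
    if (length(hit)) hit[1] else NA_character_
  }
  set.seed(7)
  for (k in 1:200) {
    clay <- runif(1, 0, 100)
    silt <- runif(1, 0, 100 - clay)
    expect_identical(classify_texture(100 - clay - silt, silt, clay),
                     oracle(clay, silt))
  }
  # full integer-grid coverage: every admissible texture maps to a class
  for (clay in seq(0, 100, by = 5))
    for (silt in seq(0, 100 - clay, by = 5))
      expect_false(is.na(oracle(clay, silt)),
                   info = paste("uncovered clay", clay, "silt", silt))
})

test_that("class-keyed PTF returns shipped rows verbatim and rejects unknown classes", {
  tab <- read.csv(system.file("extdata", "mvg_ka5_synthetic.csv",
                              package = "svatdrought"))
  for (cl in c("Ss", "Lt2", "Tt")) {
    p <- ptf_wessolek(cl)
    row <- tab[tab$class == cl, ]
    expect_equal(p$theta_r, row$theta_r)
    expect_equal(p$theta_s, row$theta_s)
    expect_equal(p$alpha, row$alpha)
    expect_equal(p$n, row$n)
    expect_equal(p$ksat, row$ksat)
  }
  for (cl in tab$class) {
    p <- ptf_wessolek(cl)
    expect_lt(p$theta_r, p$theta_s)
    expect_gt(p$n, 1)
  }
  expect_error(ptf_wessolek("XX"), "unknown")
})

test_that("regression PTF matches independent evaluation of the shipped coefficients", {
  reg <- read.csv(system.file("extdata", "ptf_regression_synthetic.csv",
                              package = "svatdrought"))
  sand <- 40; clay <- 20; bd <- 1.4; corg <- 1.5
  ev <- function(par) {
    r <- reg[reg$param == par, ]
    v <- r$intercept + r$b_sand * sand + r$b_clay * clay + r$b_bd * bd +
      r$b_corg * corg
    if (r$transform == "log10") v <- 10^v
    min(max(v, r$lower), r$upper)
  }
  p <- ptf_puhlmann(sand, clay, bd, corg)
  expect_equal(p$theta_s, ev("theta_s"), tolerance = 1e-12)
  expect_equal(p$theta_r, ev("theta_r"), tolerance = 1e-12)
  expect_equal(p$alpha, ev("alpha"), tolerance = 1e-12)
  expect_equal(p$ksat, ev("ksat"), tolerance = 1e-12)
  expect_lt(p$theta_r, p$theta_s)
  expect_identical(ptf_puhlmann(sand, clay, bd, corg),
                   ptf_puhlmann(sand, clay, bd, corg))
  expect_error(ptf_puhlmann(-10, 20, 1.4, 1), "within")
  expect_warning(ptf_puhlmann(40, 20, 0.5, 1), "validity")
})

test_that("retention curve matches the closed form at the pool boundaries", {
  p <- ref_mvg()
  expect_equal(vg_theta(0, p), p$theta_s)
  # independent closed-form evaluation, m = 1 - 1/n, h in hPa
  th <- function(psi) {
    h <- abs(psi) * 10; m <- 1 - 1 / p$n
    p$theta_r + (p$theta_s - p$theta_r) * (1 + (p$alpha * h)^p$n)^(-m)
  }
  expect_equal(vg_theta(-10, p), 0.3675, tolerance = 5e-4)
  expect_equal(vg_theta(-6.3, p), 0.3994, tolerance = 5e-4)
  expect_equal(vg_theta(-1585, p), 0.0818, tolerance = 5e-4)
  for (psi in c(-0.5, -3, -50, -700, -5000))
    expect_equal(vg_theta(psi, p), th(psi), tolerance = 1e-12)
  psis <- -10^seq(-2, 5, length.out = 40)
  expect_true(all(diff(vg_theta(psis, p)) < 0))
  # residual limit: a curve with n = 2 is within 1e-3 of theta_r at -1e6 kPa
  steep <- mvg_params(0.05, 0.45, 0.05, 2, 100)
  expect_equal(vg_theta(-1e6, steep), steep$theta_r, tolerance = 1e-3)
  expect_lt(vg_theta(-1e6, p) - p$theta_r, 2e-3)
  expect_error(vg_theta(5, p), "psi")
})

test_that("inverse retention curve round-trips", {
  p <- ref_mvg()
  expect_equal(vg_psi(p$theta_s, p), 0)
  set.seed(1)
  theta <- runif(100, p$theta_r + 1e-4, p$theta_s)
  expect_equal(vg_theta(vg_psi(theta, p), p), theta, tolerance = 1e-10)
  expect_equal(vg_psi(vg_theta(-10, p), p), -10, tolerance = 1e-8)
  expect_error(vg_psi(p$theta_r, p), "theta")
  expect_error(vg_psi(0.5, p), "theta")
})

test_that("Mualem conductivity matches its closed form and is monotone", {
  p <- ref_mvg()
  expect_equal(mualem_k(0, p), p$ksat)
  m <- 1 - 1 / p$n
  se <- (1 + (p$alpha * 100)^p$n)^(-m)         # psi = -10 kPa
  k10 <- p$ksat * se^0.5 * (1 - (1 - se^(1 / m))^m)^2
  expect_equal(mualem_k(-10, p), k10, tolerance = 1e-12)
  expect_lte(mualem_k(-100, p), mualem_k(-10, p))
  expect_true(all(diff(mualem_k(-10^seq(-1, 4, 0.5), p)) <= 0))
  expect_error(mualem_k(1, p), "psi")
})

test_that("storage capacity reproduces the worked example and its oracle", {
  prof <- ref_profile()
  sc <- storage_capacity(prof, list(ref_mvg()), 1)
  expect_equal(sc$awc, 254.1, tolerance = 1e-3)
  # gravel-free full pore space split: AWC + GWC = (theta(0)-theta(wilt))*depth
  p <- ref_mvg()
  tot <- (vg_theta(0, p) - vg_theta(-1585, p)) * 1000 * 0.8
  expect_equal(sc$awc + sc$gwc, tot, tolerance = 1e-9)
  # homogeneity: half the depth limit halves the capacity
  sc2 <- storage_capacity(prof, list(p), 0.5)
  expect_equal(sc2$awc, sc$awc / 2, tolerance = 1e-9)
  # all gravel stores nothing
  sc3 <- storage_capacity(ref_profile(gravel = 1), list(p), 1)
  expect_equal(sc3$awc, 0)
  expect_equal(sc3$gwc, 0)
  expect_warning(storage_capacity(prof, list(p), 2), "exceeds")
  gap <- rbind(ref_profile(0.4), transform(ref_profile(), top_m = 0.5,
                                           bottom_m = 1))
  expect_error(storage_capacity(gap, list(p, p), 1), "contiguous")
})

test_that("storage capacity equals fine-grid numerical integration", {
  prof <- rbind(ref_profile(0.3),
                transform(ref_profile(), top_m = 0.3, bottom_m = 0.9,
                          gravel_frac = 0.4))
  mvg <- list(ref_mvg(), mvg_params(0.08, 0.5, 0.03, 1.3, 20))
  sc <- storage_capacity(prof, mvg, 0.9)
  # oracle: 1 mm depth grid
  z <- seq(0.0005, 0.8995, by = 0.001)
  hor <- ifelse(z < 0.3, 1, 2)
  awc_o <- sum(vapply(seq_along(z), function(i) {
    p <- mvg[[hor[i]]]
    (vg_theta(-6.3, p) - vg_theta(-1585, p)) *
      (1 - prof$gravel_frac[hor[i]])
  }, numeric(1)))  # per mm slab
  expect_equal(sc$awc, awc_o, tolerance = 1e-3 * awc_o)
})

test_that("storage uncertainty propagation is seeded and degenerates correctly", {
  prof <- ref_profile()
  prof$sand_ci_lo <- prof$sand_pct; prof$sand_ci_hi <- prof$sand_pct
  prof$corg_ci_lo <- prof$corg_pct; prof$corg_ci_hi <- prof$corg_pct
  prof$gravel_ci_lo <- prof$gravel_frac
  prof$gravel_ci_hi <- prof$gravel_frac
  det <- storage_capacity(prof, apply_ptf(prof, "wessolek"), 1)
  out <- propagate_storage_uncertainty(prof, 1, n_draws = 50, seed = 1)
  expect_equal(out$awc$cv, 0)
  expect_equal(out$awc$mean, det$awc, tolerance = 1e-9)

  prof$sand_ci_lo <- prof$sand_pct - 10; prof$sand_ci_hi <- prof$sand_pct + 10
  prof$corg_ci_lo <- 0.5; prof$corg_ci_hi <- 1.5
  prof$gravel_ci_lo <- 0.1; prof$gravel_ci_hi <- 0.3
  a <- propagate_storage_uncertainty(prof, 1, n_draws = 200, seed = 3)
  b <- propagate_storage_uncertainty(prof, 1, n_draws = 200, seed = 3)
  expect_identical(a, b)
  c2 <- propagate_storage_uncertainty(prof, 1, n_draws = 200, seed = 4)
  mc_se <- a$awc$cv * a$awc$mean / sqrt(200)
  expect_lt(abs(a$awc$mean - c2$awc$mean), 3 * sqrt(2) * mc_se)
  expect_gt(a$awc$cv, 0)
  expect_lte(a$awc$ci_low, a$awc$mean)
  expect_gte(a$awc$ci_high, a$awc$mean)
  prof$sand_ci_hi <- prof$sand_ci_lo - 5
  expect_error(propagate_storage_uncertainty(prof, 1, n_draws = 10),
               "inverted")
})
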