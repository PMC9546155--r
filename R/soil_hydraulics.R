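# Soil hydraulic parameterization: texture classification, pedotransfer
# functions, Mualem-van Genuchten curves, and storage capacities.

#' Construct a Mualem-van Genuchten parameter set
#'
#' Container for the parameters of the closed-form van Genuchten retention
#' curve and Mualem conductivity model used throughout the package.
#'
#' @param theta_r Residual volumetric water content (m3/m3).
#' @param theta_s Saturated volumetric water content (m3/m3).
#' @param alpha Inverse air-entry parameter (1/hPa).
#' @param n Shape parameter (> 1, dimensionless).
#' @param ksat Saturated hydraulic conductivity (mm/day).
#' @param tau Mualem tortuosity exponent; 0.5 is the standard assumption.
#' @return An object of class `mvg_params` (named list).
#' @export
mvg_params <- function(theta_r, theta_s, alpha, n, ksat, tau = 0.5) {
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1))
    stop("require 0 <= theta_r < theta_s <= 1")
  if (alpha <= 0) stop("alpha must be > 0")
  if (n <= 1) stop("n must be > 1")
  if (ksat <= 0) stop("ksat must be > 0")
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n = n, ksat = ksat, tau = tau), class = "mvg_params")
}

#' Classify a texture into a German (KA5-style) texture class
#'
#' Classes are defined as rectangles in the clay-silt plane (the shipped
#' table `ka5_texture_classes.csv`). Boundary points belong to the class
#' listed first in the table, which makes the classification deterministic.
#'
#' @param sand,silt,clay Percent of fine earth; must sum to 100 (+/- 0.5).
#' @return Single character class code, e.g. `"Ls2"`.
#' @export
classify_texture <- function(sand, silt, clay) {
  if (any(c(sand, silt, clay) < 0) || any(c(sand, silt, clay) > 100))
    stop("texture fractions must be within [0, 100]")
  s <- sand + silt + clay
  if (abs(s - 100) > 0.5)
    stop("sand + silt + clay must sum to 100 (+/- 0.5), got ", s)
  tab <- .get_table("ka5_texture_classes.csv")
  hit <- which(clay >= tab$clay_lo & clay <= tab$clay_hi &
               silt >= tab$silt_lo & silt <= tab$silt_hi)
  if (!length(hit)) stop("no texture class matches clay=", clay, " silt=", silt)
  tab$class[hit[1]]
}

#' Tabular class-keyed pedotransfer function (Wessolek-style)
#'
#' Looks up Mualem-van Genuchten parameters for a KA5 texture class from
#' the shipped class table. The original published coefficient table is not
#' redistributed with this package; the shipped table
#' (`mvg_ka5_synthetic.csv`) is a synthetic stand-in generated from
#' class-centroid textures with a pedologically plausible regression, and
#' is clearly labelled as such.
#'
#' @param texture_class KA5 class code (see [classify_texture()]).
#' @return An [mvg_params()] object (the table row verbatim).
#' @export
ptf_wessolek <- function(texture_class) {
  tab <- .get_table("mvg_ka5_synthetic.csv")
  row <- tab[tab$class == texture_class, ]
  if (nrow(row) != 1)
    stop("unknown texture class: ", texture_class)
  mvg_params(row$theta_r, row$theta_s, row$alpha, row$n, row$ksat, row$tau)
}

#' Continuous regression pedotransfer function (Puhlmann-style)
#'
#' Predicts Mualem-van Genuchten parameters from sand, clay, bulk density
#' and organic carbon via linear regressions (log10 link for `alpha` and
#' `ksat`), with predictions clipped to physical bounds. The shipped
#' coefficient table (`ptf_regression_synthetic.csv`) is a synthetic
#' stand-in for the cited regression, labelled as such.
#'
#' @param sand,clay Percent of fine earth.
#' @param bulk_density Fine-earth bulk density (g/cm3).
#' @param corg Organic carbon (% mass).
#' @param gravel_frac Volumetric gravel fraction (0-1); carried through for
#'   interface symmetry, it does not enter the fine-earth regressions.
#' @return An [mvg_params()] object.
#' @export
ptf_puhlmann <- function(sand, clay, bulk_density, corg, gravel_frac = 0) {
  if (sand < 0 || sand > 100 || clay < 0 || clay > 100)
    stop("sand and clay must be within [0, 100]")
  if (corg < 0 || corg > 100) stop("corg must be within [0, 100]")
  if (bulk_density <= 0) stop("bulk_density must be > 0")
  if (bulk_density < 0.8 || bulk_density > 1.9 || corg > 15)
    warning("predictors outside the regression's validity range; ",
            "extrapolated prediction")
  reg <- .get_table("ptf_regression_synthetic.csv")
  ev <- function(p) {
    r <- reg[reg$param == p, ]
    v <- r$intercept + r$b_sand * sand + r$b_clay * clay +
      r$b_bd * bulk_density + r$b_corg * corg
    if (r$transform == "log10") v <- 10^v
    min(max(v, r$lower), r$upper)
  }
  n <- max(ev("n"), 1.05)
  mvg_params(ev("theta_r"), ev("theta_s"), ev("alpha"), n, ev("ksat"),
             ev("tau"))
}

.as_mvg <- function(p) {
  if (inherits(p, "mvg_params")) return(p)
  mvg_params(p$theta_r, p$theta_s, p$alpha, p$n, p$ksat,
             if (is.null(p$tau)) 0.5 else p$tau)
}

#' Water retention curve: volumetric water content at a matric potential
#'
#' theta(psi) = theta_r + (theta_s - theta_r) * (1 + (alpha*|h|)^n)^(-m)
#' with m = 1 - 1/n and h the potential in hPa (1 kPa = 10 hPa).
#'
#' @param psi Matric potential in kPa (<= 0); vectorized.
#' @param p An [mvg_params()] object.
#' @return Volumetric water content (m3/m3).
#' @export
vg_theta <- function(psi, p) {
  if (any(psi > 0)) stop("psi must be <= 0 kPa")
  p <- .as_mvg(p)
  vg_theta_cpp(as.numeric(psi), p$theta_r, p$theta_s, p$alpha, p$n)
}

#' Inverse retention curve: matric potential at a water content
#'
#' @param theta Volumetric water content, in (theta_r, theta_s].
#' @param p An [mvg_params()] object.
#' @return Matric potential in kPa (<= 0).
#' @export
vg_psi <- function(theta, p) {
  p <- .as_mvg(p)
  if (any(theta <= p$theta_r) || any(theta > p$theta_s))
    stop("theta must lie in (theta_r, theta_s]")
  vg_psi_cpp(as.numeric(theta), p$theta_r, p$theta_s, p$alpha, p$n)
}

#' Mualem unsaturated hydraulic conductivity
#'
#' K(psi) = ksat * Se^tau * (1 - (1 - Se^(1/m))^m)^2.
#'
#' @param psi Matric potential in kPa (<= 0); vectorized.
#' @param p An [mvg_params()] object.
#' @return Conductivity in mm/day.
#' @export
mualem_k <- function(psi, p) {
  if (any(psi > 0)) stop("psi must be <= 0 kPa")
  p <- .as_mvg(p)
  mualem_k_cpp(as.numeric(psi), p$theta_r, p$theta_s, p$alpha, p$n,
               p$ksat, p$tau)
}

# matric potential bounds of the storage pools (kPa)
PSI_FIELD_CAPACITY <- -6.3
PSI_WILTING <- -1585

#' Validate a soil profile table of horizons
#'
#' @param profile data.frame with columns `top_m`, `bottom_m`, `sand_pct`,
#'   `silt_pct`, `clay_pct`, `gravel_frac`, `bd_gcm3`, `corg_pct`, ordered
#'   top to bottom.
#' @return The profile, invisibly, after validation.
#' @export
validate_profile <- function(profile) {
  need <- c("top_m", "bottom_m", "sand_pct", "silt_pct", "clay_pct",
            "gravel_frac", "bd_gcm3", "corg_pct")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("profile missing columns: ", paste(miss, collapse = ", "))
  if (nrow(profile) < 1) stop("profile has no horizons")
  if (abs(profile$top_m[1]) > 1e-9) stop("first horizon must start at 0 m")
  if (any(profile$bottom_m <= profile$top_m))
    stop("each horizon needs bottom_m > top_m")
  if (nrow(profile) > 1) {
    gaps <- abs(profile$top_m[-1] - profile$bottom_m[-nrow(profile)])
    if (any(gaps > 1e-9)) stop("horizons must be contiguous (no gaps)")
  }
  tex <- profile$sand_pct + profile$silt_pct + profile$clay_pct
  if (any(abs(tex - 100) > 0.5))
    stop("sand + silt + clay must sum to 100 (+/- 0.5) in every horizon")
  if (any(profile$gravel_frac < 0 | profile$gravel_frac > 1))
    stop("gravel_frac must be within [0, 1]")
  if (any(profile$bd_gcm3 <= 0)) stop("bulk density must be > 0")
  invisible(profile)
}

#' Apply a pedotransfer function to every horizon of a profile
#'
#' @param profile A horizon table (see [validate_profile()]).
#' @param ptf `"wessolek"` (class-keyed table) or `"puhlmann"` (continuous
#'   regression).
#' @return List of [mvg_params()], one per horizon.
#' @export
apply_ptf <- function(profile, ptf = c("wessolek", "puhlmann")) {
  ptf <- match.arg(ptf)
  validate_profile(profile)
  lapply(seq_len(nrow(profile)), function(i) {
    r <- profile[i, ]
    if (ptf == "wessolek")
      ptf_wessolek(classify_texture(r$sand_pct, r$silt_pct, r$clay_pct))
    else
      ptf_puhlmann(r$sand_pct, r$clay_pct, r$bd_gcm3, r$corg_pct,
                   r$gravel_frac)
  })
}

#' Plant-available and gravitational water storage capacity of a profile
#'
#' AWC is the water held between -6.3 kPa (field capacity) and -1585 kPa
#' (wilting point); GWC is the gravitational pool between saturation and
#' -6.3 kPa. Both are corrected for the gravel fraction and truncated at
#' `depth_limit`.
#'
#' @param profile Horizon table (see [validate_profile()]).
#' @param mvg List of [mvg_params()] per horizon, e.g. from [apply_ptf()].
#' @param depth_limit Integration depth (m, > 0). If it exceeds the profile
#'   bottom, the capacity is computed to the profile bottom with a warning.
#' @return List with `awc` and `gwc` (mm) and `depth_limit` (m, effective).
#' @export
storage_capacity <- function(profile, mvg, depth_limit) {
  validate_profile(profile)
  if (depth_limit <= 0) stop("depth_limit must be > 0")
  bottom <- profile$bottom_m[nrow(profile)]
  if (depth_limit > bottom + 1e-9) {
    warning("depth_limit ", depth_limit, " m exceeds profile bottom ",
            bottom, " m; computed to profile bottom")
    depth_limit <- bottom
  }
  awc <- 0; gwc <- 0
  for (i in seq_len(nrow(profile))) {
    top <- profile$top_m[i]; bot <- min(profile$bottom_m[i], depth_limit)
    if (bot <= top) next
    p <- .as_mvg(mvg[[i]])
    th <- vg_theta(c(0, PSI_FIELD_CAPACITY, PSI_WILTING), p)
    fe <- 1 - profile$gravel_frac[i]
    thick_mm <- (bot - top) * 1000
    awc <- awc + (th[2] - th[3]) * thick_mm * fe
    gwc <- gwc + (th[1] - th[2]) * thick_mm * fe
  }
  list(awc = awc, gwc = gwc, depth_limit = depth_limit)
}

# truncated-normal draw via inverse CDF, sd from a 95% CI
.rtruncnorm <- function(nn, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, nn))
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(nn) * (phi - plo), mean, sd)
}

#' Monte-Carlo uncertainty propagation for storage capacities
#'
#' Draws sand, organic carbon and gravel per horizon from truncated normals
#' fitted to their 95% confidence intervals (sd = CI width / 3.92), with
#' clay co-varying as clay = 100 - sand - silt (silt at its mean value,
#' i.e. perfect negative sand-clay dependence), pushes each draw through
#' the chosen PTF and [storage_capacity()], and summarizes. Depth-cumulated
#' uncertainty is also combined additively (variances summed over horizons).
#'
#' @param profile Horizon table with additional CI columns `sand_ci_lo`,
#'   `sand_ci_hi`, `corg_ci_lo`, `corg_ci_hi`, `gravel_ci_lo`,
#'   `gravel_ci_hi` (95% bounds; equal bounds mean "certain").
#' @param depth_limit Integration depth (m).
#' @param ptf Pedotransfer function name, see [apply_ptf()].
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer RNG seed.
#' @return List with, for `awc` and `gwc`: `mean`, `ci_low`, `ci_high`
#'   (2.5/97.5 percentiles), `cv`, plus `sd_additive` (layer variances
#'   combined additively) and the draw matrix dimensions.
#' @export
propagate_storage_uncertainty <- function(profile, depth_limit,
                                          ptf = "wessolek",
                                          n_draws = 1000, seed = 1L) {
  validate_profile(profile)
  ci_cols <- c("sand_ci_lo", "sand_ci_hi", "corg_ci_lo", "corg_ci_hi",
               "gravel_ci_lo", "gravel_ci_hi")
  miss <- setdiff(ci_cols, names(profile))
  if (length(miss)) stop("profile missing CI columns: ",
                         paste(miss, collapse = ", "))
  for (v in c("sand", "corg", "gravel"))
    if (any(profile[[paste0(v, "_ci_hi")]] < profile[[paste0(v, "_ci_lo")]]))
      stop("inverted CI bounds for ", v)
  if (n_draws < 2) stop("n_draws must be >= 2")
  nh <- nrow(profile)
  set.seed(seed)
  awc_l <- matrix(0, n_draws, nh)  # per-layer AWC draws (mm)
  gwc_l <- matrix(0, n_draws, nh)
  for (i in seq_len(nh)) {
    r <- profile[i, ]
    sand <- .rtruncnorm(n_draws, r$sand_pct,
                        (r$sand_ci_hi - r$sand_ci_lo) / 3.92, 0, 100)
    corg <- .rtruncnorm(n_draws, r$corg_pct,
                        (r$corg_ci_hi - r$corg_ci_lo) / 3.92, 0, 100)
    gravel <- .rtruncnorm(n_draws, r$gravel_frac,
                          (r$gravel_ci_hi - r$gravel_ci_lo) / 3.92, 0, 1)
    silt <- rep(r$silt_pct, n_draws)
    clay <- pmax(0, 100 - sand - silt)
    # keep the draw on the texture simplex
    over <- sand + silt > 100
    silt[over] <- 100 - sand[over]
    top <- r$top_m; bot <- min(r$bottom_m, depth_limit)
    if (bot <= top) next
    thick_mm <- (bot - top) * 1000
    for (k in seq_len(n_draws)) {
      p <- if (ptf == "wessolek")
        ptf_wessolek(classify_texture(sand[k], silt[k], clay[k]))
      else ptf_puhlmann(sand[k], clay[k], r$bd_gcm3, corg[k], gravel[k])
      th <- vg_theta(c(0, PSI_FIELD_CAPACITY, PSI_WILTING), p)
      fe <- 1 - gravel[k]
      awc_l[k, i] <- (th[2] - th[3]) * thick_mm * fe
      gwc_l[k, i] <- (th[1] - th[2]) * thick_mm * fe
    }
  }
  awc <- rowSums(awc_l); gwc <- rowSums(gwc_l)
  summ <- function(x, xl) {
    m <- mean(x)
    list(mean = m,
         ci_low = unname(quantile(x, 0.025)),
         ci_high = unname(quantile(x, 0.975)),
         cv = if (m > 0) sd(x) / m else 0,
         sd_additive = sqrt(sum(apply(xl, 2, var))))
  }
  out <- list(awc = summ(awc, awc_l), gwc = summ(gwc, gwc_l),
              depth_limit = min(depth_limit,
                                profile$bottom_m[nh]),
              n_draws = n_draws)
  out
}
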