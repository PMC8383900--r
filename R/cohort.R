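#' Calibration targets of the synthetic cohort generator
#'
#' Bundles the published summary statistics that the cohort generator is
#' calibrated against: the standardized coefficients of the six-predictor
#' multivariate FTD model, the model multiple correlation, the marginal
#' age-FTD correlation, the per-predictor variance inflation factors, the
#' within-myopia SE-FTD correlation, the covariate marginals and the FTD
#' scale. Where a covariate's marginal moments were not published (body-mass
#' index, parapapillary atrophy area, subfoveal choroidal thickness), typical
#' values for an elderly East-Asian screening population are used; they only
#' set measurement units and do not enter any standardized-scale target.
#'
#' @param std_betas named standardized coefficients for `age`, `sex` (female
#'   indicator), `bmi`, `axial_length`, `ppa_area`, `sfct`.
#' @param target_model_R multiple correlation of the six-predictor model.
#' @param target_age_r marginal Pearson correlation of age with FTD.
#' @param target_axial_r,target_sex_r soft marginal-correlation anchors used
#'   to orient the correlation solve.
#' @param target_myopia_se_r Pearson correlation of SE with FTD within the
#'   myopic stratum.
#' @param target_vifs named variance inflation factors of the six predictors.
#' @param marginal_means_sds named list of `c(mean, sd)` per covariate.
#' @param ftd_mean,ftd_sd FTD scale (density is clipped to `[0, 1]`).
#' @param female_share proportion of women.
#' @param se_targets overall and myopic-stratum moments of spherical
#'   equivalent (diopters) used to calibrate the axial-length link.
#' @return A `generator_calibration` list.
#' @export
generator_calibration <- function(
    std_betas = c(age = 0.08, sex = -0.11, bmi = -0.06,
                  axial_length = 0.14, ppa_area = 0.09, sfct = -0.58),
    target_model_R = 0.74,
    target_age_r = 0.33,
    target_axial_r = 0.40,
    target_sex_r = -0.13,
    target_myopia_se_r = -0.25,
    target_vifs = c(age = 1.29, sex = 1.11, bmi = 1.04,
                    axial_length = 1.35, ppa_area = 1.29, sfct = 1.35),
    marginal_means_sds = list(age = c(64.1, 9.7), bmi = c(25.0, 3.5),
                              axial_length = c(23.22, 1.09),
                              ppa_area = c(1.3, 0.9), sfct = c(254, 107)),
    ftd_mean = 0.14, ftd_sd = 0.08,
    female_share = 0.564,
    se_targets = c(mean = -0.13, sd = 1.96, myopic_share = 1146 / 3074,
                   myopic_mean = -2.16, myopic_sd = 2.40)) {
  nm <- c("age", "sex", "bmi", "axial_length", "ppa_area", "sfct")
  ft_assert(identical(names(std_betas), nm) && identical(names(target_vifs), nm),
            "InvalidConfig", "std_betas and target_vifs must be named age..sfct in order")
  ft_assert(target_model_R > 0 && target_model_R < 1, "InvalidConfig",
            "target_model_R must be in (0, 1)")
  ft_assert(all(target_vifs >= 1), "InvalidConfig", "VIF targets must be >= 1")
  structure(list(std_betas = std_betas, target_model_R = target_model_R,
                 target_age_r = target_age_r, target_axial_r = target_axial_r,
                 target_sex_r = target_sex_r,
                 target_myopia_se_r = target_myopia_se_r,
                 target_vifs = target_vifs,
                 marginal_means_sds = marginal_means_sds,
                 ftd_mean = ftd_mean, ftd_sd = ftd_sd,
                 female_share = female_share, se_targets = se_targets),
            class = "generator_calibration")
}

.ft_calib_cache <- new.env(parent = emptyenv())

cal_key <- function(cal, tag) paste(tag, paste(unlist(cal[1:12]), collapse = ","))

#' Solve the predictor correlation matrix implied by the published model
#'
#' Independent predictors cannot jointly reproduce the published standardized
#' coefficients and a model multiple correlation of `target_model_R`; the
#' predictors must be correlated. This solve finds a 6 x 6 correlation matrix
#' `Sigma` such that `beta' Sigma beta` equals the target `R^2` (to 1e-3),
#' each variance inflation factor `[Sigma^-1]_jj` matches its published value
#' (to 0.05), and the implied marginal age-FTD correlation `(Sigma beta)_age`
#' matches `target_age_r` (to 0.02). The published marginal correlations of
#' axial length and sex enter as soft anchors, and a small ridge keeps the
#' solution at minimal overall correlation. The solve is deterministic.
#'
#' @param cal a [generator_calibration()]
#' @return The solved correlation matrix with a `residuals` attribute.
#' @export
calibrate_predictor_corr <- function(cal = generator_calibration()) {
  key <- cal_key(cal, "corr")
  got <- .ft_calib_cache[[key]]
  if (!is.null(got)) return(got)
  beta <- cal$std_betas
  R2 <- cal$target_model_R^2
  vt <- cal$target_vifs
  p <- 6L
  lt <- which(lower.tri(matrix(0, p, p)))
  mk <- function(th) {
    S <- diag(p); S[lt] <- th; S + t(S) - diag(diag(S))
  }
  obj <- function(th) {
    S <- mk(th)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-4) return(1e6 + 1e8 * (1e-4 - min(ev))^2)
    vif <- diag(solve(S))
    m <- drop(S %*% beta)
    1e6 * (drop(beta %*% S %*% beta) - R2)^2 +
      1e4 * sum((vif - vt)^2) +
      1e5 * (m[1] - cal$target_age_r)^2 +
      2e3 * (m[4] - cal$target_axial_r)^2 +
      5e2 * (m[2] - cal$target_sex_r)^2 +
      0.05 * sum(th^2)
  }
  fit <- stats::nlminb(rep(0, length(lt)), obj, lower = -0.95, upper = 0.95,
                       control = list(iter.max = 2000, eval.max = 4000))
  S <- mk(fit$par)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    lam <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    S <- stats::cov2cor(S)
  }
  dimnames(S) <- list(names(beta), names(beta))
  res <- list(r2_err = drop(beta %*% S %*% beta) - R2,
              vif_err = diag(solve(S)) - vt,
              age_r_err = drop(S %*% beta)[1] - cal$target_age_r)
  if (abs(res$r2_err) > 1e-3 || max(abs(res$vif_err)) > 0.05 ||
      abs(res$age_r_err) > 0.02)
    ft_stop("CalibrationFailed",
            sprintf("correlation solve residuals out of tolerance (R2 %.2e, max VIF %.3f, age r %.3f)",
                    res$r2_err, max(abs(res$vif_err)), res$age_r_err))
  attr(S, "residuals") <- res
  .ft_calib_cache[[key]] <- S
  S
}

# Latent and design layer shared by the cohort generator and the SE-link
# calibration: draws correlated latents, applies the marginal maps and
# clips, and builds the standardized design, the FTD outcome and the
# non-axial FTD residual. Must be called inside an RNG context.
cohort_core <- function(n, cal, S, Slat) {
  beta <- cal$std_betas
  fs <- cal$female_share
  Z <- matrix(stats::rnorm(n * 6L), n, 6L) %*% chol(Slat)
  mm <- cal$marginal_means_sds
  age <- pmin(pmax(mm$age[1] + mm$age[2] * Z[, 1], 50), 93)
  female <- Z[, 2] > stats::qnorm(1 - fs)
  bmi <- mm$bmi[1] + mm$bmi[2] * Z[, 3]
  axial <- pmax(mm$axial_length[1] + mm$axial_length[2] * Z[, 4], 15)
  ppa <- pmax(mm$ppa_area[1] + mm$ppa_area[2] * Z[, 5], 0)
  sfct <- pmax(mm$sfct[1] + mm$sfct[2] * Z[, 6], 0)
  X <- cbind(age = scale(age)[, 1], sex = scale(as.numeric(female))[, 1],
             bmi = scale(bmi)[, 1], axial_length = scale(axial)[, 1],
             ppa_area = scale(ppa)[, 1], sfct = scale(sfct)[, 1])
  R2 <- cal$target_model_R^2
  ftd_z <- drop(X %*% beta) + stats::rnorm(n, 0, sqrt(1 - R2))
  ftd <- pmin(pmax(cal$ftd_mean + cal$ftd_sd * ftd_z, 0), 1)
  c_af <- drop(S %*% beta)[4]
  e_perp <- (ftd_z - c_af * X[, "axial_length"]) / sqrt(1 - c_af^2)
  list(age = age, female = female, bmi = bmi, axial = axial, ppa = ppa,
       sfct = sfct, X = X, ftd = ftd, e_perp = e_perp,
       z_se = stats::rnorm(n))
}

se_from_link <- function(link, core) {
  eps <- link$s1 * (link$rr * core$e_perp +
                      sqrt(1 - link$rr^2) * core$z_se)
  pmin(pmax(link$a + link$b * core$X[, "axial_length"] -
              link$k * exp(link$d * core$X[, "axial_length"]) + eps,
            -20), 13.5)
}

# sex-latent inflation to offset dichotomization attenuation, plus a PSD
# repair of the adjusted latent correlation matrix
latent_corr <- function(cal, S) {
  fs <- cal$female_share
  atten <- stats::dnorm(stats::qnorm(1 - fs)) / sqrt(fs * (1 - fs))
  Slat <- S
  Slat[2, -2] <- pmin(pmax(S[2, -2] / atten, -0.99), 0.99)
  Slat[-2, 2] <- Slat[2, -2]
  ev <- eigen(Slat, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    Slat <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
    Slat <- stats::cov2cor(Slat)
  }
  Slat
}

# Calibrate the spherical-equivalent model
#   SE = a + b*z_AL - k*exp(d*z_AL) + s1*(rr*e_perp + sqrt(1-rr^2)*z)
# (clipped to the clinically observed [-20, 13.5] D) against the published SE
# moments and the within-myopia SE-FTD correlation, by simulated moments on a
# fixed common-random-numbers draw. The exponential term carries the
# curvilinear axial-myopia tail; rr couples the residual to the non-axial
# part of FTD (shared choroidal factors).
calibrate_se_link <- function(cal, S, Slat) {
  key <- cal_key(cal, "se")
  got <- .ft_calib_cache[[key]]
  if (!is.null(got)) return(got)
  tg <- cal$se_targets
  core <- with_local_seed(20210818, cohort_core(100000L, cal, S, Slat))
  moments <- function(par) {
    link <- list(a = par[1], b = par[2], k = exp(par[3]), d = exp(par[4]),
                 s1 = exp(par[5]), rr = tanh(par[6]))
    se <- se_from_link(link, core)
    my <- se < -0.25
    c(mean(se), stats::sd(se), mean(my), mean(se[my]), stats::sd(se[my]),
      stats::cor(se[my], core$ftd[my]))
  }
  targ <- c(tg["mean"], tg["sd"], tg["myopic_share"], tg["myopic_mean"],
            tg["myopic_sd"], cal$target_myopia_se_r)
  wt <- c(20, 3, 40, 40, 2, 4000)
  obj <- function(par) sum(wt * (moments(par) - targ)^2)
  st <- c(0.7, -0.6, log(0.3), log(1.1), log(0.85), atanh(-0.2))
  o1 <- stats::optim(st, obj, method = "Nelder-Mead",
                     control = list(maxit = 4000, reltol = 1e-12))
  fit <- stats::nlminb(o1$par, obj, control = list(iter.max = 2000, eval.max = 4000))
  mo <- moments(fit$par)
  if (abs(mo[6] - cal$target_myopia_se_r) > 0.03)
    ft_stop("CalibrationFailed",
            sprintf("SE link: myopic correlation %.3f misses target %.3f", mo[6],
                    cal$target_myopia_se_r))
  par <- fit$par
  out <- list(a = par[1], b = par[2], k = exp(par[3]), d = exp(par[4]),
              s1 = exp(par[5]), rr = tanh(par[6]), achieved = mo)
  .ft_calib_cache[[key]] <- out
  out
}

#' Generate a calibrated synthetic cohort
#'
#' Draws one latent standard-normal 6-vector per subject with the solved
#' correlation structure (the sex entry inflated to offset dichotomization
#' attenuation), maps each latent to its covariate scale, thresholds the sex
#' latent at the published female share, and sets
#' `FTD = X beta + sqrt(1 - R^2) * noise` on the standardized design scale
#' before rescaling to the published FTD mean/SD and clipping to `[0, 1]`.
#' Spherical equivalent is drawn from the calibrated axial-length link;
#' `se = sphere + cylinder / 2` holds exactly.
#'
#' @param n cohort size (>= 50; moment checks are meaningless below that).
#' @param cal a [generator_calibration()]
#' @param seed RNG seed.
#' @return A data frame with columns
#'   `age, sex, bmi, axial_length, ppa_area, sfct, sphere, cylinder, se, ftd`.
#' @export
generate_cohort <- function(n, cal = generator_calibration(), seed = 1L) {
  if (n < 50) ft_stop("CohortTooSmall", "n must be at least 50")
  S <- calibrate_predictor_corr(cal)
  Slat <- latent_corr(cal, S)
  selink <- calibrate_se_link(cal, S, Slat)
  with_local_seed(seed, {
    core <- cohort_core(n, cal, S, Slat)
    se <- se_from_link(selink, core)
    cyl <- -abs(stats::rnorm(n, 0.3, 0.3))
    data.frame(age = core$age,
               sex = ifelse(core$female, "female", "male"), bmi = core$bmi,
               axial_length = core$axial, ppa_area = core$ppa,
               sfct = core$sfct, sphere = se - cyl / 2, cylinder = cyl,
               se = se, ftd = core$ftd, stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort table CSV
#'
#' The on-disk format has the fixed header
#' `age,sex,bmi,axial_length,ppa_area,sfct,sphere,cylinder,se,ftd` with
#' `sex` coded `male` / `female`.
#'
#' @param cohort a cohort data frame
#' @param path CSV path
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "bmi", "axial_length", "ppa_area", "sfct",
            "sphere", "cylinder", "se", "ftd")
  ft_assert(all(need %in% names(x)), "InvalidConfig",
            "cohort CSV is missing required columns")
  x
}
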