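#' @keywords internal
# numeric design column for a predictor; 2-level character/factor columns
# become 0/1 indicators. Sex is coded female = 1 (the convention of the
# calibrated generator); any other binary column codes its alphabetically
# second level as 1.
design_column <- function(x, name) {
  if (is.character(x) || is.factor(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) > 2)
      ft_stop("InvalidConfig", sprintf("predictor '%s' has > 2 levels", name))
    one <- if (setequal(lev, c("female", "male"))) "female" else lev[min(2, length(lev))]
    x <- as.numeric(as.character(x) == one)
  }
  as.numeric(x)
}

#' Univariate regression screen
#'
#' Fits a separate simple linear regression of the outcome on each candidate
#' predictor and reports the unstandardized coefficient, the standardized
#' coefficient (equal to the Pearson correlation in the simple-regression
#' case), its 95% confidence interval and p-value. This is the first-stage
#' screen of the published analysis; arbitrary extra columns can be screened.
#'
#' @param cohort a cohort data frame
#' @param outcome outcome column name (default `"ftd"`)
#' @param predictors character vector of predictor columns (default: all
#'   other columns)
#' @return A data frame with one row per predictor: `predictor`, `b`,
#'   `beta`, `ci_lo`, `ci_hi`, `p`.
#' @export
univariate_screen <- function(cohort, outcome = "ftd",
                              predictors = setdiff(names(cohort), outcome)) {
  y <- as.numeric(cohort[[outcome]])
  rows <- lapply(predictors, function(nm) {
    x <- design_column(cohort[[nm]], nm)
    if (length(unique(x)) < 2)
      ft_stop("ConstantPredictor", sprintf("predictor '%s' is constant", nm))
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)["x", ]
    data.frame(predictor = nm, b = sm["x", 1],
               beta = sm["x", 1] * stats::sd(x) / stats::sd(y),
               ci_lo = ci[1], ci_hi = ci[2], p = sm["x", 4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# VIFs of an lm fit: diagonal of the inverse design correlation matrix
model_vifs <- function(X) {
  if (ncol(X) == 1) return(stats::setNames(1, colnames(X)))
  diag(solve(stats::cor(X)))
}

#' Stepwise multivariate regression with VIF pruning
#'
#' Reproduces the two-stage model reduction of the published analysis:
#' (a) while any predictor's variance inflation factor exceeds `vif_max`,
#' remove the predictor with the largest VIF (collinearity pruning);
#' (b) backward-eliminate the predictor with the largest p-value while any
#' p-value exceeds `alpha`. The final model is reported with per-term
#' unstandardized and standardized coefficients, 95% confidence intervals,
#' p-values and VIFs, plus the model multiple correlation.
#'
#' @param cohort a cohort data frame
#' @param candidates candidate predictor columns
#' @param outcome outcome column (default `"ftd"`)
#' @param vif_max collinearity threshold (default 3)
#' @param alpha significance threshold for retention (default 0.05)
#' @return A `regression_report`: list with `terms` (per-term data frame),
#'   `model_r`, `n` and a `steps` log of removals.
#' @export
multivariate_stepwise <- function(cohort, candidates, outcome = "ftd",
                                  vif_max = 3, alpha = 0.05) {
  ft_assert(all(candidates %in% names(cohort)), "InvalidConfig",
            "all candidates must be cohort columns")
  y <- as.numeric(cohort[[outcome]])
  X <- sapply(candidates, function(nm) design_column(cohort[[nm]], nm))
  colnames(X) <- candidates
  steps <- character(0)
  repeat {  # (a) collinearity pruning
    v <- model_vifs(X)
    if (max(v) <= vif_max) break
    drop <- names(which.max(v))
    steps <- c(steps, sprintf("vif: dropped %s (VIF %.2f)", drop, max(v)))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
    if (ncol(X) == 0) ft_stop("EmptyModel", "all candidates eliminated by VIF pruning")
  }
  repeat {  # (b) backward elimination on p-values
    fit <- stats::lm(y ~ X)
    sm <- summary(fit)$coefficients
    pv <- sm[-1, 4]
    names(pv) <- colnames(X)
    if (max(pv) <= alpha) break
    drop <- names(which.max(pv))
    steps <- c(steps, sprintf("p: dropped %s (p %.3f)", drop, max(pv)))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
    if (ncol(X) == 0) ft_stop("EmptyModel", "all candidates eliminated")
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)[-1, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  terms <- data.frame(predictor = colnames(X), b = sm[-1, 1],
                      beta = sm[-1, 1] * sds / stats::sd(y),
                      ci_lo = ci[, 1], ci_hi = ci[, 2], p = sm[-1, 4],
                      vif = as.numeric(model_vifs(X)))
  rownames(terms) <- NULL
  structure(list(terms = terms, model_r = sqrt(summary(fit)$r.squared),
                 n = length(y), steps = steps),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Multivariate model: R = %.3f, n = %d\n", x$model_r, x$n))
  print(x$terms, digits = 3)
  if (length(x$steps)) cat("Steps:", paste(x$steps, collapse = "; "), "\n")
  invisible(x)
}

#' Stratified FTD summaries
#'
#' Reports (i) FTD by decade of age (50-59, 60-69, >= 70) with a one-way
#' ANOVA across groups, (ii) FTD by sex with a two-sample t-test, and
#' (iii) FTD and SE by refractive status with the within-stratum Pearson
#' correlation of SE and FTD. Refraction classes use strict cut-offs: myopia
#' SE < -0.25 D, hypermetropia SE > +0.25 D, emmetropia otherwise (an SE of
#' exactly -0.25 D is emmetropic); every subject falls in exactly one class.
#' An empty stratum is reported with `n = 0` and missing statistics.
#'
#' @param cohort a cohort data frame
#' @return A list with `age_groups` (+ `anova_f`, `anova_p`), `sex`
#'   (+ `t`, `t_p`) and `refraction` data frames.
#' @export
stratified_summaries <- function(cohort) {
  ft_assert(nrow(cohort) > 0, "InvalidConfig", "cohort is empty")
  grp <- cut(cohort$age, c(-Inf, 60, 70, Inf), right = FALSE,
             labels = c("50-59", "60-69", ">=70"))
  agg <- function(sel, val) {
    n <- sum(sel)
    data.frame(n = as.integer(n), mean = if (n) mean(val[sel]) else NA_real_,
               sd = if (n > 1) stats::sd(val[sel]) else NA_real_)
  }
  age_tab <- do.call(rbind, lapply(levels(grp), function(g) agg(grp == g, cohort$ftd)))
  age_groups <- cbind(group = levels(grp), age_tab)
  av <- summary(stats::aov(ftd ~ grp, data = cbind(cohort, grp = grp)))[[1]]
  sex_tab <- do.call(rbind, lapply(c("male", "female"),
                                   function(s) agg(cohort$sex == s, cohort$ftd)))
  sexes <- cbind(sex = c("male", "female"), sex_tab)
  tt <- stats::t.test(ftd ~ sex, data = cohort)
  refr <- ifelse(cohort$se < -0.25, "myopia",
                 ifelse(cohort$se > 0.25, "hypermetropia", "emmetropia"))
  ref_rows <- lapply(c("emmetropia", "hypermetropia", "myopia"), function(cl) {
    sel <- refr == cl
    n <- sum(sel)
    r <- p <- NA_real_
    if (n >= 3 && stats::sd(cohort$se[sel]) > 0) {
      ct <- stats::cor.test(cohort$se[sel], cohort$ftd[sel])
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(class = cl, n = as.integer(n),
               ftd_mean = if (n) mean(cohort$ftd[sel]) else NA_real_,
               ftd_sd = if (n > 1) stats::sd(cohort$ftd[sel]) else NA_real_,
               se_mean = if (n) mean(cohort$se[sel]) else NA_real_,
               se_sd = if (n > 1) stats::sd(cohort$se[sel]) else NA_real_,
               r = r, p = p)
  })
  list(age_groups = age_groups,
       anova_f = av[1, "F value"], anova_p = av[1, "Pr(>F)"],
       sex = sexes, t = unname(tt$statistic), t_p = tt$p.value,
       refraction = do.call(rbind, ref_rows))
}
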