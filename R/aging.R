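#' Mixed-effects model of sSNV density versus age
#'
#' Fits `y_ij = beta * age_j + mu + theta_j + eps_ij` by maximum likelihood,
#' with a Gaussian random intercept per donor. The age effect p-value comes
#' from a likelihood-ratio test against the `beta = 0` submodel; the
#' confidence interval for `beta` is Wald-based.
#'
#' @param density per-cell sSNV density (sSNV per Mb), the outcome
#' @param age per-cell donor age (years)
#' @param donor per-cell donor identifier
#' @param conf_level confidence level for the slope interval
#' @return list of class `aging_fit`: `beta`, `mu`, `ci` (for beta),
#'   `p_age` (LRT), `tau` (donor s.d.), `sigma` (residual s.d.), `loglik`,
#'   `n_cells`, `n_donors`, and the `lme4` fit in `$model`
#' @export
fit_age_model <- function(density, age, donor, conf_level = 0.95) {
  d <- data.frame(y = density, age = age, donor = factor(donor))
  d <- d[complete.cases(d), ]
  if (length(unique(d$donor)) < 3) stop_invalid("need >= 3 donors")
  if (length(unique(d$age)) < 2) stop_invalid("all donor ages are equal")
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (nlevels(droplevels(d$donor)) >= nrow(d)) {
    # one cell per donor: the donor variance is unidentifiable and the ML
    # fit degenerates to ordinary least squares
    fit <- lm(y ~ age, data = d)
    fit0 <- lm(y ~ 1, data = d)
    lrt_p <- pchisq(2 * (as.numeric(logLik(fit)) - as.numeric(logLik(fit0))),
                    df = 1, lower.tail = FALSE)
    beta <- unname(coef(fit)[["age"]])
    se <- sqrt(diag(stats::vcov(fit)))[["age"]]
    return(structure(list(beta = beta, mu = unname(coef(fit)[[1]]),
                          se = se, ci = c(beta - z * se, beta + z * se),
                          p_age = lrt_p, tau = 0,
                          sigma = summary(fit)$sigma,
                          loglik = as.numeric(logLik(fit)),
                          n_cells = nrow(d),
                          n_donors = length(unique(d$donor)),
                          model = fit),
                     class = "aging_fit"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ age + (1 | donor), data = d, REML = FALSE)))
  fit0 <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | donor), data = d, REML = FALSE)))
  lrt <- anova(fit0, fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[["age"]])
  beta <- lme4::fixef(fit)[["age"]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(beta = beta, mu = lme4::fixef(fit)[["(Intercept)"]],
                 se = se, ci = c(beta - z * se, beta + z * se),
                 p_age = lrt$`Pr(>Chisq)`[2],
                 tau = sqrt(vc$vcov[vc$grp == "donor"]),
                 sigma = sqrt(vc$vcov[vc$grp == "Residual"]),
                 loglik = as.numeric(logLik(fit)),
                 n_cells = nrow(d), n_donors = length(unique(d$donor)),
                 model = fit),
            class = "aging_fit")
}

#' @export
print.aging_fit <- function(x, ...) {
  cat(sprintf(
    "Age slope: %.4g sSNV/Mb/yr (95%% CI %.4g..%.4g), intercept %.4g, LRT p = %.3g\n",
    x$beta, x$ci[1], x$ci[2], x$mu, x$p_age))
  cat(sprintf("  %d cells, %d donors; tau = %.3g, sigma = %.3g\n",
              x$n_cells, x$n_donors, x$tau, x$sigma))
  invisible(x)
}

#' Age x cell-type interaction model
#'
#' Fits `y_ijk = (beta + gamma_k) * age_j + mu + theta_jk + eps_ijk` by
#' maximum likelihood, with a random intercept per donor-cell-type pair and
#' a common intercept. Reports per-type slopes (`beta + gamma_k`), the LRT
#' p-value for any slope difference, and pairwise slope-difference LRTs.
#'
#' @param density,age,donor as in [fit_age_model()]
#' @param cell_type per-cell type labels (>= 2 types)
#' @param conf_level confidence level for per-type slope intervals
#' @return list of class `aging_interaction_fit`: `slopes` (data.frame with
#'   per-type slope, se, ci), `p_interaction`, `pairwise` (data.frame of
#'   slope-difference LRT p-values), `loglik`, `model`
#' @export
fit_interaction_model <- function(density, age, donor, cell_type,
                                  conf_level = 0.95) {
  d <- data.frame(y = density, age = age, donor = factor(donor),
                  ct = factor(cell_type))
  d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$ct)) < 2) stop_invalid("need >= 2 cell types")
  d$ct <- droplevels(d$ct)
  for (lev in levels(d$ct)) {
    if (length(unique(d$donor[d$ct == lev])) < 2)
      warning("cell type ", lev, " has a single donor")
  }
  d$dct <- interaction(d$donor, d$ct, drop = TRUE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ age:ct + (1 | dct), data = d, REML = FALSE)))
  fit_eq <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ age + (1 | dct), data = d, REML = FALSE)))
  p_int <- anova(fit_eq, fit)$`Pr(>Chisq)`[2]
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  nm <- paste0("age:ct", levels(d$ct))
  z <- qnorm(1 - (1 - conf_level) / 2)
  slopes <- data.frame(cell_type = levels(d$ct),
                       slope = fe[nm],
                       se = sqrt(diag(V)[nm]))
  slopes$ci_lo <- slopes$slope - z * slopes$se
  slopes$ci_hi <- slopes$slope + z * slopes$se
  rownames(slopes) <- NULL
  pairs <- utils::combn(levels(d$ct), 2)
  pw <- NULL
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d2 <- d
    # merge the pair's slopes, keep the others free
    d2$ct_merged <- as.character(d2$ct)
    d2$ct_merged[d2$ct_merged %in% c(a, b)] <- paste(a, b, sep = "+")
    d2$ct_merged <- factor(d2$ct_merged)
    fm <- if (nlevels(d2$ct_merged) > 1) y ~ age:ct_merged + (1 | dct)
          else y ~ age + (1 | dct)
    fit_m <- suppressMessages(suppressWarnings(lme4::lmer(fm, data = d2, REML = FALSE)))
    p <- pchisq(2 * (as.numeric(logLik(fit)) - as.numeric(logLik(fit_m))),
                df = 1, lower.tail = FALSE)
    pw <- rbind(pw, data.frame(type_a = a, type_b = b, p = p))
  }
  structure(list(slopes = slopes, p_interaction = p_int, pairwise = pw,
                 loglik = as.numeric(logLik(fit)), model = fit),
            class = "aging_interaction_fit")
}

#' @export
print.aging_interaction_fit <- function(x, ...) {
  cat("Per-type age slopes (sSNV/Mb/yr):\n")
  print(x$slopes, row.names = FALSE)
  cat(sprintf("Interaction LRT p = %.3g\n", x$p_interaction))
  invisible(x)
}

#' Age model with confounder covariates
#'
#' Refits the donor-random-intercept age model with additional per-cell
#' fixed-effect covariates (e.g. MAPD, CoV, depth, PMI). Cells with missing
#' covariates are dropped with a warning; a covariate nearly collinear with
#' age (|r| > 0.99) triggers a warning.
#'
#' @param density,age,donor as in [fit_age_model()]
#' @param covariates data.frame of per-cell covariates
#' @return `aging_fit` (adjusted age slope and LRT p), plus
#'   `covariate_coefs`
#' @export
add_covariates <- function(density, age, donor, covariates) {
  covariates <- as.data.frame(covariates)
  d <- data.frame(y = density, age = age, donor = factor(donor), covariates)
  keep <- complete.cases(d)
  if (any(!keep)) {
    warning(sum(!keep), " cell(s) dropped for missing covariates")
    d <- d[keep, ]
  }
  for (nm in names(covariates)) {
    if (sd(d[[nm]]) > 0 && abs(cor(d[[nm]], d$age)) > 0.99)
      warning("covariate ", nm, " is collinear with age")
  }
  rhs <- paste(c("age", names(covariates)), collapse = " + ")
  f1 <- stats::as.formula(paste("y ~", rhs, "+ (1 | donor)"))
  f0 <- stats::as.formula(paste("y ~", paste(names(covariates), collapse = " + "),
                                "+ (1 | donor)"))
  fit <- suppressMessages(suppressWarnings(lme4::lmer(f1, data = d, REML = FALSE)))
  fit0 <- suppressMessages(suppressWarnings(lme4::lmer(f0, data = d, REML = FALSE)))
  lrt <- anova(fit0, fit)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[["age"]])
  beta <- fe[["age"]]
  structure(list(beta = beta, mu = fe[["(Intercept)"]], se = se,
                 ci = c(beta - 1.96 * se, beta + 1.96 * se),
                 p_age = lrt$`Pr(>Chisq)`[2],
                 covariate_coefs = fe[names(covariates)],
                 loglik = as.numeric(logLik(fit)),
                 n_cells = nrow(d), n_donors = length(unique(d$donor)),
                 tau = NA_real_, sigma = NA_real_, model = fit),
            class = "aging_fit")
}
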