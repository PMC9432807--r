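test_that("noiseless linear data is interpolated exactly", {
  ages <- rep(c(1, 10, 50, 80), each = 3)
  donors <- rep(paste0("D", 1:4), each = 3)
  y <- 0.01 * ages + 0.1
  fit <- fit_age_model(y, ages, donors)
  expect_equal(fit$beta, 0.01, tolerance = 1e-8)
  expect_equal(fit$mu, 0.1, tolerance = 1e-8)
})

test_that("with one cell per donor the fit reduces to ordinary least squares", {
  set.seed(2)
  ages <- c(1, 5, 20, 35, 50, 62, 75, 82)
  y <- 0.01 * ages + 0.1 + rnorm(8, 0, 0.05)
  fit <- fit_age_model(y, ages, paste0("D", 1:8))
  ols <- lm(y ~ ages)
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-4)
  expect_equal(fit$mu, unname(coef(ols)[1]), tolerance = 1e-4)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_age_model(1:4, c(5, 5, 5, 5), paste0("D", 1:4)), "equal")
  expect_error(fit_age_model(1:4, 1:4, c("a", "a", "b", "b")), "3 donors")
})

test_that("slope coverage holds across simulated cohorts", {
  # direct simulation from the generative mixed model (12 donors x 4 cells)
  donors <- default_donors()
  cover <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    theta <- rnorm(12, 0, 0.05)
    d <- do.call(rbind, lapply(1:12, function(j)
      data.frame(donor = donors$donor_id[j], age = donors$age[j],
                 y = 0.1 + 0.010 * donors$age[j] + theta[j] +
                   rnorm(4, 0, 0.15))))
    fit <- fit_age_model(d$y, d$age, d$donor)
    if (fit$ci[1] <= 0.010 && fit$ci[2] >= 0.010) cover <- cover + 1
  }
  expect_gte(cover, 18)
})

test_that("interaction model recovers distinct per-type slopes", {
  donors <- default_donors()
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    mk <- function(ct, slope) do.call(rbind, lapply(1:12, function(j)
      data.frame(donor = donors$donor_id[j], age = donors$age[j], ct = ct,
                 y = 0.1 + slope * donors$age[j] + rnorm(1, 0, 0.05) +
                   rnorm(3, 0, 0.15))))
    d <- rbind(mk("cardiomyocyte", 0.010), mk("neuron", 0.003))
    fit <- fit_interaction_model(d$y, d$age, d$donor, d$ct)
    sl <- fit$slopes
    ratio_hat <- sl$slope[sl$cell_type == "cardiomyocyte"] /
      sl$slope[sl$cell_type == "neuron"]
    # delta-method CI on the ratio via the neuron slope CI
    i <- sl$cell_type == "neuron"
    if (sl$ci_lo[i] <= 0.003 && sl$ci_hi[i] >= 0.003 &&
        ratio_hat > 1.5) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("identical cell types show no spurious interaction", {
  donors <- default_donors()
  sig <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    mk <- function(ct) do.call(rbind, lapply(1:12, function(j)
      data.frame(donor = donors$donor_id[j], age = donors$age[j], ct = ct,
                 y = 0.1 + 0.008 * donors$age[j] + rnorm(1, 0, 0.05) +
                   rnorm(3, 0, 0.15))))
    d <- rbind(mk("typeA"), mk("typeB"))
    fit <- fit_interaction_model(d$y, d$age, d$donor, d$ct)
    if (fit$p_interaction < 0.05) sig <- sig + 1
  }
  expect_lte(sig, 2)    # about the nominal 5% false-positive rate
})

test_that("slopes are invariant to relabeling the reference cell type", {
  donors <- default_donors()
  set.seed(77)
  mk <- function(ct, slope) do.call(rbind, lapply(1:12, function(j)
    data.frame(donor = donors$donor_id[j], age = donors$age[j], ct = ct,
               y = 0.1 + slope * donors$age[j] + rnorm(2, 0, 0.1))))
  d <- rbind(mk("aaa", 0.01), mk("zzz", 0.003))
  f1 <- fit_interaction_model(d$y, d$age, d$donor, d$ct)
  d2 <- d; d2$ct <- factor(d2$ct, levels = c("zzz", "aaa"))
  f2 <- fit_interaction_model(d2$y, d2$age, d2$donor, d2$ct)
  s1 <- f1$slopes[order(f1$slopes$cell_type), ]
  s2 <- f2$slopes[order(f2$slopes$cell_type), ]
  expect_equal(s1$slope, s2$slope, tolerance = 1e-6)
})

test_that("independent covariates leave the age effect essentially unchanged", {
  donors <- default_donors()
  set.seed(88)
  d <- do.call(rbind, lapply(1:12, function(j)
    data.frame(donor = donors$donor_id[j], age = donors$age[j],
               y = 0.1 + 0.01 * donors$age[j] + rnorm(4, 0, 0.1))))
  covs <- data.frame(mapd = runif(nrow(d)), cov = runif(nrow(d)))
  base <- fit_age_model(d$y, d$age, d$donor)
  adj <- add_covariates(d$y, d$age, d$donor, covs)
  expect_lt(abs(adj$beta - base$beta), 2 * base$se)
  expect_lt(adj$p_age, 0.05)
})

test_that("a covariate equal to age triggers a collinearity warning", {
  donors <- default_donors()
  set.seed(89)
  d <- do.call(rbind, lapply(1:12, function(j)
    data.frame(donor = donors$donor_id[j], age = donors$age[j],
               y = 0.1 + 0.01 * donors$age[j] + rnorm(2, 0, 0.1))))
  expect_warning(add_covariates(d$y, d$age, d$donor,
                                data.frame(copy_age = d$age)),
                 "collinear")
})

test_that("likelihood-ratio p-values are approximately uniform under the null", {
  donors <- default_donors()
  ps <- vapply(1:200, function(s) {
    set.seed(600 + s)
    d <- do.call(rbind, lapply(1:12, function(j)
      data.frame(donor = donors$donor_id[j], age = donors$age[j],
                 y = 0.5 + rnorm(1, 0, 0.05) + rnorm(3, 0, 0.15))))
    fit_age_model(d$y, d$age, d$donor)$p_age
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
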