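test_that("noise-free linear data is recovered exactly", {
  co <- small_cohort(15, 15, 0, seed = 70,
                     gspec = growth_spec(scheme = "linear", residual_sd = 0))
  f <- fit_lgcm(co, lgcm_spec("linear", sex_adjustment = "never",
                              adjust_within_wave_age = FALSE))
  tr <- attr(co, "truth")
  expect_equal(unname(f$alpha["intercept"]), mean(tr$eta0), tolerance = 1e-3)
  expect_equal(unname(f$alpha["slope"]), mean(tr$eta1), tolerance = 1e-3)
  expect_lt(max(f$Theta), 2e-4)     # residual variances collapse to the floor
  gf <- extract_growth_factors(f)
  expect_equal(gf$intercept, tr$eta0, tolerance = 1e-2)
  expect_equal(gf$slope, tr$eta1, tolerance = 1e-2)
})

test_that("FIML equals the direct multivariate-normal log-likelihood on complete data", {
  co <- small_cohort(25, 25, 0, seed = 71)
  f <- fit_lgcm(co, lgcm_spec("logarithmic", sex_adjustment = "never",
                              adjust_within_wave_age = FALSE))
  Y <- f$data$Y
  expect_true(all(!is.na(Y)))
  lam <- f$loadings
  Lmb <- cbind(1, lam)
  Sigma <- Lmb %*% f$Psi %*% t(Lmb) + diag(f$Theta, 4)
  mu <- matrix(f$alpha["intercept"] + lam * f$alpha["slope"], nrow(Y), 4,
               byrow = TRUE)
  expect_equal(f$loglik, mvn_loglik(Y, mu, Sigma), tolerance = 1e-8 * abs(f$loglik))
})

test_that("missing waves are handled by observed-pattern likelihood", {
  co <- small_cohort(40, 40, 0, seed = 72)
  co$bmi_2[1:30] <- NA
  co$bmi_4[31:50] <- NA
  f <- fit_lgcm(co, lgcm_spec("logarithmic", sex_adjustment = "never"))
  expect_true(f$converged)
  expect_equal(f$n_used, nrow(co))
  gf <- extract_growth_factors(f)
  expect_false(anyNA(gf$slope))
  ## factor scores still track the truth
  tr <- attr(co, "truth")
  expect_gt(cor(gf$slope, tr$eta1), 0.85)
})

test_that("auto sex adjustment keeps sex on the slope only when only the slope differs", {
  co <- small_cohort(120, 180, 0, seed = 73,
                     gspec = growth_spec(slope_mean_by_sex = c(M = 2.3, F = 2.0)))
  f <- fit_lgcm(co, lgcm_spec("logarithmic", sex_adjustment = "auto"))
  expect_false(f$terms$sex_int)
  expect_true(f$terms$sex_slo)
  expect_gt(f$sex_p[["intercept"]], 0.05)
  expect_lt(f$sex_p[["slope"]], 0.001)
})

test_that("fit indices follow their defining formulas at the boundary cases", {
  co <- small_cohort(40, 40, 0, seed = 74)
  f <- fit_lgcm(co, lgcm_spec("logarithmic", sex_adjustment = "never"))
  ix <- fit_indices(f)
  ## perfect-fit limit: chi2 = df implies RMSEA 0, CFI 1
  f2 <- f
  f2$chi2 <- f2$df
  ix2 <- fit_indices(f2)
  expect_equal(ix2$rmsea, 0)
  expect_equal(ix2$cfi, 1)
  ## worst case: model no better than baseline
  f3 <- f
  f3$chi2 <- f3$chi2_base; f3$df <- f3$df_base
  ix3 <- fit_indices(f3)
  expect_equal(ix3$cfi, 0)
  ## hand recomputation of the generic case
  expect_equal(ix$cfi,
               1 - max(ix$chi2 - ix$df, 0) /
                 max(ix$chi2_baseline - ix$df_baseline, ix$chi2 - ix$df, 0))
  expect_equal(ix$rmsea,
               sqrt(max(ix$chi2 - ix$df, 0) / (ix$df * (f$n_used - 1))))
  expect_true(ix$rmsea_ci[1] <= ix$rmsea && ix$rmsea <= ix$rmsea_ci[2])
})

test_that("scheme selection is a pure function of the two index sets", {
  mk <- function(rmsea, cfi, tli) {
    structure(list(chi2 = 1, df = 1, chi2_baseline = 10, df_baseline = 1,
                   cfi = cfi, tli = tli, rmsea = rmsea,
                   rmsea_ci = c(0, 1), rmsea_defined = TRUE),
              class = "fit_indices")
  }
  good <- mk(0.03, 0.99, 0.98)
  bad <- mk(0.09, 0.93, 0.92)
  worse <- mk(0.2, 0.8, 0.8)
  expect_equal(select_scheme(good, good), list(scheme = "linear", good_fit = TRUE))
  expect_equal(select_scheme(bad, good), list(scheme = "logarithmic", good_fit = TRUE))
  expect_equal(select_scheme(bad, worse), list(scheme = "linear", good_fit = FALSE))
  expect_equal(select_scheme(worse, bad), list(scheme = "logarithmic", good_fit = FALSE))
})

test_that("log-scheme data fits the log model well and the linear model poorly", {
  co <- small_cohort(120, 180, 0, seed = 75)
  ix_log <- fit_indices(fit_lgcm(co, lgcm_spec("logarithmic")))
  ix_lin <- fit_indices(fit_lgcm(co, lgcm_spec("linear")))
  expect_lt(ix_log$rmsea, 0.06)
  expect_gt(ix_lin$rmsea, ix_log$rmsea)
  expect_equal(select_scheme(ix_lin, ix_log)$scheme, "logarithmic")
})

test_that("cluster-robust covariance behaves at the i.i.d. and duplication limits", {
  co <- small_cohort(0, 0, 150, seed = 76)
  f <- fit_lgcm(co, lgcm_spec("logarithmic", sex_adjustment = "never"))
  H <- twinomics:::num_hess(f$objective, f$par)
  Vmod <- solve(H)
  ## singleton clusters: robust ~ model-based
  Vrob <- robust_se(f, cluster = seq_len(f$n_used))
  expect_equal(Vrob[1, 1] / Vmod[1, 1], 1, tolerance = 0.2)
  ## duplicating every individual into 2-member clusters doubles the variance
  co2 <- co[rep(seq_len(nrow(co)), each = 2), ]
  co2$id <- paste0(co2$id, rep(c("a", "b"), nrow(co)))
  class(co2) <- class(co)
  attr(co2, "cohort_spec") <- attr(co, "cohort_spec")
  f2 <- fit_lgcm(co2, lgcm_spec("logarithmic", sex_adjustment = "never"))
  V2rob <- robust_se(f2)                       # families = duplication clusters
  V2mod <- solve(twinomics:::num_hess(f2$objective, f2$par))
  expect_equal(V2rob[1, 1] / V2mod[1, 1], 2, tolerance = 0.3)
  ## family-correlated data: robust SE exceeds the naive one for the means
  co3 <- small_cohort(100, 100, 0, seed = 77)
  f3 <- fit_lgcm(co3, lgcm_spec("logarithmic", sex_adjustment = "never"))
  V3rob <- robust_se(f3)
  V3mod <- solve(twinomics:::num_hess(f3$objective, f3$par))
  expect_gt(V3rob[1, 1], V3mod[1, 1])
})

test_that("factor scores shrink to the mean as residual noise grows", {
  co <- small_cohort(30, 30, 0, seed = 78)
  f <- fit_lgcm(co, lgcm_spec("logarithmic", sex_adjustment = "never"))
  f_noisy <- f
  f_noisy$Theta <- rep(1e6, 4)
  gf <- extract_growth_factors(f_noisy)
  expect_lt(sd(gf$slope), 0.05)
  expect_equal(mean(gf$intercept), unname(f$alpha["intercept"]), tolerance = 0.2)
})

test_that("growth-factor scores recover the latent truth at moderate noise", {
  co <- small_cohort(150, 150, 0, seed = 79,
                     gspec = growth_spec(residual_sd = 0.5))
  f <- fit_lgcm(co, lgcm_spec("logarithmic"))
  gf <- extract_growth_factors(f)
  tr <- attr(co, "truth")
  expect_gt(cor(gf$intercept, tr$eta0), 0.9)
  expect_gt(cor(gf$slope, tr$eta1), 0.9)
})

test_that("TMI is mass over height cubed and flows through the growth model", {
  co <- small_cohort(10, 10, 0, seed = 80)
  co$weight_4[1] <- 60; co$height_4[1] <- 1.70
  co <- compute_tmi(co)
  expect_equal(co$tmi_4[1], 60 / 1.70^3, tolerance = 1e-12)
  expect_equal(co$tmi_4[1], 12.2125, tolerance = 1e-4)
  ## height 1 m: TMI equals weight
  co$height_2 <- 1
  co <- compute_tmi(co)
  expect_equal(co$tmi_2, co$weight_2)
  ## TMI waves are accepted by the growth fitter
  f <- fit_lgcm(co, lgcm_spec("logarithmic", sex_adjustment = "never"),
                measure = "tmi")
  expect_true(f$converged)
  co$height_3 <- -1
  expect_error(compute_tmi(co), "height")
})
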