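test_that("saturated twin correlations equal double-entry Pearson without covariates", {
  set.seed(301)
  d <- data.frame(family_id = rep(1:24, each = 2),
                  zygosity = rep(c("MZ", "DZ"), each = 24),
                  trait = rnorm(48))
  tp <- make_twin_pairs(d, "trait")
  sat <- suppressWarnings(twin_correlations(tp))
  first <- seq(1, 48, 2); second <- seq(2, 48, 2)
  de_mz <- double_entry_cor(d$trait[first][1:12], d$trait[second][1:12])
  de_dz <- double_entry_cor(d$trait[first][13:24], d$trait[second][13:24])
  expect_equal(sat$rMZ, de_mz, tolerance = 1e-4)
  expect_equal(sat$rDZ, de_dz, tolerance = 1e-4)
  ## identical co-twins give correlation ~ 1
  d2 <- d; d2$trait <- rep(rnorm(24), each = 2)
  sat2 <- suppressWarnings(twin_correlations(make_twin_pairs(d2, "trait")))
  expect_gt(sat2$rMZ, 0.999)
  expect_gt(sat2$rDZ, 0.999)
  ## single-zygosity data is an error
  d3 <- d[d$zygosity == "MZ", ]
  expect_error(twin_correlations(make_twin_pairs(d3, "trait")), "zygosity")
})

test_that("model-family choice follows the rDZ/rMZ ratio rule", {
  mk <- function(rmz, rdz) {
    structure(list(rMZ = rmz, rDZ = rdz), class = "saturated_fit")
  }
  expect_equal(choose_model_family(mk(0.4, 0.3))$candidates,
               c("ACE", "AE", "CE", "E"))
  expect_equal(choose_model_family(mk(0.6, 0.2))$candidates, "AE")
  expect_equal(choose_model_family(mk(0.5, 0.5))$candidates,
               c("ACE", "AE", "CE", "E"))
  fam <- choose_model_family(mk(-0.1, 0.2))
  expect_equal(fam$candidates, "E")
  expect_match(fam$flag, "rMZ")
})

test_that("univariate AE estimates track heritability and the Falconer moment oracle", {
  set.seed(302)
  co <- generate_cohort(cohort_spec(10000, 10000, 0, seed = 302))
  x <- ae_trait(co, h2 = 0.5)
  d <- twin_data(co, x)
  tp <- make_twin_pairs(d, "trait")
  f <- fit_univariate(tp, "AE")
  first <- !duplicated(co$family_id); second <- duplicated(co$family_id)
  zyg <- co$zygosity[first]
  rmz <- cor(x[first][zyg == "MZ"], x[second][zyg == "MZ"])
  rdz <- cor(x[first][zyg == "DZ"], x[second][zyg == "DZ"])
  expect_lt(abs(f$h2 - 2 * (rmz - rdz)), 0.03)
  expect_lt(abs(f$h2 - 0.5), 0.03)
  expect_equal(f$h2 + f$c2 + f$e2, 1, tolerance = 1e-12)
})

test_that("null twin data yields h2 near zero and e2 near one", {
  set.seed(303)
  co <- generate_cohort(cohort_spec(500, 500, 0, seed = 303))
  d <- twin_data(co, rnorm(nrow(co)))
  f <- fit_univariate(make_twin_pairs(d, "trait"), "AE")
  expect_equal(f$h2, 0, tolerance = 0.07)
  expect_equal(f$e2, 1, tolerance = 0.07)
})

test_that("nesting holds: AE cannot beat ACE, and the saturated model bounds both", {
  set.seed(304)
  co <- generate_cohort(cohort_spec(150, 200, 0, seed = 304))
  x <- ae_trait(co, h2 = 0.4, c2 = 0.2)
  d <- twin_data(co, x)
  tp <- make_twin_pairs(d, "trait")
  ace <- fit_univariate(tp, "ACE")
  ae <- fit_univariate(tp, "AE")
  ce <- fit_univariate(tp, "CE")
  e <- fit_univariate(tp, "E")
  sat <- twin_correlations(tp)
  expect_lte(ace$minus2ll, ae$minus2ll + 1e-6)
  expect_lte(ace$minus2ll, ce$minus2ll + 1e-6)
  expect_lte(ae$minus2ll, e$minus2ll + 1e-6)
  expect_lte(sat$minus2ll, ace$minus2ll + 1e-6)
})

test_that("AIC selection prefers parsimony on ties and recovers a pure-C architecture", {
  f1 <- structure(list(model = "ACE", minus2ll = 100, npar = 6, aic = 112),
                  class = "univariate_fit")
  f2 <- structure(list(model = "AE", minus2ll = 100, npar = 5, aic = 110),
                  class = "univariate_fit")
  best <- select_by_aic(list(f1, f2))
  expect_equal(best$model, "AE")
  expect_equal(attr(best, "comparison")$delta_aic, c(0, 2))
  ## equal likelihood: fewer parameters wins
  f3 <- structure(list(model = "CE", minus2ll = 100, npar = 5, aic = 110),
                  class = "univariate_fit")
  expect_equal(select_by_aic(list(f3, f1))$model, "CE")
  ## pure shared-environment generating data favours CE over AE
  set.seed(305)
  wins <- replicate(12, {
    co <- generate_cohort(cohort_spec(106, 164, 0))
    x <- ae_trait(co, h2 = 0, c2 = 0.35)
    tp <- make_twin_pairs(twin_data(co, x), "trait")
    ce <- fit_univariate(tp, "CE"); ae <- fit_univariate(tp, "AE")
    ce$aic < ae$aic
  })
  expect_gt(mean(wins), 0.6)
})

test_that("profile CIs for h2 bracket the estimate and cover a known truth", {
  set.seed(306)
  co <- generate_cohort(cohort_spec(106, 164, 0, seed = 306))
  x <- ae_trait(co, h2 = 0.72)
  f <- fit_univariate(make_twin_pairs(twin_data(co, x), "trait"), "AE")
  expect_equal(f$ci_method, "profile")
  expect_lt(f$ci$h2[1], f$h2)
  expect_gt(f$ci$h2[2], f$h2)
  expect_equal(sort(1 - f$ci$h2), f$ci$e2, tolerance = 1e-6)
})

test_that("incomplete pairs contribute through their marginal likelihood", {
  set.seed(307)
  co <- generate_cohort(cohort_spec(200, 300, 0, seed = 307))
  x <- ae_trait(co, h2 = 0.6)
  d <- twin_data(co, x)
  ## drop one co-twin's trait in 60 families: fit must still converge and
  ## stay close to the complete-data fit
  drop_rows <- which(duplicated(d$family_id))[1:60]
  d_miss <- d; d_miss$trait[drop_rows] <- NA
  f_full <- fit_univariate(make_twin_pairs(d, "trait"), "AE")
  f_miss <- fit_univariate(make_twin_pairs(d_miss, "trait"), "AE")
  expect_equal(f_miss$h2, f_full$h2, tolerance = 0.08)
  ## with no missing data, FIML equals the complete-pair likelihood computed
  ## directly from the bivariate normal density
  tp <- make_twin_pairs(d, "trait")
  V <- f_full$V; cmz <- f_full$A; cdz <- 0.5 * f_full$A
  mu <- unname(f_full$beta[1])
  ll <- 0
  for (z in c("MZ", "DZ")) {
    cv <- if (z == "MZ") cmz else cdz
    Y <- tp$y[tp$zyg == z, , drop = FALSE]
    ll <- ll + mvn_loglik(Y, matrix(mu, nrow(Y), 2),
                          matrix(c(V, cv, cv, V), 2))
  }
  expect_equal(f_full$minus2ll, -2 * ll, tolerance = 1e-6 * abs(ll))
})

test_that("bivariate AE decomposition obeys its defining identities", {
  set.seed(308)
  co <- generate_cohort(cohort_spec(106, 164, 0, seed = 308))
  d <- simulate_biv_ae(co, 0.72, 0.35, 0.29, 0.44)
  tp <- make_twin_pairs(d, c("trait_x", "trait_y"))
  f <- fit_bivariate_ae(tp)
  ## rPh identity at the ML point
  expect_equal(f$rph_implied,
               f$rA * sqrt(f$h2[1] * f$h2[2]) + f$rE * sqrt(f$e2[1] * f$e2[2]),
               tolerance = 1e-8)
  expect_true(abs(f$rA) <= 1 && abs(f$rE) <= 1)
  ## cross-twin cross-trait: MZ value is twice the DZ value
  expect_equal(unname(f$cross_twin_cross_trait["MZ"]),
               2 * unname(f$cross_twin_cross_trait["DZ"]), tolerance = 1e-10)
  ## CIs bracket the estimates
  expect_true(f$rE_ci[1] < f$rE && f$rE < f$rE_ci[2])
})

test_that("bivariate self-pairing and independence behave as limiting cases", {
  set.seed(309)
  co <- generate_cohort(cohort_spec(150, 200, 0, seed = 309))
  x <- ae_trait(co, h2 = 0.6)
  ## trait paired with a noisy copy of itself: rA and rE near 1
  d <- data.frame(id = co$id, family_id = co$family_id, zygosity = co$zygosity,
                  trait_x = x, trait_y = x + rnorm(length(x), 0, 0.05))
  f <- fit_bivariate_ae(make_twin_pairs(d, c("trait_x", "trait_y")))
  expect_gt(f$rA, 0.95)
  expect_gt(f$rE, 0.95)
  ## independent traits: both correlations near 0
  d2 <- simulate_biv_ae(co, 0.6, 0.6, 0, 0)
  f2 <- fit_bivariate_ae(make_twin_pairs(d2, c("trait_x", "trait_y")))
  expect_lt(abs(f2$rA), 0.2)
  expect_lt(abs(f2$rE), 0.15)
})

test_that("adjusting a trait by a covariate removes shared-driver correlations", {
  set.seed(310)
  co <- generate_cohort(cohort_spec(300, 450, 0, seed = 310))
  ## two traits sharing their genetic driver entirely
  d <- simulate_biv_ae(co, 0.7, 0.7, 0.9, 0.1)
  ## adjusting x by y attenuates rA toward zero
  d_adj <- adjust_trait(d, "trait_x", "trait_y")
  f_adj <- fit_bivariate_ae(make_twin_pairs(d_adj, c("trait_x", "trait_y")))
  f_raw <- fit_bivariate_ae(make_twin_pairs(d, c("trait_x", "trait_y")))
  expect_lt(abs(f_adj$rA), abs(f_raw$rA))
  ## the adjusted pair has (near) zero phenotypic correlation by construction
  expect_lt(abs(f_adj$rph_implied), 0.08)
  ## uncorrelated covariate leaves the trait unchanged up to centering
  d2 <- d
  d2$cov <- rnorm(nrow(d2))
  d3 <- adjust_trait(d2, "trait_x", "cov")
  expect_gt(cor(d3$trait_x, d2$trait_x), 0.99)
  ## degenerate cases surface cleanly
  expect_error(adjust_trait(transform(d, c0 = 1), "trait_x", "c0"), "constant")
  d4 <- d; d4$trait_y <- d4$trait_x
  d4 <- adjust_trait(d4, "trait_y", "trait_x")
  expect_error(fit_bivariate_ae(make_twin_pairs(d4, c("trait_x", "trait_y"))))
})
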