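# Shared fixture builders: everything is generated in code at test time.

## small cohort with simulated BMI under default-like conditions
small_cohort <- function(n_mz = 30, n_dz = 40, n_single = 0, seed = 42,
                         gspec = growth_spec()) {
  co <- generate_cohort(cohort_spec(n_mz, n_dz, n_single, seed = seed))
  simulate_bmi_trajectories(co, gspec)
}

## single standardized AE trait on a cohort, via the omics generator with
## batch machinery switched off
ae_trait <- function(cohort, h2, c2 = 0) {
  om <- simulate_omics(cohort, omics_spec(n_features = 1, h2 = h2, c2 = c2,
                                          n_batches = 1, batch_shift_sd = 0,
                                          batch_scale_range = c(1, 1),
                                          missing_censor_quantile = 0))
  log2(om$values[, 1])
}

## individual-level data frame for twin-model fitting
twin_data <- function(cohort, trait) {
  data.frame(id = cohort$id, family_id = cohort$family_id,
             zygosity = cohort$zygosity, sex = cohort$sex,
             age_at_sampling = cohort$age_at_sampling, trait = trait,
             stringsAsFactors = FALSE)
}

## phenotype table wired straight from generated traits (no LGCM needed)
direct_pheno <- function(cohort, bmi = cohort$bmi_at_sampling,
                         intercept = NA_real_, slope = NA_real_) {
  data.frame(id = cohort$id, family_id = cohort$family_id,
             zygosity = cohort$zygosity, sex = cohort$sex,
             age_at_sampling = cohort$age_at_sampling,
             bmi_at_sampling = bmi, bmi_intercept = intercept,
             bmi_slope = slope, stringsAsFactors = FALSE)
}

## one-column omics matrix from a numeric vector
one_feature_matrix <- function(cohort, x, name = "F1") {
  omics_matrix(matrix(x, ncol = 1, dimnames = list(cohort$id, name)),
               scale = "log2")
}

## double-entry Pearson correlation (independent oracle for the saturated fit)
double_entry_cor <- function(y1, y2) {
  stats::cor(c(y1, y2), c(y2, y1))
}

## direct multivariate-normal log-density (independent oracle for FIML)
mvn_loglik <- function(Y, mu, Sigma) {
  U <- chol(Sigma)
  R <- Y - mu
  Z <- R %*% backsolve(U, diag(ncol(Y)))
  sum(-0.5 * (ncol(Y) * log(2 * pi) + 2 * sum(log(diag(U))) + rowSums(Z^2)))
}
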