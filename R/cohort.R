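#' Specify a synthetic twin cohort
#'
#' Builds the specification consumed by [generate_cohort()]. Defaults emulate
#' a Finnish adolescent twin sample with four survey waves at mean ages
#' 11.4, 14.0, 17.6 and 22.4 years and 59% female participants; the default
#' per-wave age jitter matches the observed wave age spread (sd 0.3, 0.1,
#' 0.2, 0.7 years).
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons non-negative counts of complete
#'   monozygotic pairs, complete dizygotic pairs, and twin individuals whose
#'   co-twin is absent from the sample.
#' @param female_fraction probability that an individual (or an MZ pair) is
#'   female.
#' @param wave_mean_ages strictly increasing vector of reference ages (years),
#'   one per wave.
#' @param wave_age_sd per-wave sd (years) of the family-level age jitter;
#'   scalar or one value per wave.
#' @param seed optional integer seed; when given, [generate_cohort()] is
#'   deterministic.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 106, n_dz_pairs = 164, n_singletons = 111,
                        female_fraction = 0.59,
                        wave_mean_ages = c(11.4, 14.0, 17.6, 22.4),
                        wave_age_sd = c(0.3, 0.1, 0.2, 0.7),
                        seed = NULL) {
  check_that(length(n_mz_pairs) == 1 && n_mz_pairs >= 0 && n_mz_pairs == floor(n_mz_pairs),
             "n_mz_pairs", "must be a single non-negative integer")
  check_that(length(n_dz_pairs) == 1 && n_dz_pairs >= 0 && n_dz_pairs == floor(n_dz_pairs),
             "n_dz_pairs", "must be a single non-negative integer")
  check_that(length(n_singletons) == 1 && n_singletons >= 0 && n_singletons == floor(n_singletons),
             "n_singletons", "must be a single non-negative integer")
  check_that(female_fraction >= 0 && female_fraction <= 1,
             "female_fraction", "must lie in [0, 1]")
  check_that(length(wave_mean_ages) >= 2 && all(diff(wave_mean_ages) > 0),
             "wave_mean_ages", "must be strictly increasing")
  if (length(wave_age_sd) == 1) wave_age_sd <- rep(wave_age_sd, length(wave_mean_ages))
  check_that(length(wave_age_sd) == length(wave_mean_ages) && all(wave_age_sd >= 0),
             "wave_age_sd", "must be non-negative, one value per wave")
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 n_singletons = n_singletons, female_fraction = female_fraction,
                 wave_mean_ages = wave_mean_ages, wave_age_sd = wave_age_sd,
                 seed = seed),
            class = "cohort_spec")
}

## Sex-specific reference stature (m) by age, linearly interpolated.
ref_height <- function(sex, age) {
  ages <- c(6, 11.4, 14, 17.6, 22.4, 35)
  hm <- c(1.19, 1.47, 1.64, 1.77, 1.795, 1.795)
  hf <- c(1.18, 1.48, 1.59, 1.65, 1.66, 1.66)
  out <- numeric(length(age))
  m <- sex == "M"
  out[m] <- stats::approx(ages, hm, xout = age[m], rule = 2)$y
  out[!m] <- stats::approx(ages, hf, xout = age[!m], rule = 2)$y
  out
}

#' Generate a twin cohort skeleton
#'
#' Creates individuals in MZ/DZ families and singletons with sexes, per-wave
#' ages and heights. BMI waves are filled in by
#' [simulate_bmi_trajectories()]. Co-twins share family id, zygosity and
#' wave ages (the jitter around the reference age is drawn at the family
#' level); MZ co-twins share sex, DZ co-twins' sexes are independent so both
#' same-sex and opposite-sex DZ pairs occur. Singletons carry `NA` zygosity
#' and contribute no within-pair covariance downstream.
#'
#' @param spec a [cohort_spec()].
#' @return A `twin_cohort` data frame: one row per individual with columns
#'   `id`, `family_id`, `zygosity`, `sex`, `age_<w>`, `height_<w>`,
#'   `weight_<w>`, `bmi_<w>`, `age_at_sampling`, `bmi_at_sampling`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  W <- length(spec$wave_mean_ages)
  n_fam <- spec$n_mz_pairs + spec$n_dz_pairs + spec$n_singletons
  fam_size <- rep(c(2L, 2L, 1L), c(spec$n_mz_pairs, spec$n_dz_pairs, spec$n_singletons))
  zyg_fam <- rep(c("MZ", "DZ", NA), c(spec$n_mz_pairs, spec$n_dz_pairs, spec$n_singletons))
  n <- sum(fam_size)

  if (n == 0) {
    out <- data.frame(id = character(0), family_id = character(0),
                      zygosity = character(0), sex = character(0),
                      stringsAsFactors = FALSE)
    for (v in c("age", "height", "weight", "bmi")) {
      for (w in seq_len(W)) out[[paste0(v, "_", w)]] <- numeric(0)
    }
    out$age_at_sampling <- numeric(0)
    out$bmi_at_sampling <- numeric(0)
    class(out) <- c("twin_cohort", "data.frame")
    attr(out, "cohort_spec") <- spec
    return(out)
  }

  family_id <- rep(sprintf("F%04d", seq_len(n_fam)), fam_size)
  id <- sprintf("T%04d", seq_len(n))
  zygosity <- rep(zyg_fam, fam_size)

  ## sexes: one draw per MZ pair, independent otherwise
  sex <- character(n)
  pos <- 1L
  for (f in seq_len(n_fam)) {
    k <- fam_size[f]
    if (identical(zyg_fam[f], "MZ")) {
      s <- if (stats::runif(1) < spec$female_fraction) "F" else "M"
      sex[pos:(pos + k - 1)] <- s
    } else {
      sex[pos:(pos + k - 1)] <- ifelse(stats::runif(k) < spec$female_fraction, "F", "M")
    }
    pos <- pos + k
  }

  ## family-level wave-age jitter, shared by co-twins
  jit <- matrix(stats::rnorm(n_fam * W, 0, rep(spec$wave_age_sd, each = n_fam)), n_fam, W)
  ages <- jit[rep(seq_len(n_fam), fam_size), , drop = FALSE] +
    matrix(spec$wave_mean_ages, n, W, byrow = TRUE)

  ## individual stature deviation, stable across waves
  hdev <- rep(stats::rnorm(n_fam, 0, 0.035), fam_size) + stats::rnorm(n, 0, 0.025)
  heights <- matrix(0, n, W)
  for (w in seq_len(W)) heights[, w] <- ref_height(sex, ages[, w]) * (1 + hdev)

  out <- data.frame(id = id, family_id = family_id, zygosity = zygosity,
                    sex = sex, stringsAsFactors = FALSE)
  for (w in seq_len(W)) out[[paste0("age_", w)]] <- ages[, w]
  for (w in seq_len(W)) out[[paste0("height_", w)]] <- heights[, w]
  for (w in seq_len(W)) out[[paste0("weight_", w)]] <- NA_real_
  for (w in seq_len(W)) out[[paste0("bmi_", w)]] <- NA_real_
  out$age_at_sampling <- ages[, W]
  out$bmi_at_sampling <- NA_real_
  class(out) <- c("twin_cohort", "data.frame")
  attr(out, "cohort_spec") <- spec
  out
}

#' @export
print.twin_cohort <- function(x, ...) {
  W <- sum(grepl("^age_[0-9]+$", names(x)))
  cat("Twin cohort:", nrow(x), "individuals,",
      length(unique(x$family_id)), "families,", W, "waves\n")
  cat("  MZ:", sum(x$zygosity == "MZ", na.rm = TRUE),
      " DZ:", sum(x$zygosity == "DZ", na.rm = TRUE),
      " singletons:", sum(is.na(x$zygosity)), "\n")
  if (!all(is.na(x$bmi_at_sampling)))
    cat("  BMI simulated; mean BMI at sampling:",
        round(mean(x$bmi_at_sampling, na.rm = TRUE), 2), "\n")
  invisible(x)
}

#' Specify the BMI growth-generating model
#'
#' Parameters of the latent intercept/slope model used by
#' [simulate_bmi_trajectories()]. Defaults reproduce the adolescent-cohort
#' conditions: logarithmic time basis, mean intercept 17.6 BMI units, mean
#' slope 2.3 (male) / 2.0 (female) on the log-time scale (a 10-year gain of
#' about 5-6 BMI units), intercept heritability 0.72 and slope heritability
#' 0.63 under an AE architecture.
#'
#' @param scheme `"linear"` or `"logarithmic"` time basis; the slope loading
#'   at wave w is `dt` or `log(dt + 1)` with `dt` the years since the first
#'   reference age.
#' @param intercept_mean,intercept_sd latent intercept distribution (BMI units).
#' @param slope_mean_by_sex named vector `c(M = , F = )` of mean slopes.
#' @param slope_sd latent slope sd.
#' @param intercept_slope_corr correlation applied to both the genetic and the
#'   unique-environment components of (intercept, slope); the implied
#'   phenotypic correlation is
#'   `r * (sqrt(a2_int * a2_slo) + sqrt((1-a2_int)(1-a2_slo)))`.
#' @param a2_intercept,a2_slope additive-genetic variance fractions in `[0,1]`
#'   (generation is restricted to admissible values; downstream estimates may
#'   go negative).
#' @param residual_sd wave-level measurement noise sd (BMI units).
#' @return A list of class `growth_spec`.
#' @export
growth_spec <- function(scheme = c("logarithmic", "linear"),
                        intercept_mean = 17.6, intercept_sd = 2.2,
                        slope_mean_by_sex = c(M = 2.3, F = 2.0),
                        slope_sd = 0.6, intercept_slope_corr = 0.3,
                        a2_intercept = 0.72, a2_slope = 0.63,
                        residual_sd = 0.5) {
  scheme <- match.arg(scheme)
  check_that(intercept_sd >= 0, "intercept_sd", "must be >= 0")
  check_that(slope_sd >= 0, "slope_sd", "must be >= 0")
  check_that(residual_sd >= 0, "residual_sd", "must be >= 0")
  check_that(abs(intercept_slope_corr) <= 1, "intercept_slope_corr", "must lie in [-1, 1]")
  check_that(a2_intercept >= 0 && a2_intercept <= 1, "a2_intercept", "must lie in [0, 1]")
  check_that(a2_slope >= 0 && a2_slope <= 1, "a2_slope", "must lie in [0, 1]")
  check_that(all(c("M", "F") %in% names(slope_mean_by_sex)),
             "slope_mean_by_sex", "needs named elements M and F")
  structure(list(scheme = scheme, intercept_mean = intercept_mean,
                 intercept_sd = intercept_sd, slope_mean_by_sex = slope_mean_by_sex,
                 slope_sd = slope_sd, intercept_slope_corr = intercept_slope_corr,
                 a2_intercept = a2_intercept, a2_slope = a2_slope,
                 residual_sd = residual_sd),
            class = "growth_spec")
}

## Slope loadings for a scheme given reference wave ages.
growth_loadings <- function(ref_ages, scheme) {
  dt <- ref_ages - ref_ages[1]
  switch(scheme,
         linear = dt,
         logarithmic = log(dt + 1),
         stop("unknown growth scheme: ", scheme, call. = FALSE))
}

## Family-structured standard-normal draws: one column set per requested
## variable; MZ co-twins share the draw, DZ co-twins correlate 0.5,
## singletons are independent. `R` is an optional cross-variable correlation.
r_family_normal <- function(cohort, k = 1, R = NULL) {
  if (is.null(R)) R <- diag(k)
  fam <- factor(cohort$family_id, levels = unique(cohort$family_id))
  n_fam <- nlevels(fam)
  fidx <- as.integer(fam)
  common <- rmvn(n_fam, R)[fidx, , drop = FALSE]
  unique_part <- rmvn(nrow(cohort), R)
  w_common <- ifelse(is.na(cohort$zygosity), 0,
                     ifelse(cohort$zygosity == "MZ", 1, sqrt(0.5)))
  w_unique <- sqrt(1 - w_common^2)
  ## MZ co-twins must share the unique part weighting 0 -> identical values
  common * w_common + unique_part * w_unique
}

#' Simulate BMI trajectories on a cohort
#'
#' Draws latent growth factors (eta0, eta1) per individual under an AE twin
#' architecture (MZ genetic sharing 1, DZ 0.5), forms per-wave BMI as
#' `eta0 + lambda_w * eta1 + e_iw`, and back-fills weights so that
#' `BMI = weight / height^2` holds exactly. The wave-4 BMI and age define
#' `bmi_at_sampling` and `age_at_sampling`. Latent truths (growth factors and
#' standardized genetic/unique components of the slope and of BMI at
#' sampling) are stored in `attr(cohort, "truth")` for parameter-recovery
#' testing.
#'
#' @param cohort a [generate_cohort()] result.
#' @param spec a [growth_spec()].
#' @return The cohort with BMI, weight and sampling columns filled.
#' @export
simulate_bmi_trajectories <- function(cohort, spec) {
  if (!inherits(spec, "growth_spec")) stop("'spec' must be a growth_spec", call. = FALSE)
  cspec <- attr(cohort, "cohort_spec")
  W <- sum(grepl("^age_[0-9]+$", names(cohort)))
  ref <- if (!is.null(cspec)) cspec$wave_mean_ages else
    colMeans(as.matrix(cohort[paste0("age_", seq_len(W))]))
  lam <- growth_loadings(ref, spec$scheme)
  n <- nrow(cohort)

  R <- matrix(c(1, spec$intercept_slope_corr, spec$intercept_slope_corr, 1), 2)
  A <- r_family_normal(cohort, 2, R)     # genetic components (intercept, slope)
  E <- rmvn(n, R)                        # unique-environment components

  a0 <- spec$a2_intercept; a1 <- spec$a2_slope
  eta0 <- spec$intercept_mean +
    spec$intercept_sd * (sqrt(a0) * A[, 1] + sqrt(1 - a0) * E[, 1])
  mu1 <- unname(spec$slope_mean_by_sex[cohort$sex])
  eta1 <- mu1 + spec$slope_sd * (sqrt(a1) * A[, 2] + sqrt(1 - a1) * E[, 2])

  eps <- matrix(stats::rnorm(n * W, 0, spec$residual_sd), n, W)
  bmi <- outer(eta0, rep(1, W)) + outer(eta1, lam) + eps
  for (w in seq_len(W)) {
    cohort[[paste0("bmi_", w)]] <- bmi[, w]
    cohort[[paste0("weight_", w)]] <- bmi[, w] * cohort[[paste0("height_", w)]]^2
  }
  cohort$bmi_at_sampling <- bmi[, W]
  cohort$age_at_sampling <- cohort[[paste0("age_", W)]]

  ## standardized genetic / unique components of the two target traits
  s0 <- spec$intercept_sd; s1 <- spec$slope_sd; rho <- spec$intercept_slope_corr
  lw <- lam[W]
  pa <- s0 * sqrt(a0) * A[, 1] + lw * s1 * sqrt(a1) * A[, 2]
  va <- s0^2 * a0 + lw^2 * s1^2 * a1 + 2 * lw * s0 * s1 * rho * sqrt(a0 * a1)
  pu <- s0 * sqrt(1 - a0) * E[, 1] + lw * s1 * sqrt(1 - a1) * E[, 2] + eps[, W]
  vu <- s0^2 * (1 - a0) + lw^2 * s1^2 * (1 - a1) +
    2 * lw * s0 * s1 * rho * sqrt((1 - a0) * (1 - a1)) + spec$residual_sd^2

  truth <- data.frame(id = cohort$id, eta0 = eta0, eta1 = eta1,
                      g_slope = A[, 2], u_slope = E[, 2],
                      g_bms = if (va > 0) pa / sqrt(va) else 0,
                      u_bms = pu / sqrt(vu),
                      stringsAsFactors = FALSE)
  attr(cohort, "truth") <- truth
  attr(cohort, "truth_h2") <- c(bmi_slope = a1, bmi_at_sampling = va / (va + vu))
  attr(cohort, "growth_spec") <- spec
  attr(cohort, "loadings") <- lam
  cohort
}

#' Export a cohort's phenotypes in long format
#'
#' @param cohort a `twin_cohort`.
#' @return Data frame with one row per individual and wave: `individual_id`,
#'   `family_id`, `zygosity`, `sex`, `wave`, `age`, `height_m`, `weight_kg`,
#'   `bmi`.
#' @export
cohort_long <- function(cohort) {
  W <- sum(grepl("^age_[0-9]+$", names(cohort)))
  do.call(rbind, lapply(seq_len(W), function(w) {
    data.frame(individual_id = cohort$id, family_id = cohort$family_id,
               zygosity = cohort$zygosity, sex = cohort$sex, wave = w,
               age = cohort[[paste0("age_", w)]],
               height_m = cohort[[paste0("height_", w)]],
               weight_kg = cohort[[paste0("weight_", w)]],
               bmi = cohort[[paste0("bmi_", w)]],
               stringsAsFactors = FALSE)
  }))
}
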