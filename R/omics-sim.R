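#' Specify a synthetic omics layer
#'
#' Parameters for [simulate_omics()]. Each feature is generated as a weighted
#' sum of a family-structured additive-genetic component, a family-shared
#' environmental component and an individual unique component, with optional
#' genetic (`rA`) and unique-environment (`rE`) correlations to a target BMI
#' trait, then pushed through batch location/scale effects and detection-limit
#' (left-censoring) missingness.
#'
#' The default variance-fraction sampler emulates a plasma proteome: 80% of
#' features draw `h2` from a Beta(2, 3.5) (mean ~0.36) with `c2 = 0`; the
#' remaining 20% have `h2 = 0` and `c2 ~ Uniform(0.19, 0.41)` (purely
#' shared-environmental features averaging ~28% shared variance).
#'
#' @param n_features number of features.
#' @param feature_class `"protein"`, `"metabolite"` or `"gene_expression"`.
#' @param h2,c2 per-feature variance fractions: numeric vectors (recycled) or
#'   a function of `n`; `NULL` uses the default sampler above.
#' @param target_trait `"bmi_at_sampling"`, `"bmi_slope"` or `"none"`.
#' @param rA,rE per-feature genetic/unique correlations with the target trait
#'   (recycled).
#' @param n_batches number of measurement batches.
#' @param batch_shift_sd sd of the per-feature-per-batch additive shift
#'   (log2 units).
#' @param batch_scale_range range of the per-feature-per-batch multiplicative
#'   scale factor.
#' @param missing_censor_quantile per-batch left-censoring quantile in
#'   `[0, 0.5)`; the default 0.0086 reproduces a dataset-wide missingness of
#'   about 0.86%.
#' @param lipo_block optional `list(size =, rho =)`: the first `size` features
#'   share a latent block factor with loading `sqrt(rho)`, emulating a
#'   correlated lipoprotein panel.
#' @return A list of class `omics_spec`.
#' @export
omics_spec <- function(n_features = 439,
                       feature_class = c("protein", "metabolite", "gene_expression"),
                       h2 = NULL, c2 = NULL,
                       target_trait = c("none", "bmi_at_sampling", "bmi_slope"),
                       rA = 0, rE = 0,
                       n_batches = 4, batch_shift_sd = 0.4,
                       batch_scale_range = c(0.8, 1.25),
                       missing_censor_quantile = 0.0086,
                       lipo_block = NULL) {
  feature_class <- match.arg(feature_class)
  target_trait <- match.arg(target_trait)
  check_that(n_features >= 1, "n_features", "must be >= 1")
  check_that(n_batches >= 1, "n_batches", "must be >= 1")
  check_that(missing_censor_quantile >= 0 && missing_censor_quantile < 0.5,
             "missing_censor_quantile", "must lie in [0, 0.5)")
  check_that(batch_shift_sd >= 0, "batch_shift_sd", "must be >= 0")
  if (!is.null(lipo_block)) {
    check_that(is.list(lipo_block) && all(c("size", "rho") %in% names(lipo_block)),
               "lipo_block", "must be list(size =, rho =)")
    check_that(lipo_block$size <= n_features, "lipo_block", "block larger than n_features")
  }
  structure(list(n_features = n_features, feature_class = feature_class,
                 h2 = h2, c2 = c2, target_trait = target_trait, rA = rA, rE = rE,
                 n_batches = n_batches, batch_shift_sd = batch_shift_sd,
                 batch_scale_range = batch_scale_range,
                 missing_censor_quantile = missing_censor_quantile,
                 lipo_block = lipo_block),
            class = "omics_spec")
}

draw_variance_fractions <- function(spec) {
  m <- spec$n_features
  if (is.null(spec$h2) && is.null(spec$c2)) {
    ce <- stats::runif(m) < 0.2
    h2 <- ifelse(ce, 0, stats::rbeta(m, 2, 3.5))
    c2 <- ifelse(ce, stats::runif(m, 0.19, 0.41), 0)
  } else {
    h2 <- spec$h2 %||% 0
    c2 <- spec$c2 %||% 0
    h2 <- if (is.function(h2)) h2(m) else rep_len(h2, m)
    c2 <- if (is.function(c2)) c2(m) else rep_len(c2, m)
  }
  if (any(h2 < 0 | c2 < 0 | h2 + c2 > 1 + 1e-12)) {
    stop("invalid variance fractions: need h2 >= 0, c2 >= 0, h2 + c2 <= 1", call. = FALSE)
  }
  list(h2 = h2, c2 = pmin(c2, 1 - h2))
}

#' Simulate an omics matrix with known genetic architecture
#'
#' @param cohort a `twin_cohort`; must carry latent truth (see
#'   [simulate_bmi_trajectories()]) when any `rA` or `rE` is nonzero.
#' @param spec an [omics_spec()].
#' @return An [omics_matrix()] on the raw (positive) scale with batch labels
#'   and detection-limit missingness. `feature_info` records the generating
#'   `h2`, `c2`, `e2`, `rA`, `rE` per feature.
#' @export
simulate_omics <- function(cohort, spec) {
  if (!inherits(spec, "omics_spec")) stop("'spec' must be an omics_spec", call. = FALSE)
  n <- nrow(cohort)
  m <- spec$n_features
  vf <- draw_variance_fractions(spec)
  h2 <- vf$h2; c2 <- vf$c2; e2 <- 1 - h2 - c2
  rA <- rep_len(spec$rA, m)
  rE <- rep_len(spec$rE, m)
  check_that(all(abs(rA) <= 1) && all(abs(rE) <= 1), "rA/rE", "must lie in [-1, 1]")
  if (any(rA != 0 & h2 == 0)) {
    if (is.null(spec$h2)) {
      ## default sampler produced purely environmental features: they have no
      ## genetic path, so the trait coupling applies to heritable features only
      rA[h2 == 0] <- 0
    } else {
      stop("rA requested for a feature with h2 = 0: no genetic path to correlate",
           call. = FALSE)
    }
  }

  gt <- ut <- rep(0, n)
  if (spec$target_trait != "none") {
    truth <- attr(cohort, "truth")
    if (is.null(truth) && any(rA != 0 | rE != 0)) {
      stop("cohort carries no latent truth; run simulate_bmi_trajectories() first",
           call. = FALSE)
    }
    if (!is.null(truth)) {
      gt <- if (spec$target_trait == "bmi_slope") truth$g_slope else truth$g_bms
      ut <- if (spec$target_trait == "bmi_slope") truth$u_slope else truth$u_bms
    }
  }

  G <- r_family_normal(cohort, m)                 # feature-specific genetic part
  fam <- factor(cohort$family_id, levels = unique(cohort$family_id))
  C <- matrix(stats::rnorm(nlevels(fam) * m), nlevels(fam), m)[as.integer(fam), , drop = FALSE]
  U <- matrix(stats::rnorm(n * m), n, m)

  if (!is.null(spec$lipo_block)) {
    b <- seq_len(spec$lipo_block$size)
    rho <- spec$lipo_block$rho
    GL <- r_family_normal(cohort, 1)[, 1]
    UL <- stats::rnorm(n)
    G[, b] <- sqrt(rho) * GL + sqrt(1 - rho) * G[, b]
    U[, b] <- sqrt(rho) * UL + sqrt(1 - rho) * U[, b]
  }

  Gmix <- outer(gt, rA) + sweep(G, 2, sqrt(1 - rA^2), `*`)
  Umix <- outer(ut, rE) + sweep(U, 2, sqrt(1 - rE^2), `*`)
  z <- sweep(Gmix, 2, sqrt(h2), `*`) + sweep(C, 2, sqrt(c2), `*`) +
    sweep(Umix, 2, sqrt(e2), `*`)

  ## batch location/scale effects on the log2 scale, then left-censoring
  batch <- factor(sample(seq_len(spec$n_batches), n, replace = TRUE))
  mu <- stats::rnorm(m, 12, 1.5)
  log2val <- sweep(z, 2, mu, `+`)
  for (b in levels(batch)) {
    idx <- batch == b
    gamma <- stats::rnorm(m, 0, spec$batch_shift_sd)
    delta <- stats::runif(m, spec$batch_scale_range[1], spec$batch_scale_range[2])
    log2val[idx, ] <- sweep(sweep(z[idx, , drop = FALSE], 2, delta, `*`), 2, mu + gamma, `+`)
  }
  ## detection-limit missingness: within each batch, the k lowest values of a
  ## feature fall below detection, k ~ Binomial(n_batch, q)
  q <- spec$missing_censor_quantile
  if (q > 0) {
    for (b in levels(batch)) {
      idx <- which(batch == b)
      if (length(idx) < 2) next
      sub <- log2val[idx, , drop = FALSE]
      k <- stats::rbinom(m, length(idx), q)
      for (j in which(k > 0)) {
        sub[order(sub[, j])[seq_len(min(k[j], length(idx) - 1))], j] <- NA
      }
      log2val[idx, ] <- sub
    }
  }

  values <- 2^log2val
  rownames(values) <- cohort$id
  colnames(values) <- sprintf("%s_%03d", switch(spec$feature_class,
                                                protein = "PROT",
                                                metabolite = "MET",
                                                gene_expression = "GENE"),
                              seq_len(m))
  info <- data.frame(feature_id = colnames(values), class = spec$feature_class,
                     h2 = h2, c2 = c2, e2 = e2, rA = rA, rE = rE,
                     stringsAsFactors = FALSE)
  omics_matrix(values, batch = batch, feature_info = info, scale = "raw")
}

#' Specify a polygenic-score generator
#'
#' @param target_trait trait whose additive-genetic value the score proxies
#'   (`"bmi_at_sampling"` or `"bmi_slope"`).
#' @param r2_with_genetic_value squared correlation in `[0, 1]` between the
#'   score and the standardized additive-genetic value.
#' @param n_genetic_pcs number of nuisance genetic principal components to
#'   emit alongside the score.
#' @return A list of class `prs_spec`.
#' @export
prs_spec <- function(target_trait = c("bmi_at_sampling", "bmi_slope"),
                     r2_with_genetic_value = 0.25, n_genetic_pcs = 10) {
  target_trait <- match.arg(target_trait)
  check_that(r2_with_genetic_value >= 0 && r2_with_genetic_value <= 1,
             "r2_with_genetic_value", "must lie in [0, 1]")
  check_that(n_genetic_pcs >= 0, "n_genetic_pcs", "must be >= 0")
  structure(list(target_trait = target_trait,
                 r2_with_genetic_value = r2_with_genetic_value,
                 n_genetic_pcs = n_genetic_pcs),
            class = "prs_spec")
}

#' Simulate polygenic scores as noisy additive-genetic proxies
#'
#' `PRS = sqrt(r2) * g + sqrt(1 - r2) * noise` with `g` the standardized
#' additive-genetic value of the target trait and individual-level noise, so
#' MZ co-twins' scores coincide exactly when `r2 = 1`. The score is scaled to
#' mean zero and unit variance; nuisance genetic PCs are independent standard
#' normals.
#'
#' @param cohort a `twin_cohort` carrying latent truth.
#' @param spec a [prs_spec()].
#' @return Data frame `id`, `prs`, `pc1` ... `pcK`.
#' @export
simulate_prs <- function(cohort, spec) {
  if (!inherits(spec, "prs_spec")) stop("'spec' must be a prs_spec", call. = FALSE)
  truth <- attr(cohort, "truth")
  if (is.null(truth)) {
    stop("cohort carries no latent truth; run simulate_bmi_trajectories() first",
         call. = FALSE)
  }
  g <- if (spec$target_trait == "bmi_slope") truth$g_slope else truth$g_bms
  r2 <- spec$r2_with_genetic_value
  raw <- sqrt(r2) * g + sqrt(1 - r2) * stats::rnorm(nrow(cohort))
  prs <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw
  out <- data.frame(id = cohort$id, prs = prs, stringsAsFactors = FALSE)
  if (spec$n_genetic_pcs > 0) {
    pcs <- matrix(stats::rnorm(nrow(cohort) * spec$n_genetic_pcs), nrow(cohort))
    colnames(pcs) <- paste0("pc", seq_len(spec$n_genetic_pcs))
    out <- cbind(out, as.data.frame(pcs))
  }
  out
}

#' Simulate a bivariate AE trait pair on a cohort
#'
#' Direct generator for bivariate twin-model recovery studies: two
#' standardized traits with additive-genetic fractions `h2x`, `h2y`, genetic
#' correlation `rA` and unique-environment correlation `rE`, so the implied
#' phenotypic correlation is `rA * sqrt(h2x * h2y) + rE * sqrt((1-h2x)(1-h2y))`.
#'
#' @param cohort a `twin_cohort` (only ids, families and zygosity are used).
#' @param h2x,h2y additive-genetic variance fractions in `[0, 1]`.
#' @param rA,rE latent correlations in `[-1, 1]`.
#' @return Data frame `id`, `family_id`, `zygosity`, `trait_x`, `trait_y`.
#' @export
simulate_biv_ae <- function(cohort, h2x, h2y, rA, rE) {
  check_that(h2x >= 0 && h2x <= 1, "h2x", "must lie in [0, 1]")
  check_that(h2y >= 0 && h2y <= 1, "h2y", "must lie in [0, 1]")
  check_that(abs(rA) <= 1, "rA", "must lie in [-1, 1]")
  check_that(abs(rE) <= 1, "rE", "must lie in [-1, 1]")
  RA <- matrix(c(1, rA, rA, 1), 2)
  RE <- matrix(c(1, rE, rE, 1), 2)
  G <- r_family_normal(cohort, 2, RA)
  E <- rmvn(nrow(cohort), RE)
  data.frame(id = cohort$id, family_id = cohort$family_id,
             zygosity = cohort$zygosity,
             trait_x = sqrt(h2x) * G[, 1] + sqrt(1 - h2x) * E[, 1],
             trait_y = sqrt(h2y) * G[, 2] + sqrt(1 - h2y) * E[, 2],
             stringsAsFactors = FALSE)
}
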