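#' Specify a latent growth curve model
#'
#' @param scheme time basis: `"linear"` (slope loading `dt`) or
#'   `"logarithmic"` (`log(dt + 1)`), with `dt` the years between a wave's
#'   reference age and the first reference age.
#' @param reference_ages per-wave reference ages (years); `NULL` takes the
#'   cohort's observed wave means.
#' @param adjust_within_wave_age include a single shared coefficient linearly
#'   adjusting BMI for age differences within waves.
#' @param sex_adjustment `"auto"` keeps a sex effect on a growth-factor mean
#'   only when its Wald p-value is below `sex_effect_alpha`; `"always"` /
#'   `"never"` force or suppress both.
#' @param sex_effect_alpha significance level for the auto rule.
#' @return A list of class `lgcm_spec`.
#' @export
lgcm_spec <- function(scheme = c("logarithmic", "linear"), reference_ages = NULL,
                      adjust_within_wave_age = TRUE,
                      sex_adjustment = c("auto", "always", "never"),
                      sex_effect_alpha = 0.05) {
  scheme <- match.arg(scheme)
  sex_adjustment <- match.arg(sex_adjustment)
  check_that(sex_effect_alpha > 0 && sex_effect_alpha < 1,
             "sex_effect_alpha", "must lie in (0, 1)")
  if (!is.null(reference_ages)) {
    check_that(all(diff(reference_ages) > 0), "reference_ages", "must be increasing")
  }
  structure(list(scheme = scheme, reference_ages = reference_ages,
                 adjust_within_wave_age = adjust_within_wave_age,
                 sex_adjustment = sex_adjustment,
                 sex_effect_alpha = sex_effect_alpha),
            class = "lgcm_spec")
}

## ---- generic FIML multivariate-normal engine -------------------------------
## Y: n x W outcome with NA for missing waves.
## D: n x W x q mean design array (mu = apply over q of D * beta).
## cov_fun(cpar) -> W x W covariance.
## Patterns of observed waves are grouped once; the likelihood is evaluated
## per group with a Cholesky of the pattern's covariance submatrix.
fiml_patterns <- function(Y) {
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  split(seq_len(nrow(Y)), key)
}

fiml_negll <- function(par, Y, D, cov_fun, q, patterns, per_individual = FALSE) {
  beta <- par[seq_len(q)]
  Sigma <- cov_fun(par[-seq_len(q)])
  if (anyNA(Sigma) || any(!is.finite(Sigma))) return(if (per_individual) rep(1e10, nrow(Y)) else 1e10)
  W <- ncol(Y)
  mu <- matrix(0, nrow(Y), W)
  for (j in seq_len(q)) mu <- mu + D[, , j, drop = TRUE] * beta[j]
  ll <- if (per_individual) numeric(nrow(Y)) else 0
  for (idx in patterns) {
    obs <- which(!is.na(Y[idx[1], ]))
    if (length(obs) == 0) next
    S <- Sigma[obs, obs, drop = FALSE]
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L)) return(if (per_individual) rep(1e10, nrow(Y)) else 1e10)
    R <- Y[idx, obs, drop = FALSE] - mu[idx, obs, drop = FALSE]
    Z <- R %*% backsolve(L, diag(length(obs)))
    logdet <- 2 * sum(log(diag(L)))
    li <- -0.5 * (length(obs) * log(2 * pi) + logdet + rowSums(Z^2))
    if (per_individual) ll[idx] <- li else ll <- ll + sum(li)
  }
  if (per_individual) -ll else -ll
}

fit_fiml_mvn <- function(Y, D, cov_fun, start, q, lower = NULL, control = list()) {
  patterns <- fiml_patterns(Y)
  obj <- function(p) fiml_negll(p, Y, D, cov_fun, q, patterns)
  lower <- lower %||% rep(-Inf, length(start))
  opt <- stats::nlminb(start, obj, lower = lower,
                       control = utils::modifyList(
                         list(iter.max = 2000, eval.max = 4000,
                              rel.tol = 1e-10), control))
  grad <- num_grad(obj, opt$par)
  at_bound <- is.finite(lower) & (opt$par <= lower + 1e-6)
  gnorm <- if (all(at_bound)) 0 else max(abs(grad[!at_bound]))
  list(par = opt$par, loglik = -opt$objective,
       converged = opt$convergence == 0 || gnorm < 1e-3,
       gradient_norm = gnorm, objective = obj, patterns = patterns)
}

## Mean design for the growth model and its saturated / baseline companions.
lgcm_mean_design <- function(Y, lam, sexM, age_dev, terms, kind = "growth") {
  n <- nrow(Y); W <- ncol(Y)
  cols <- list()
  if (kind == "growth") {
    cols$alpha0 <- matrix(1, n, W)
    cols$alpha1 <- matrix(lam, n, W, byrow = TRUE)
    if (terms$sex_int) cols$sex_intercept <- matrix(sexM, n, W)
    if (terms$sex_slo) cols$sex_slope <- outer(sexM, lam)
    if (terms$age) cols$beta_age <- age_dev
  } else {
    for (w in seq_len(W)) {
      m <- matrix(0, n, W); m[, w] <- 1
      cols[[paste0("mean_w", w)]] <- m
    }
    if (terms$sex_int || terms$sex_slo) {
      for (w in seq_len(W)) {
        m <- matrix(0, n, W); m[, w] <- sexM
        cols[[paste0("sex_w", w)]] <- m
      }
    }
    if (terms$age) cols$beta_age <- age_dev
  }
  D <- array(unlist(cols), dim = c(n, W, length(cols)),
             dimnames = list(NULL, NULL, names(cols)))
  D
}

lgcm_cov_fun <- function(lam) {
  W <- length(lam)
  Lmb <- cbind(1, lam)
  function(cp) {
    L <- matrix(c(exp(cp[1]), 0, cp[2], exp(cp[3])), 2, 2, byrow = TRUE)
    Psi <- L %*% t(L)
    Theta <- diag(exp(cp[3 + seq_len(W)]), W)
    Lmb %*% Psi %*% t(Lmb) + Theta
  }
}

#' Fit a latent growth curve model by full-information maximum likelihood
#'
#' Two-factor (intercept, slope) growth model on 4-wave BMI (or TMI) with a
#' fixed time basis, a single shared within-wave age-adjustment coefficient,
#' optional sex effects on the growth-factor means, and per-wave residual
#' variances. Missing waves enter through each individual's observed-data
#' likelihood. Alongside the growth model, the saturated (free means, free
#' covariance) and independence baseline models are fitted on the same data
#' for chi-square-based fit indices.
#'
#' @param cohort a `twin_cohort` with BMI (or TMI) waves.
#' @param spec an [lgcm_spec()].
#' @param measure `"bmi"` or `"tmi"` wave columns to model.
#' @return An object of class `lgcm_fit` with parameter estimates (growth
#'   factor means `alpha`, covariance `Psi`, residual variances `Theta`,
#'   age/sex coefficients), model-based vcov, log-likelihoods and chi-square
#'   statistics of the model, saturated and baseline fits.
#' @export
fit_lgcm <- function(cohort, spec = lgcm_spec(), measure = c("bmi", "tmi")) {
  measure <- match.arg(measure)
  W <- sum(grepl("^age_[0-9]+$", names(cohort)))
  ycols <- paste0(measure, "_", seq_len(W))
  if (!all(ycols %in% names(cohort))) {
    stop("cohort lacks ", measure, " wave columns; run simulate_bmi_trajectories()",
         if (measure == "tmi") " and compute_tmi()" else "", call. = FALSE)
  }
  Y <- as.matrix(cohort[ycols])
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  AGE <- as.matrix(cohort[paste0("age_", seq_len(W))])[keep, , drop = FALSE]
  sexM <- as.numeric(cohort$sex[keep] == "M")
  ref <- spec$reference_ages %||%
    (attr(cohort, "cohort_spec")$wave_mean_ages %||% colMeans(AGE, na.rm = TRUE))
  lam <- growth_loadings(ref, spec$scheme)
  age_dev <- AGE - matrix(ref, nrow(AGE), W, byrow = TRUE)
  age_dev[is.na(age_dev)] <- 0

  fit_once <- function(terms) {
    D <- lgcm_mean_design(Y, lam, sexM, age_dev, terms, "growth")
    q <- dim(D)[3]
    m1 <- colMeans(Y, na.rm = TRUE)
    a1_start <- if (max(lam) > 0) (m1[W] - m1[1]) / lam[W] else 0
    start_mean <- c(m1[1], a1_start, rep(0, q - 2))
    vy <- stats::var(Y[, 1], na.rm = TRUE)
    start_cov <- c(log(sqrt(max(vy * 0.8, 0.1))), 0, log(0.5), rep(log(0.25), W))
    ## residual variances floored at 1e-4 so exactly rank-2 (noise-free) data
    ## stays on a bounded likelihood surface
    low <- c(rep(-Inf, q + 3), rep(log(1e-4), W))
    f <- fit_fiml_mvn(Y, D, lgcm_cov_fun(lam), c(start_mean, start_cov), q,
                      lower = low)
    f$terms <- terms; f$q <- q; f$D <- D
    f$par_names <- c(dimnames(D)[[3]],
                     c("lpsi11", "psi21", "lpsi22", paste0("ltheta", seq_len(W))))
    f
  }

  terms <- list(sex_int = spec$sex_adjustment != "never",
                sex_slo = spec$sex_adjustment != "never",
                age = spec$adjust_within_wave_age)
  f <- fit_once(terms)
  sex_p <- c(intercept = NA_real_, slope = NA_real_)
  if (spec$sex_adjustment %in% c("auto", "always")) {
    H <- num_hess(f$objective, f$par)
    V <- tryCatch(solve(H), error = function(e) matrix(NA, length(f$par), length(f$par)))
    for (nm in c("sex_intercept", "sex_slope")) {
      j <- match(nm, f$par_names)
      if (!is.na(j) && is.finite(V[j, j]) && V[j, j] > 0) {
        z <- f$par[j] / sqrt(V[j, j])
        sex_p[if (nm == "sex_intercept") "intercept" else "slope"] <-
          2 * stats::pnorm(-abs(z))
      }
    }
    if (spec$sex_adjustment == "auto") {
      terms$sex_int <- isTRUE(sex_p["intercept"] < spec$sex_effect_alpha)
      terms$sex_slo <- isTRUE(sex_p["slope"] < spec$sex_effect_alpha)
      f <- fit_once(terms)
    }
  }
  if (!f$converged) {
    stop("LGCM did not converge (gradient norm ", signif(f$gradient_norm, 3),
         "); best parameters: ", paste(signif(f$par, 4), collapse = ", "),
         call. = FALSE)
  }

  ## saturated and baseline fits for indices
  sat_D <- lgcm_mean_design(Y, lam, sexM, age_dev, terms, "saturated")
  q_sat <- dim(sat_D)[3]
  tri <- which(lower.tri(diag(W), diag = TRUE))
  diag_pos <- match(which(lower.tri(diag(W), diag = TRUE) & row(diag(W)) == col(diag(W))), tri)
  sat_cov <- function(cp) {
    L <- matrix(0, W, W)
    L[tri] <- cp
    diag(L) <- exp(cp[diag_pos])
    L %*% t(L)
  }
  Sobs <- stats::cov(Y, use = "pairwise.complete.obs")
  Sobs[is.na(Sobs)] <- 0
  Ls <- tryCatch(t(chol(Sobs + diag(1e-4, W))), error = function(e) diag(sqrt(diag(Sobs))))
  cp0 <- numeric(length(tri))
  cp0 <- Ls[tri]
  cp0[diag_pos] <- log(pmax(diag(Ls), 1e-3))
  sat_start <- c(colMeans(Y, na.rm = TRUE),
                 rep(0, q_sat - W - terms$age), if (terms$age) 0, cp0)
  sat_low <- rep(-Inf, q_sat + length(tri))
  sat_low[q_sat + diag_pos] <- log(1e-3)
  sat <- fit_fiml_mvn(Y, sat_D, sat_cov, sat_start[seq_len(q_sat + length(tri))],
                      q_sat, lower = sat_low)
  base_cov <- function(cp) diag(exp(cp), W)
  base <- fit_fiml_mvn(Y, sat_D, base_cov,
                       c(sat_start[seq_len(q_sat)],
                         log(apply(Y, 2, stats::var, na.rm = TRUE))), q_sat,
                       lower = c(rep(-Inf, q_sat), rep(log(1e-6), W)))

  p_model <- length(f$par)
  p_sat <- q_sat + length(tri)
  p_base <- q_sat + W
  cpar <- f$par[-seq_len(f$q)]
  Lp <- matrix(c(exp(cpar[1]), 0, cpar[2], exp(cpar[3])), 2, 2, byrow = TRUE)
  Psi <- Lp %*% t(Lp)
  Theta <- exp(cpar[3 + seq_len(W)])

  beta <- f$par[seq_len(f$q)]
  names(beta) <- f$par_names[seq_len(f$q)]

  out <- list(
    par = f$par, par_names = f$par_names, q = f$q,
    alpha = c(intercept = unname(beta["alpha0"]), slope = unname(beta["alpha1"])),
    sex_effects = c(intercept = unname(beta["sex_intercept"]),
                    slope = unname(beta["sex_slope"])),
    sex_p = sex_p,
    beta_age = unname(beta["beta_age"]),
    Psi = Psi, Theta = Theta, loadings = lam, scheme = spec$scheme,
    reference_ages = ref,
    loglik = f$loglik, ll_sat = sat$loglik, ll_base = base$loglik,
    chi2 = max(0, 2 * (sat$loglik - f$loglik)), df = p_sat - p_model,
    chi2_base = max(0, 2 * (sat$loglik - base$loglik)), df_base = p_sat - p_base,
    n_used = nrow(Y), measure = measure, spec = spec,
    objective = f$objective, terms = f$terms,
    data = list(Y = Y, D = f$D, sexM = sexM, age_dev = age_dev,
                id = cohort$id[keep], family_id = cohort$family_id[keep]),
    converged = f$converged
  )
  class(out) <- "lgcm_fit"
  out
}

#' @export
print.lgcm_fit <- function(x, ...) {
  cat("Latent growth curve model (", x$scheme, " scheme, FIML, n = ",
      x$n_used, ")\n", sep = "")
  cat("  growth-factor means: intercept ", round(x$alpha[1], 3),
      ", slope ", round(x$alpha[2], 3), "\n", sep = "")
  if (any(!is.na(x$sex_effects))) {
    cat("  sex effects (M - F):",
        paste(names(x$sex_effects)[!is.na(x$sex_effects)],
              round(x$sex_effects[!is.na(x$sex_effects)], 3), collapse = ", "), "\n")
  }
  cat("  Psi:\n"); print(round(x$Psi, 4))
  cat("  residual variances:", paste(round(x$Theta, 4), collapse = ", "), "\n")
  cat("  loglik ", round(x$loglik, 2), "; chi2 = ", round(x$chi2, 2),
      " on ", x$df, " df\n", sep = "")
  invisible(x)
}

#' @export
coef.lgcm_fit <- function(object, ...) {
  stats::setNames(object$par, object$par_names)
}

#' @export
logLik.lgcm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' Chi-square-based fit indices of a growth model
#'
#' CFI, TLI and RMSEA (with a 90% confidence interval from the noncentral
#' chi-square distribution) computed against the independence baseline fitted
#' on the same data. `N` in the RMSEA denominator is the number of
#' individuals.
#'
#' @param fit an [fit_lgcm()] result.
#' @return A list of class `fit_indices`: `chi2`, `df`, `chi2_baseline`,
#'   `df_baseline`, `cfi`, `tli`, `rmsea`, `rmsea_ci` (90%), `rmsea_defined`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "lgcm_fit"))
  cm <- fit$chi2; dm <- fit$df
  cb <- fit$chi2_base; db <- fit$df_base
  N <- fit$n_used
  cfi <- 1 - max(cm - dm, 0) / max(cb - db, cm - dm, .Machine$double.eps)
  tli <- if (db > 0 && (cb / db - 1) != 0) ((cb / db) - (cm / dm)) / ((cb / db) - 1) else NA
  tli <- min(tli, 1)
  if (dm <= 0) {
    rmsea <- NA; ci <- c(NA, NA); defined <- FALSE
  } else {
    defined <- TRUE
    rmsea <- sqrt(max(cm - dm, 0) / (dm * (N - 1)))
    ncp_for <- function(p) {
      if (stats::pchisq(cm, dm) < p) return(0)
      stats::uniroot(function(nc) stats::pchisq(cm, dm, ncp = nc) - p,
                     c(0, max(10 * cm, 1)), extendInt = "downX")$root
    }
    ci <- sqrt(pmax(c(ncp_for(0.95), ncp_for(0.05)), 0) / (dm * (N - 1)))
  }
  structure(list(chi2 = cm, df = dm, chi2_baseline = cb, df_baseline = db,
                 cfi = cfi, tli = tli, rmsea = rmsea, rmsea_ci = ci,
                 rmsea_defined = defined),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2 = %.2f (df %d); baseline chi2 = %.2f (df %d)\n",
              x$chi2, x$df, x$chi2_baseline, x$df_baseline))
  cat(sprintf("CFI = %.3f, TLI = %.3f, RMSEA = %.3f [%.3f, %.3f]\n",
              x$cfi, x$tli, x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2]))
  invisible(x)
}

#' Choose between the linear and logarithmic time bases
#'
#' The linear scheme is retained when it meets all three conventional cutoffs
#' (RMSEA < 0.06, CFI > 0.95, TLI > 0.95); otherwise the logarithmic scheme
#' is preferred when it meets them; otherwise the better-RMSEA scheme is
#' returned with a `good_fit = FALSE` flag.
#'
#' @param indices_linear,indices_log [fit_indices()] of the two fits.
#' @return `list(scheme =, good_fit =)`.
#' @export
select_scheme <- function(indices_linear, indices_log) {
  good <- function(ix) {
    isTRUE(ix$rmsea < 0.06) && isTRUE(ix$cfi > 0.95) && isTRUE(ix$tli > 0.95)
  }
  if (good(indices_linear)) return(list(scheme = "linear", good_fit = TRUE))
  if (good(indices_log)) return(list(scheme = "logarithmic", good_fit = TRUE))
  best <- if (isTRUE(indices_linear$rmsea <= indices_log$rmsea)) "linear" else "logarithmic"
  list(scheme = best, good_fit = FALSE)
}

#' Cluster-robust (sandwich) parameter covariance of a growth model
#'
#' `H^-1 (sum_f g_f g_f') H^-1` with `g_f` the summed per-individual score
#' over family `f` and `H` the observed information, correcting standard
#' errors for family clustering.
#'
#' @param fit an [fit_lgcm()] result.
#' @param cluster cluster labels, one per used individual; defaults to the
#'   family ids stored in the fit.
#' @return Robust covariance matrix of the parameter vector (named).
#' @export
robust_se <- function(fit, cluster = NULL) {
  stopifnot(inherits(fit, "lgcm_fit"))
  cluster <- cluster %||% fit$data$family_id
  check_that(length(cluster) == fit$n_used, "cluster", "one label per used individual")
  Y <- fit$data$Y; D <- fit$data$D
  patterns <- fiml_patterns(Y)
  cf <- lgcm_cov_fun(fit$loadings)
  ll_i <- function(p) -fiml_negll(p, Y, D, cf, fit$q, patterns, per_individual = TRUE)
  p <- fit$par
  S <- matrix(0, length(p), nrow(Y))
  for (j in seq_along(p)) {
    d <- 1e-6 * max(abs(p[j]), 1)
    pp <- p; pp[j] <- p[j] + d
    pm <- p; pm[j] <- p[j] - d
    S[j, ] <- (ll_i(pp) - ll_i(pm)) / (2 * d)
  }
  G <- rowsum(t(S), group = cluster)      # clusters x p
  meat <- crossprod(G)
  H <- num_hess(fit$objective, p)
  Hi <- tryCatch(solve(H), error = function(e) {
    stop("singular observed information (condition number ",
         signif(kappa(H), 3), ")", call. = FALSE)
  })
  V <- Hi %*% meat %*% Hi
  dimnames(V) <- list(fit$par_names, fit$par_names)
  V
}

#' Extract per-individual growth-factor scores
#'
#' Regression-method (empirical-Bayes) factor scores using each individual's
#' observed waves:
#' `eta_hat = alpha_i + Psi L_i' (L_i Psi L_i' + Theta_i)^-1 (y_i - mu_i)`.
#'
#' @param fit an [fit_lgcm()] result.
#' @return Data frame of class `growth_factor_set`: `id`, `intercept`,
#'   `slope`, `scheme`.
#' @export
extract_growth_factors <- function(fit) {
  stopifnot(inherits(fit, "lgcm_fit"))
  Y <- fit$data$Y; D <- fit$data$D
  W <- ncol(Y)
  Lmb <- cbind(1, fit$loadings)
  Sigma <- Lmb %*% fit$Psi %*% t(Lmb) + diag(fit$Theta, W)
  beta <- fit$par[seq_len(fit$q)]
  mu <- matrix(0, nrow(Y), W)
  for (j in seq_len(fit$q)) mu <- mu + D[, , j, drop = TRUE] * beta[j]
  a0 <- beta[1] + if (fit$terms$sex_int) fit$data$sexM * beta[match("sex_intercept", fit$par_names)] else 0
  a1 <- beta[2] + if (fit$terms$sex_slo) fit$data$sexM * beta[match("sex_slope", fit$par_names)] else 0
  scores <- matrix(NA_real_, nrow(Y), 2)
  for (idx in fiml_patterns(Y)) {
    obs <- which(!is.na(Y[idx[1], ]))
    if (length(obs) == 0) next
    K <- fit$Psi %*% t(Lmb[obs, , drop = FALSE]) %*%
      solve(Sigma[obs, obs, drop = FALSE])
    R <- Y[idx, obs, drop = FALSE] - mu[idx, obs, drop = FALSE]
    scores[idx, ] <- R %*% t(K)
  }
  out <- data.frame(id = fit$data$id,
                    intercept = a0 + scores[, 1], slope = a1 + scores[, 2],
                    scheme = fit$scheme, stringsAsFactors = FALSE)
  class(out) <- c("growth_factor_set", "data.frame")
  out
}

#' Add triponderal mass index waves to a cohort
#'
#' `TMI = weight / height^3` (kg m^-3); the downstream pipeline accepts TMI
#' wherever BMI is accepted via the `measure` argument.
#'
#' @param cohort a `twin_cohort` with height and weight waves.
#' @return The cohort with `tmi_<w>` and `tmi_at_sampling` columns.
#' @export
compute_tmi <- function(cohort) {
  W <- sum(grepl("^age_[0-9]+$", names(cohort)))
  for (w in seq_len(W)) {
    h <- cohort[[paste0("height_", w)]]
    if (any(!is.na(h) & h <= 0)) stop("nonpositive height at wave ", w, call. = FALSE)
    cohort[[paste0("tmi_", w)]] <- cohort[[paste0("weight_", w)]] / h^3
  }
  cohort$tmi_at_sampling <- cohort[[paste0("tmi_", W)]]
  cohort
}
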