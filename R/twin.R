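#' Arrange individual-level data into twin pairs
#'
#' Builds the pairwise structure consumed by the twin-model fitters. Families
#' of two become a pair; families of one (or with a co-twin missing all
#' traits) are retained as incomplete pairs and contribute through their
#' marginal likelihood. Observation vectors are twin-major: all of twin 1's
#' traits, then twin 2's.
#'
#' @param data data frame with one row per individual: `family_id`,
#'   `zygosity`, the trait columns and any covariate columns.
#' @param traits character vector of 1 or 2 trait column names.
#' @param covariates character vector of covariate column names regressed out
#'   of the means during model fitting (default none).
#' @return An object of class `twin_pairs`.
#' @export
make_twin_pairs <- function(data, traits, covariates = character(0)) {
  check_that(length(traits) %in% 1:2, "traits", "must name 1 or 2 columns")
  check_that(all(c(traits, covariates, "family_id", "zygosity") %in% names(data)),
             "data", "missing required columns")
  k <- length(traits)
  fam <- factor(data$family_id, levels = unique(data$family_id))
  idx <- split(seq_len(nrow(data)), fam)
  n_pairs <- length(idx)
  y <- matrix(NA_real_, n_pairs, 2 * k)
  qx <- 1 + length(covariates)
  Xc <- array(NA_real_, c(n_pairs, 2, qx))
  zyg <- character(n_pairs)
  for (f in seq_len(n_pairs)) {
    rows <- idx[[f]]
    zyg[f] <- as.character(data$zygosity[rows[1]])
    for (t in seq_along(rows)[1:min(2, length(rows))]) {
      r <- rows[t]
      y[f, (t - 1) * k + seq_len(k)] <- as.numeric(data[r, traits])
      Xc[f, t, ] <- c(1, as.numeric(data[r, covariates]))
    }
    if (length(rows) > 2) {
      stop("family with more than 2 members: ", data$family_id[rows[1]],
           call. = FALSE)
    }
  }
  ## zygosity NA (singletons) cannot inform pair covariance; their marginal
  ## likelihood is zygosity-free, so group them with DZ for bookkeeping
  zyg[is.na(zyg) | !(zyg %in% c("MZ", "DZ"))] <- "DZ"
  structure(list(y = y, X = Xc, zyg = zyg, k = k, traits = traits,
                 covariates = covariates),
            class = "twin_pairs")
}

#' @export
print.twin_pairs <- function(x, ...) {
  complete <- rowSums(is.na(x$y)) == 0
  cat("Twin pairs:", nrow(x$y), "families,", x$k, "trait(s) [",
      paste(x$traits, collapse = ", "), "]\n")
  cat("  complete pairs: MZ", sum(x$zyg == "MZ" & complete),
      " DZ", sum(x$zyg == "DZ" & complete), "\n")
  invisible(x)
}

## ---- pattern-grouped FIML engine with GLS-profiled means -------------------
## Sigma_fun(theta) must return list(MZ = , DZ = ) of (2k x 2k) covariances.
## Means are profiled: at each theta the GLS estimate of the mean
## coefficients is computed in closed form via per-group whitening, so the
## optimizer only travels the variance-component space.
twin_groups <- function(pairs) {
  mask <- ifelse(is.na(pairs$y), "0", "1")
  key <- paste(pairs$zyg, apply(mask, 1, paste, collapse = ""))
  split(seq_len(nrow(pairs$y)), key)
}

## mean design per pair entry: entry (twin t, trait j) regresses on twin t's
## covariates with trait-specific coefficients
twin_mean_design <- function(pairs) {
  k <- pairs$k
  qx <- dim(pairs$X)[3]
  q <- k * qx
  n <- nrow(pairs$y)
  D <- array(0, c(n, 2 * k, q))
  for (t in 1:2) {
    for (j in seq_len(k)) {
      e <- (t - 1) * k + j
      cols <- (j - 1) * qx + seq_len(qx)
      D[, e, cols] <- pairs$X[, t, ]
    }
  }
  D
}

twin_negll <- function(theta, pairs, Sigma_fun, groups, D) {
  Sig <- Sigma_fun(theta)
  if (is.null(Sig)) return(1e10)
  q <- dim(D)[3]
  bigY <- numeric(0)
  bigX <- NULL
  logdet_total <- 0
  n_obs <- 0
  chunks <- vector("list", length(groups))
  ci <- 0
  for (g in groups) {
    zyg <- pairs$zyg[g[1]]
    obs <- which(!is.na(pairs$y[g[1], ]))
    if (length(obs) == 0) next
    S <- Sig[[zyg]][obs, obs, drop = FALSE]
    U <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    Ui <- backsolve(U, diag(length(obs)))
    Yw <- pairs$y[g, obs, drop = FALSE] %*% Ui
    Xw <- matrix(0, length(g) * length(obs), q)
    for (j in seq_len(q)) {
      Xw[, j] <- as.vector(D[g, obs, j, drop = FALSE][, , 1] %*% Ui)
    }
    ci <- ci + 1
    chunks[[ci]] <- list(y = as.vector(Yw), X = Xw)
    logdet_total <- logdet_total + length(g) * 2 * sum(log(diag(U)))
    n_obs <- n_obs + length(g) * length(obs)
  }
  chunks <- chunks[seq_len(ci)]
  bigY <- unlist(lapply(chunks, `[[`, "y"))
  bigX <- do.call(rbind, lapply(chunks, `[[`, "X"))
  fit <- stats::lm.fit(bigX, bigY)
  rss <- sum(fit$residuals^2)
  0.5 * (n_obs * log(2 * pi) + logdet_total + rss)
}

twin_beta_at <- function(theta, pairs, Sigma_fun, groups, D) {
  ## same whitening as twin_negll but returns the GLS mean coefficients
  Sig <- Sigma_fun(theta)
  q <- dim(D)[3]
  ys <- list(); Xs <- list(); ci <- 0
  for (g in groups) {
    zyg <- pairs$zyg[g[1]]
    obs <- which(!is.na(pairs$y[g[1], ]))
    if (length(obs) == 0) next
    U <- chol(Sig[[zyg]][obs, obs, drop = FALSE])
    Ui <- backsolve(U, diag(length(obs)))
    Yw <- pairs$y[g, obs, drop = FALSE] %*% Ui
    Xw <- matrix(0, length(g) * length(obs), q)
    for (j in seq_len(q)) {
      Xw[, j] <- as.vector(D[g, obs, j, drop = FALSE][, , 1] %*% Ui)
    }
    ci <- ci + 1
    ys[[ci]] <- as.vector(Yw); Xs[[ci]] <- Xw
  }
  stats::lm.fit(do.call(rbind, Xs), unlist(ys))$coefficients
}

twin_fit_engine <- function(pairs, Sigma_fun, start, lower = NULL, upper = NULL) {
  groups <- twin_groups(pairs)
  D <- twin_mean_design(pairs)
  obj <- function(th) twin_negll(th, pairs, Sigma_fun, groups, D)
  lo <- lower %||% rep(-Inf, length(start))
  hi <- upper %||% rep(Inf, length(start))
  opt <- NULL
  ## deterministic restart ladder: keeps fits reproducible under a fixed seed
  scales <- c(1, 0.7, 1.4, 0.85)
  for (try in 1:4) {
    s <- start * scales[try]
    cand <- stats::nlminb(s, obj, lower = lo, upper = hi,
                          control = list(iter.max = 1000, eval.max = 2000,
                                         rel.tol = 1e-12))
    if (is.null(opt) || cand$objective < opt$objective) opt <- cand
    grad <- num_grad(obj, opt$par)
    if (opt$convergence == 0 || max(abs(grad)) < 1e-2) break
  }
  if (!(opt$convergence == 0 || max(abs(grad)) < 1e-2)) {
    stop("twin model did not converge; gradient: ",
         paste(signif(grad, 3), collapse = ", "), call. = FALSE)
  }
  list(theta = opt$par, m2ll = 2 * opt$objective, objective = obj,
       beta = twin_beta_at(opt$par, pairs, Sigma_fun, groups, D),
       groups = groups, D = D)
}

## ---- saturated twin correlations -------------------------------------------

#' Twin correlations from saturated bivariate-normal models
#'
#' Fits, separately per zygosity group, a bivariate normal with
#' covariate-regressed means, a common variance and a free within-pair
#' correlation (twin order exchangeable), by maximum likelihood over the
#' observed-data patterns. Confidence intervals use the Fisher z transform
#' with the number of complete pairs.
#'
#' @param pairs a univariate [make_twin_pairs()].
#' @param conf confidence level (default 0.95).
#' @return An object of class `saturated_fit`: `rMZ`, `rDZ` with CIs,
#'   per-zygosity means/variances, `minus2ll`.
#' @export
twin_correlations <- function(pairs, conf = 0.95) {
  stopifnot(inherits(pairs, "twin_pairs"), pairs$k == 1)
  if (!all(c("MZ", "DZ") %in% pairs$zyg)) {
    stop("both zygosity groups required to estimate twin correlations", call. = FALSE)
  }
  out <- list()
  m2ll <- 0
  for (z in c("MZ", "DZ")) {
    sel <- pairs$zyg == z
    if (sum(sel & rowSums(!is.na(pairs$y)) == 2) < 10) {
      warning("fewer than 10 complete ", z, " pairs; correlation unstable",
              call. = FALSE)
    }
    sub <- pairs
    sub$y <- pairs$y[sel, , drop = FALSE]
    sub$X <- pairs$X[sel, , , drop = FALSE]
    sub$zyg <- pairs$zyg[sel]
    Sigma_fun <- function(th) {
      v <- exp(th[1]); r <- tanh(th[2])
      S <- matrix(c(v, r * v, r * v, v), 2)
      list(MZ = S, DZ = S)
    }
    v0 <- stats::var(as.vector(sub$y), na.rm = TRUE)
    f <- twin_fit_engine(sub, Sigma_fun, c(log(v0), 0))
    n_complete <- sum(rowSums(!is.na(sub$y)) == 2)
    r <- tanh(f$theta[2])
    zse <- 1 / sqrt(max(n_complete - 3, 1))
    ci <- tanh(atanh(r) + stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2)) * zse)
    out[[z]] <- list(r = r, ci = ci, var = exp(f$theta[1]), beta = f$beta,
                     n_complete = n_complete)
    m2ll <- m2ll + f$m2ll
  }
  structure(list(rMZ = out$MZ$r, rMZ_ci = out$MZ$ci,
                 rDZ = out$DZ$r, rDZ_ci = out$DZ$ci,
                 var_mz = out$MZ$var, var_dz = out$DZ$var,
                 beta_mz = out$MZ$beta, beta_dz = out$DZ$beta,
                 n_mz = out$MZ$n_complete, n_dz = out$DZ$n_complete,
                 minus2ll = m2ll, conf = conf),
            class = "saturated_fit")
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat(sprintf("Saturated twin correlations: rMZ = %.3f [%.3f, %.3f] (n = %d), rDZ = %.3f [%.3f, %.3f] (n = %d)\n",
              x$rMZ, x$rMZ_ci[1], x$rMZ_ci[2], x$n_mz,
              x$rDZ, x$rDZ_ci[1], x$rDZ_ci[2], x$n_dz))
  invisible(x)
}

#' Candidate model family from the twin-correlation signature
#'
#' `rDZ/rMZ > 0.5` indicates shared environment can be modelled (candidates
#' ACE, AE, CE, E); a ratio at or below 0.5 points to non-additive genetic
#' variance, which is not modelled here, so only AE is fitted. Non-positive
#' `rMZ` yields the E family only, flagged.
#'
#' @param sat a [twin_correlations()] result.
#' @return `list(candidates = character, ratio =, flag =)`.
#' @export
choose_model_family <- function(sat) {
  stopifnot(inherits(sat, "saturated_fit"))
  if (sat$rMZ <= 0) {
    return(list(candidates = "E", ratio = NA_real_,
                flag = "rMZ <= 0: no familial resemblance"))
  }
  ratio <- sat$rDZ / sat$rMZ
  if (ratio > 0.5) {
    list(candidates = c("ACE", "AE", "CE", "E"), ratio = ratio, flag = NULL)
  } else {
    list(candidates = "AE", ratio = ratio,
         flag = "rDZ/rMZ <= 0.5: dominance indicated but not modelled")
  }
}

## ---- univariate variance-component models ----------------------------------

univariate_sigma_fun <- function(model) {
  function(th) {
    A <- C <- 0; i <- 1
    if (grepl("A", model)) { A <- th[i]; i <- i + 1 }
    if (grepl("C", model)) { C <- th[i]; i <- i + 1 }
    E <- th[i]
    V <- A + C + E
    if (V <= 0 || E <= 0) return(NULL)
    mk <- function(cv) {
      if (abs(cv) >= V) return(NULL)
      matrix(c(V, cv, cv, V), 2)
    }
    Smz <- mk(A + C); Sdz <- mk(0.5 * A + C)
    if (is.null(Smz) || is.null(Sdz)) return(NULL)
    list(MZ = Smz, DZ = Sdz)
  }
}

#' Fit a univariate variance-component twin model
#'
#' FIML over twin pairs with expected covariance `A + C` (MZ) or
#' `0.5 A + C` (DZ) and total variance `V = A + C + E`. Components are
#' parameterized directly as unbounded variances (not squared paths), so
#' negative A or C estimates are attainable; E is kept positive. Means are
#' regressed on the pair covariates. Standardized components satisfy
#' `h2 + c2 + e2 = 1` by construction. 95% CIs for the standardized
#' components come from the profile likelihood (chi-square(1) cutoff,
#' bisection) for AE and CE models, and from the delta method (flagged) for
#' ACE.
#'
#' @param pairs a univariate [make_twin_pairs()].
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @param conf confidence level (default 0.95).
#' @return An object of class `univariate_fit`.
#' @export
fit_univariate <- function(pairs, model = c("AE", "ACE", "CE", "E"), conf = 0.95) {
  model <- match.arg(model)
  stopifnot(inherits(pairs, "twin_pairs"), pairs$k == 1)
  Sigma_fun <- univariate_sigma_fun(model)

  ## moment starts from double-entry correlations
  v0 <- stats::var(as.vector(pairs$y), na.rm = TRUE)
  de <- function(z) {
    sel <- pairs$zyg == z & rowSums(!is.na(pairs$y)) == 2
    if (sum(sel) < 3) return(0)
    stats::cor(c(pairs$y[sel, 1], pairs$y[sel, 2]),
               c(pairs$y[sel, 2], pairs$y[sel, 1]))
  }
  rmz <- de("MZ"); rdz <- de("DZ")
  A0 <- max(min(2 * (rmz - rdz), 0.9), -0.3) * v0
  C0 <- max(min(2 * rdz - rmz, 0.9), -0.3) * v0
  start <- switch(model,
                  ACE = c(A0, C0, max(v0 - A0 - C0, 0.05 * v0)),
                  AE = c(max(rmz, 0.1) * v0, max((1 - rmz), 0.1) * v0),
                  CE = c(max(rdz, 0.1) * v0, max((1 - rdz), 0.1) * v0),
                  E = v0)
  nv <- length(start)
  lower <- c(rep(-Inf, nv - 1), 1e-10)
  f <- twin_fit_engine(pairs, Sigma_fun, start, lower = lower)

  th <- f$theta
  A <- if (grepl("A", model)) th[1] else 0
  C <- if (grepl("C", model)) th[if (grepl("A", model)) 2 else 1] else 0
  E <- th[nv]
  V <- A + C + E
  est <- c(h2 = A / V, c2 = C / V, e2 = E / V)

  npar <- nv + length(f$beta)
  ci <- list(h2 = c(NA, NA), c2 = c(NA, NA), e2 = c(NA, NA))
  ci_method <- "none"
  cut <- stats::qchisq(conf, 1)
  if (model %in% c("AE", "CE")) {
    ## profile the single standardized fraction; V and means re-optimized
    comp <- if (model == "AE") "h2" else "c2"
    groups <- twin_groups(pairs); D <- twin_mean_design(pairs)
    prof <- function(fr) {
      sf <- function(lv) {
        v <- exp(lv)
        univariate_sigma_fun(model)(if (model == "AE") c(fr * v, (1 - fr) * v)
                                    else c(fr * v, (1 - fr) * v))
      }
      o <- stats::optimize(function(lv) {
        twin_negll(1, pairs, function(...) sf(lv), groups, D)
      }, interval = log(v0) + c(-4, 4))
      2 * o$objective
    }
    m2ll_min <- f$m2ll
    bound <- function(side) {
      fhat <- est[comp]
      lim <- if (side < 0) -0.499 else 0.999
      gap <- function(fr) prof(fr) - (m2ll_min + cut)
      if (gap(lim) < 0) return(lim)
      lo <- fhat; hi <- lim
      for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (gap(mid) > 0) hi <- mid else lo <- mid
        if (abs(hi - lo) < 1e-4) break
      }
      (lo + hi) / 2
    }
    b <- sort(c(bound(-1), bound(1)))
    ci[[comp]] <- b
    ci[[if (model == "AE") "e2" else "e2"]] <- sort(1 - b)
    ci_method <- "profile"
  } else if (model == "ACE") {
    H <- num_hess(f$objective, th)
    Vth <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vth)) {
      for (comp in c("h2", "c2", "e2")) {
        gfun <- function(t) {
          a <- t[1]; c <- t[2]; e <- t[3]; v <- a + c + e
          switch(comp, h2 = a / v, c2 = c / v, e2 = e / v)
        }
        gr <- num_grad(gfun, th)
        se <- sqrt(max(as.numeric(t(gr) %*% Vth %*% gr), 0))
        ci[[comp]] <- est[comp] + stats::qnorm(c((1 - conf) / 2,
                                                 1 - (1 - conf) / 2)) * se
      }
      ci_method <- "delta"
    }
  }

  structure(list(model = model, A = A, C = C, E = E, V = V,
                 h2 = unname(est["h2"]), c2 = unname(est["c2"]),
                 e2 = unname(est["e2"]),
                 ci = ci, ci_method = ci_method, conf = conf,
                 beta = f$beta, minus2ll = f$m2ll,
                 aic = f$m2ll + 2 * npar, npar = npar),
            class = "univariate_fit")
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("%s twin model: h2 = %.3f, c2 = %.3f, e2 = %.3f (%s CIs)\n",
              x$model, x$h2, x$c2, x$e2, x$ci_method))
  if (!all(is.na(x$ci$h2)))
    cat(sprintf("  h2 95%% CI [%.3f, %.3f]\n", x$ci$h2[1], x$ci$h2[2]))
  cat(sprintf("  -2lnL = %.2f, AIC = %.2f (%d parameters)\n",
              x$minus2ll, x$aic, x$npar))
  invisible(x)
}

#' Select among fitted twin models by AIC
#'
#' Minimum AIC wins; exact ties go to the model with fewer parameters.
#'
#' @param fits list of [fit_univariate()] results on identical data.
#' @return The winning fit, with a `comparison` attribute (model, -2lnL,
#'   parameters, AIC, delta-AIC).
#' @export
select_by_aic <- function(fits) {
  check_that(length(fits) >= 1, "fits", "need at least one fit")
  tab <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    minus2ll = vapply(fits, `[[`, 0, "minus2ll"),
                    npar = vapply(fits, function(f) as.numeric(f$npar), 0),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    stringsAsFactors = FALSE)
  tab$delta_aic <- tab$aic - min(tab$aic)
  ord <- order(tab$aic, tab$npar)
  best <- fits[[ord[1]]]
  attr(best, "comparison") <- tab[order(tab$aic, tab$npar), , drop = FALSE]
  best
}

## ---- bivariate Cholesky AE model -------------------------------------------

bivariate_sigma_fun <- function(th) {
  La <- matrix(c(th[1], 0, th[2], th[3]), 2, 2, byrow = TRUE)
  Le <- matrix(c(th[4], 0, th[5], th[6]), 2, 2, byrow = TRUE)
  A <- La %*% t(La); E <- Le %*% t(Le)
  W <- A + E
  if (any(!is.finite(W))) return(NULL)
  mk <- function(w) rbind(cbind(W, w * A), cbind(w * A, W))
  list(MZ = mk(1), DZ = mk(0.5), A = A, E = E)
}

#' Fit a bivariate AE Cholesky twin model
#'
#' Four-variate FIML per pair (two traits by two twins). The additive-genetic
#' and unique-environment 2x2 covariance blocks are Cholesky-parameterized
#' (so they are positive semidefinite and the latent correlations are bounded
#' by 1 at the ML point); the cross-twin block is `A` for MZ and `0.5 A` for
#' DZ pairs. Decomposes the phenotypic correlation into the genetic
#' correlation `rA = A12 / sqrt(A11 A22)` and the nonshared-environmental
#' correlation `rE = E12 / sqrt(E11 E22)`; at the ML point
#' `rPh = rA sqrt(h2_1 h2_2) + rE sqrt(e2_1 e2_2)` holds exactly. CIs for rA
#' and rE are delta-method on the Fisher-z scale.
#'
#' @param pairs a bivariate [make_twin_pairs()].
#' @param conf confidence level (default 0.95).
#' @return An object of class `bivariate_fit`: blocks `A` and `E`, `rA`,
#'   `rE` with CIs, per-trait `h2`, implied phenotypic correlation, and the
#'   cross-twin cross-trait correlations per zygosity.
#' @export
fit_bivariate_ae <- function(pairs, conf = 0.95) {
  stopifnot(inherits(pairs, "twin_pairs"), pairs$k == 2)
  ## moment-based starting values
  cc <- rowSums(is.na(pairs$y)) == 0
  vx <- stats::var(c(pairs$y[, 1], pairs$y[, 3]), na.rm = TRUE)
  vy <- stats::var(c(pairs$y[, 2], pairs$y[, 4]), na.rm = TRUE)
  rph <- stats::cor(c(pairs$y[cc, 1], pairs$y[cc, 3]),
                    c(pairs$y[cc, 2], pairs$y[cc, 4]))
  sa <- sqrt(vx * 0.5); se_ <- sqrt(vx * 0.5)
  sy_a <- sqrt(vy * 0.5); sy_e <- sqrt(vy * 0.5)
  start <- c(sa, rph * sy_a, sy_a * sqrt(max(1 - rph^2, 0.2)),
             se_, rph * sy_e, sy_e * sqrt(max(1 - rph^2, 0.2)))
  f <- twin_fit_engine(pairs, bivariate_sigma_fun, start)
  S <- bivariate_sigma_fun(f$theta)
  A <- S$A; E <- S$E
  if (min(diag(E)) <= 0) stop("inadmissible fit: unique-environment block not PD",
                              call. = FALSE)
  V <- diag(A) + diag(E)
  h2 <- diag(A) / V
  e2 <- diag(E) / V
  rA <- A[1, 2] / sqrt(A[1, 1] * A[2, 2])
  rE <- E[1, 2] / sqrt(E[1, 1] * E[2, 2])
  rph_implied <- rA * sqrt(h2[1] * h2[2]) + rE * sqrt(e2[1] * e2[2])
  ctct <- c(MZ = A[1, 2] / sqrt(V[1] * V[2]),
            DZ = 0.5 * A[1, 2] / sqrt(V[1] * V[2]))

  ## delta-method CIs on the Fisher-z scale
  H <- num_hess(f$objective, f$theta)
  Vth <- tryCatch(solve(H), error = function(e) NULL)
  ci_of <- function(which_block) {
    if (is.null(Vth)) return(c(NA, NA))
    g <- function(th) {
      s <- bivariate_sigma_fun(th)
      M <- if (which_block == "A") s$A else s$E
      r <- M[1, 2] / sqrt(M[1, 1] * M[2, 2])
      atanh(max(min(r, 1 - 1e-10), -1 + 1e-10))
    }
    gr <- num_grad(g, f$theta)
    sez <- sqrt(max(as.numeric(t(gr) %*% Vth %*% gr), 0))
    tanh(g(f$theta) + stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2)) * sez)
  }

  structure(list(A = A, E = E, rA = rA, rE = rE,
                 rA_ci = ci_of("A"), rE_ci = ci_of("E"),
                 h2 = h2, e2 = e2, rph_implied = rph_implied,
                 cross_twin_cross_trait = ctct,
                 beta = f$beta, minus2ll = f$m2ll,
                 npar = 6 + length(f$beta), conf = conf,
                 traits = pairs$traits),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate AE twin model [%s ~ %s]\n",
              x$traits[1], x$traits[2]))
  cat(sprintf("  rA = %.3f [%.3f, %.3f], rE = %.3f [%.3f, %.3f]\n",
              x$rA, x$rA_ci[1], x$rA_ci[2], x$rE, x$rE_ci[1], x$rE_ci[2]))
  cat(sprintf("  h2: %.3f / %.3f; implied rPh = %.3f\n",
              x$h2[1], x$h2[2], x$rph_implied))
  invisible(x)
}

#' Residualize a trait on an individual-level covariate
#'
#' Replaces the trait by its residual from an individual-level linear
#' regression on the covariate, for sensitivity re-runs of the bivariate
#' models (for example, adjusting the BMI slope by BMI at blood sampling).
#'
#' @param data individual-level data frame.
#' @param trait trait column name.
#' @param covariate covariate column name.
#' @return `data` with the trait column replaced by residuals.
#' @export
adjust_trait <- function(data, trait, covariate) {
  check_that(all(c(trait, covariate) %in% names(data)), "data",
             "missing trait or covariate column")
  x <- data[[covariate]]
  if (stats::sd(x, na.rm = TRUE) == 0) {
    stop("constant covariate '", covariate, "' cannot be regressed out",
         call. = FALSE)
  }
  ok <- stats::complete.cases(data[[trait]], x)
  res <- rep(NA_real_, nrow(data))
  fit <- stats::lm(data[[trait]][ok] ~ x[ok])
  res[ok] <- stats::residuals(fit)
  data[[trait]] <- res
  data
}
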