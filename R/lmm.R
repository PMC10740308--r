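#' Fit a twin-clustered linear mixed model by REML
#'
#' Random-intercept model tailored to twin data: a family intercept shared by
#' co-twins plus a second intercept shared only within MZ pairs, so MZ
#' co-twins may be more correlated than DZ co-twins. Families are blocks of
#' at most two individuals, which the fitter exploits: each pair is whitened
#' by its sum/difference contrasts, the residual variance is profiled out,
#' and the two variance ratios are optimized on a box-constrained scale
#' (boundary estimates of zero are permitted and flagged).
#'
#' Marginal covariance per individual: `s2_family + s2_mzpair + s2_residual`
#' on the diagonal; within-pair covariance `s2_family` (DZ) or
#' `s2_family + s2_mzpair` (MZ).
#'
#' @param y numeric outcome.
#' @param X fixed-effects design matrix (including the intercept column).
#' @param family_id family label per row; families must have 1 or 2 rows.
#' @param zygosity `"MZ"`, `"DZ"` or `NA` per row.
#' @param reml use REML (default) or ML.
#' @param theta optional fixed variance components
#'   `c(family =, mzpair =, residual =)`; when supplied no optimization is
#'   done and the fixed-effect GLS estimates at these components are
#'   returned.
#' @return An object of class `lmm_fit`: `beta`, `se`, `vcov_beta`, `theta`
#'   (named variance components), `theta_vcov` (asymptotic covariance of the
#'   non-boundary components), `loglik` (restricted), `boundary` flags,
#'   `n`, `p`.
#' @export
fit_lmm <- function(y, X, family_id, zygosity, reml = TRUE, theta = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  check_that(nrow(X) == n, "X", "row count must match outcome length")
  p <- ncol(X)
  fam <- factor(family_id, levels = unique(family_id))
  sizes <- table(fam)
  if (any(sizes > 2)) {
    stop("families with more than 2 members: ",
         paste(names(sizes)[sizes > 2], collapse = ", "), call. = FALSE)
  }
  idx_by_fam <- split(seq_len(n), fam)
  pair_idx <- do.call(rbind, idx_by_fam[sizes == 2])
  single_idx <- unlist(idx_by_fam[sizes == 1], use.names = FALSE)
  is_mz <- if (!is.null(pair_idx)) {
    z <- zygosity[pair_idx[, 1]]
    !is.na(z) & z == "MZ"
  } else logical(0)

  ## whitened design at variance ratios g = (gf, gm): returns transformed
  ## response/design rows and the per-row variance factors (in s2_res units)
  whiten <- function(gf, gm) {
    rows_y <- numeric(0); rows_X <- NULL; v <- numeric(0)
    if (!is.null(pair_idx)) {
      i1 <- pair_idx[, 1]; i2 <- pair_idx[, 2]
      a <- 1 + gf + gm
      b <- gf + ifelse(is_mz, gm, 0)
      ys <- (y[i1] + y[i2]) / sqrt(2); yd <- (y[i1] - y[i2]) / sqrt(2)
      Xs <- (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / sqrt(2)
      Xd <- (X[i1, , drop = FALSE] - X[i2, , drop = FALSE]) / sqrt(2)
      rows_y <- c(ys, yd); rows_X <- rbind(Xs, Xd)
      v <- c(a + b, a - b)
    }
    if (length(single_idx) > 0) {
      rows_y <- c(rows_y, y[single_idx])
      rows_X <- rbind(rows_X, X[single_idx, , drop = FALSE])
      v <- c(v, rep(1 + gf + gm, length(single_idx)))
    }
    list(y = rows_y / sqrt(v), X = rows_X / sqrt(v), logdet = sum(log(v)))
  }

  gls_at <- function(gf, gm) {
    w <- whiten(gf, gm)
    qr_w <- qr(w$X)
    beta <- qr.coef(qr_w, w$y)
    r <- w$y - w$X %*% beta
    rss <- sum(r^2)
    logdet_xtx <- 2 * sum(log(abs(diag(qr.R(qr_w)))))
    list(beta = beta, rss = rss, logdet_v = w$logdet,
         logdet_xtx = logdet_xtx, XtXi = chol2inv(qr.R(qr_w)))
  }

  ## profiled REML / ML criterion in the ratios
  crit <- function(par) {
    g <- gls_at(par[1], par[2])
    if (reml) {
      (n - p) * log(g$rss / (n - p)) + g$logdet_v + g$logdet_xtx
    } else {
      n * log(g$rss / n) + g$logdet_v
    }
  }

  ## identifiability: with no pairs both ratios collapse into the residual;
  ## with no MZ pairs the MZ-pair component has no information
  has_pairs <- !is.null(pair_idx)
  has_mz <- any(is_mz)
  if (is.null(theta)) {
    if (!has_pairs) {
      gf <- 0; gm <- 0
    } else if (!has_mz) {
      opt <- stats::nlminb(0.3, function(g) crit(c(g, 0)), lower = 0,
                           control = list(rel.tol = 1e-12))
      gf <- opt$par; gm <- 0
    } else {
      opt <- stats::nlminb(c(0.3, 0.3), crit, lower = c(0, 0),
                           control = list(rel.tol = 1e-12))
      gf <- opt$par[1]; gm <- opt$par[2]
    }
    g <- gls_at(gf, gm)
    s2e <- g$rss / (if (reml) n - p else n)
    theta <- c(family = gf * s2e, mzpair = gm * s2e, residual = s2e)
  } else {
    check_that(length(theta) == 3 && theta[3] > 0, "theta",
               "needs c(family, mzpair, residual) with residual > 0")
    theta <- stats::setNames(as.numeric(theta), c("family", "mzpair", "residual"))
    g <- gls_at(theta[1] / theta[3], theta[2] / theta[3])
    s2e <- theta[3]
  }
  boundary <- c(family = theta[["family"]] < 1e-8, mzpair = theta[["mzpair"]] < 1e-8)

  ## restricted log-likelihood at arbitrary theta (used for the information)
  reml_ll <- function(th) {
    if (any(th <= 0) && th[3] <= 0) return(-1e10)
    gf <- max(th[1], 0) / th[3]; gm <- max(th[2], 0) / th[3]
    gg <- gls_at(gf, gm)
    -0.5 * ((n - p) * log(2 * pi * th[3]) + gg$logdet_v + gg$logdet_xtx +
              gg$rss / th[3])
  }

  vcov_beta <- s2e * g$XtXi
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  active <- c(!boundary, TRUE)
  th_act <- theta[active]
  H <- num_hess(function(t) -reml_ll(replace(theta, which(active), t)), th_act)
  theta_vcov <- tryCatch(solve(H), error = function(e) diag(Inf, length(th_act)))

  structure(list(beta = stats::setNames(as.numeric(g$beta), colnames(X)),
                 se = sqrt(diag(vcov_beta)), vcov_beta = vcov_beta,
                 theta = theta, theta_vcov = theta_vcov, active = active,
                 loglik = reml_ll(theta), reml = reml, boundary = boundary,
                 n = n, p = p,
                 gls_at = gls_at),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Twin-clustered linear mixed model (", if (x$reml) "REML" else "ML",
      ", n = ", x$n, ")\n", sep = "")
  cat("  variance components: family ", signif(x$theta[1], 4),
      ", MZ-pair ", signif(x$theta[2], 4),
      ", residual ", signif(x$theta[3], 4),
      if (any(x$boundary)) "  [boundary]" else "", "\n", sep = "")
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$beta

#' Satterthwaite t-test for a fixed-effect contrast
#'
#' `t = c'beta / sqrt(c'Vc)` with denominator degrees of freedom
#' `df = 2 (c'Vc)^2 / (g' A g)`, where `g` is the gradient of the contrast
#' variance in the variance components (central finite differences, relative
#' step 1e-6) and `A` the asymptotic covariance of the component estimates.
#'
#' @param fit an [fit_lmm()] result.
#' @param contrast numeric contrast over the fixed effects, or the name of a
#'   single coefficient.
#' @return `list(estimate =, se =, t =, df =, p =)`.
#' @export
satterthwaite_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.character(contrast)) {
    j <- match(contrast, names(fit$beta))
    if (is.na(j)) stop("no coefficient named '", contrast, "'", call. = FALSE)
    contrast <- replace(numeric(length(fit$beta)), j, 1)
  }
  cvec <- as.numeric(contrast)
  fvar <- function(th_act) {
    th <- fit$theta
    th[which(fit$active)] <- th_act
    g <- fit$gls_at(max(th[1], 0) / th[3], max(th[2], 0) / th[3])
    th[3] * as.numeric(t(cvec) %*% g$XtXi %*% cvec)
  }
  th_act <- fit$theta[fit$active]
  v <- unname(fvar(th_act))
  grad <- num_grad(fvar, th_act, h = 1e-6)
  denom <- as.numeric(t(grad) %*% fit$theta_vcov %*% grad)
  df <- if (denom > 0 && is.finite(denom)) 2 * v^2 / denom else fit$n - fit$p
  if (df <= 0) stop("degenerate variance surface: nonpositive Satterthwaite df",
                    call. = FALSE)
  est <- unname(sum(cvec * fit$beta))
  se <- sqrt(v)
  tval <- est / se
  list(estimate = est, se = se, t = tval, df = unname(df),
       p = unname(2 * stats::pt(-abs(tval), df)))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, with `m` the number of tests performed in the
#' scan (failed fits still count).
#'
#' @param p p-values in `[0, 1]` (`NA` passed through).
#' @param m number of tests.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]", call. = FALSE)
  check_that(m >= 1, "m", "must be >= 1")
  pmin(1, m * p)
}

#' Assemble the per-individual phenotype table for association scans
#'
#' Joins cohort descriptors with extracted growth factors.
#'
#' @param cohort a `twin_cohort`.
#' @param growth a [extract_growth_factors()] result.
#' @return Data frame with `id`, `family_id`, `zygosity`, `sex`,
#'   `age_at_sampling`, `bmi_at_sampling`, `bmi_intercept`, `bmi_slope`.
#' @export
make_assoc_pheno <- function(cohort, growth) {
  m <- merge(
    data.frame(id = cohort$id, family_id = cohort$family_id,
               zygosity = cohort$zygosity, sex = cohort$sex,
               age_at_sampling = cohort$age_at_sampling,
               bmi_at_sampling = cohort$bmi_at_sampling,
               stringsAsFactors = FALSE),
    data.frame(id = growth$id, bmi_intercept = growth$intercept,
               bmi_slope = growth$slope, stringsAsFactors = FALSE),
    by = "id")
  m[order(m$id), , drop = FALSE]
}

## Covariate design shared by all scans: age at sampling (centered), age^2,
## sex, and the sex-by-age interactions; optional extra columns appended.
assoc_design <- function(pheno, extra = NULL) {
  age_c <- pheno$age_at_sampling - mean(pheno$age_at_sampling)
  sexM <- as.numeric(pheno$sex == "M")
  X <- cbind(`(Intercept)` = 1, age = age_c, age2 = age_c^2, sexM = sexM,
             `sexM:age` = sexM * age_c, `sexM:age2` = sexM * age_c^2)
  if (!is.null(extra)) X <- cbind(X, extra)
  X
}

#' Mixed-model association scan of omics features against a trajectory marker
#'
#' Per feature, fits [fit_lmm()] with the z-scored marker as outcome, the
#' z-scored feature as fixed predictor, and age at blood sampling, age
#' squared, sex and the sex-by-age interactions as covariates (plus the BMI
#' intercept when the outcome is the BMI slope, and optionally the batch).
#' The feature coefficient is tested with [satterthwaite_test()] and the
#' scan is Bonferroni-controlled over the number of features tested.
#'
#' @param pheno a [make_assoc_pheno()] table.
#' @param omics an [omics_matrix()], ideally preprocessed/z-scaled.
#' @param outcome `"bmi_at_sampling"`, `"bmi_slope"` or `"bmi_intercept"`.
#' @param alpha family-wise significance level (default 0.05).
#' @param include_batch add batch indicator covariates.
#' @return An `association_table` data frame (one row per feature: estimate,
#'   SE, t, Satterthwaite df, nominal and Bonferroni p, significance flag)
#'   sorted by nominal p (ties broken by feature id), with attributes `m`
#'   and `threshold` (= `alpha / m`). Failed fits yield `NA` rows and still
#'   count in `m`.
#' @export
run_association_scan <- function(pheno, omics, outcome = c("bmi_at_sampling",
                                                           "bmi_slope",
                                                           "bmi_intercept"),
                                 alpha = 0.05, include_batch = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(omics, "omics_matrix"))
  ids <- intersect(pheno$id, rownames(omics$values))
  ph <- pheno[match(ids, pheno$id), , drop = FALSE]
  V <- omics$values[ids, , drop = FALSE]
  m <- ncol(V)
  extra <- NULL
  if (outcome == "bmi_slope") extra <- cbind(bmi_intercept = ph$bmi_intercept)
  if (include_batch && !is.null(omics$batch)) {
    b <- droplevels(omics$batch[match(ids, rownames(omics$values))])
    if (nlevels(b) > 1) {
      bm <- stats::model.matrix(~b)[, -1, drop = FALSE]
      extra <- cbind(extra, bm)
    }
  }
  rows <- lapply(seq_len(m), function(j) {
    res <- tryCatch({
      ok <- stats::complete.cases(V[, j], ph[[outcome]])
      y <- zscore(ph[[outcome]][ok], outcome)
      x <- zscore(V[ok, j], colnames(V)[j])
      X <- cbind(assoc_design(ph[ok, , drop = FALSE],
                              if (is.null(extra)) NULL else extra[ok, , drop = FALSE]),
                 feature = x)
      fit <- fit_lmm(y, X, ph$family_id[ok], ph$zygosity[ok])
      st <- satterthwaite_test(fit, "feature")
      data.frame(feature = colnames(V)[j], estimate = st$estimate, se = st$se,
                 t = st$t, df = st$df, p = st$p, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("feature ", colnames(V)[j], " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(feature = colnames(V)[j], estimate = NA_real_, se = NA_real_,
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- bonferroni_adjust(tab$p, m)
  tab$significant <- !is.na(tab$p_bonferroni) & tab$p_bonferroni < alpha
  tab <- tab[order(tab$p, tab$feature, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "m") <- m
  attr(tab, "threshold") <- alpha / m
  attr(tab, "outcome") <- outcome
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' @export
print.association_table <- function(x, n = 10, ...) {
  cat("Association scan (", attr(x, "outcome") %||% "outcome", "): ",
      attr(x, "m"), " features, Bonferroni threshold ",
      signif(attr(x, "threshold"), 3), "\n", sep = "")
  cat("  significant:", sum(x$significant, na.rm = TRUE), "\n")
  print.data.frame(utils::head(x, n), digits = 3)
  invisible(x)
}
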