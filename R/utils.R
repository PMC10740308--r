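# Internal numeric helpers shared across fitting code.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Central-difference gradient of scalar function f at x.
## Step is relative (h * max(|x|, 1)) so it behaves on variance and log scales.
num_grad <- function(f, x, h = 1e-6, ...) {
  p <- length(x)
  g <- numeric(p)
  for (j in seq_len(p)) {
    d <- h * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + d
    xm <- x; xm[j] <- x[j] - d
    g[j] <- (f(xp, ...) - f(xm, ...)) / (2 * d)
  }
  g
}

## Central-difference Hessian (symmetrized).
num_hess <- function(f, x, h = 1e-5, ...) {
  p <- length(x)
  H <- matrix(0, p, p)
  d <- h * pmax(abs(x), 1)
  f0 <- f(x, ...)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + d[i]
        xm <- x; xm[i] <- x[i] - d[i]
        H[i, i] <- (f(xp, ...) - 2 * f0 + f(xm, ...)) / d[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + d[i]; xpp[j] <- x[j] + d[j]
        xpm <- x; xpm[i] <- x[i] + d[i]; xpm[j] <- x[j] - d[j]
        xmp <- x; xmp[i] <- x[i] - d[i]; xmp[j] <- x[j] + d[j]
        xmm <- x; xmm[i] <- x[i] - d[i]; xmm[j] <- x[j] - d[j]
        H[i, j] <- H[j, i] <-
          (f(xpp, ...) - f(xpm, ...) - f(xmp, ...) + f(xmm, ...)) /
          (4 * d[i] * d[j])
      }
    }
  }
  H
}

## Draw n rows from N(0, R) for a correlation/covariance matrix R.
rmvn <- function(n, R) {
  L <- chol(R)
  matrix(stats::rnorm(n * nrow(R)), n) %*% L
}

## Sample-sd z-scoring of a numeric vector; errors on zero variance.
zscore <- function(x, label = "x") {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score '", label, "': zero or undefined variance", call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

## Validation helper: fail with the offending field's name.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop("invalid '", field, "': ", msg, call. = FALSE)
  invisible(TRUE)
}

## Stable hash of an R object: canonicalize (sort names recursively),
## serialize to a temp file, md5. Used by the run manifest.
stable_hash <- function(x) {
  canon <- function(o) {
    if (is.list(o)) {
      nm <- names(o)
      if (!is.null(nm) && all(nzchar(nm))) o <- o[order(nm)]
      lapply(o, canon)
    } else o
  }
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(canon(x)), f)
  unname(tools::md5sum(f))
}
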