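make_mat <- function(values, batch = NULL, scale = "raw") {
  omics_matrix(values, batch = batch, scale = scale)
}

test_that("log2 transform is exact and rejects nonpositive values", {
  m <- make_mat(matrix(c(8, 1, 4, NA), 2, 2))
  out <- log2_transform(m)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_true(is.na(out$values[2, 2]))
  expect_equal(out$scale, "log2")
  bad <- make_mat(matrix(c(2, -1), 1, 2))
  expect_error(log2_transform(bad), "nonpositive")
})

test_that("missingness filter uses a strict threshold", {
  v <- matrix(1, 100, 3)
  v[1:11, 1] <- NA     # 11% missing -> dropped
  v[1:10, 2] <- NA     # exactly 10% -> retained
  st <- filter_missingness(make_mat(v, scale = "log2"), 0.10)
  expect_equal(ncol(st$matrix$values), 2)
  expect_equal(st$report$dropped, "X0001")
  ## max_frac 1 is the identity
  st2 <- filter_missingness(make_mat(v, scale = "log2"), 1)
  expect_equal(ncol(st2$matrix$values), 3)
})

test_that("per-batch minimum imputation matches the brute-force oracle", {
  v <- matrix(c(5.1, 4.2, NA, 7.0, 6.5, 6.0), 3, 2)
  m <- make_mat(v, batch = c("a", "a", "a"), scale = "log2")
  st <- impute_min_per_batch(m)
  expect_equal(st$matrix$values[3, 1], 4.2)
  expect_equal(st$report$fraction_imputed, 1 / 6)
  ## batch with no observed value falls back to the global minimum
  v2 <- matrix(c(3, 4, NA, NA), 4, 1)
  m2 <- make_mat(v2, batch = c("a", "a", "b", "b"), scale = "log2")
  expect_equal(impute_min_per_batch(m2)$matrix$values[3, 1], 3)
  ## no missing values: identity with zero imputed fraction
  m3 <- make_mat(matrix(1:4, 2, 2), batch = c("a", "b"), scale = "log2")
  st3 <- impute_min_per_batch(m3)
  expect_equal(st3$matrix$values, m3$values)
  expect_equal(st3$report$fraction_imputed, 0)
  ## fully missing feature is an error
  v4 <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(impute_min_per_batch(make_mat(v4, batch = c("a", "b"),
                                             scale = "log2")),
               "zero observed")
})

test_that("generator defaults produce an imputed fraction near 0.86%", {
  co <- small_cohort(106, 164, 111, seed = 5)
  om <- simulate_omics(co, omics_spec(n_features = 439))
  frac <- mean(is.na(om$values))
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.013)
})

test_that("batch adjustment converges to per-batch centering on large balanced data", {
  set.seed(101)
  n <- 400; p <- 30
  base <- matrix(rnorm(n * p, 10), n, p)
  batch <- rep(c("b1", "b2"), each = n / 2)
  shifted <- base
  shifted[batch == "b2", ] <- shifted[batch == "b2", ] + 2
  m <- make_mat(shifted, batch = batch, scale = "log2")
  st <- combat_adjust(m)
  ## oracle: direct per-batch centering (plus global mean restoration)
  d1 <- colMeans(st$matrix$values[batch == "b1", ]) -
    colMeans(st$matrix$values[batch == "b2", ])
  expect_lt(mean(abs(d1)), 0.12)   # EB shrinkage leaves sampling noise only
  expect_lt(max(abs(d1)), 2 * 0.2) # versus the +2 generating offset
  ## global feature means preserved on the balanced design (the scale
  ## component of the adjustment perturbs them at the 1e-5 level)
  expect_lt(max(abs(colMeans(st$matrix$values) - colMeans(shifted))), 1e-4)
  ## identical batch distributions: adjustment is near-identity
  m0 <- make_mat(base, batch = batch, scale = "log2")
  st0 <- combat_adjust(m0)
  expect_lt(max(abs(st0$matrix$values - base)), 0.2)
  ## 4x variance ratio between batches is equalized
  scaled <- base
  scaled[batch == "b2", ] <- 10 + (scaled[batch == "b2", ] - 10) * 2
  stv <- combat_adjust(make_mat(scaled, batch = batch, scale = "log2"))
  vr <- apply(stv$matrix$values[batch == "b1", ], 2, var) /
    apply(stv$matrix$values[batch == "b2", ], 2, var)
  expect_lt(max(abs(log(vr))), 0.35)
  ## a batch of size 1 is rejected with advice
  expect_error(combat_adjust(make_mat(base[1:3, ], batch = c("a", "a", "b"),
                                      scale = "log2")),
               "size 1")
})

test_that("PCA outlier screen flags gross outliers and honours its threshold", {
  set.seed(102)
  v <- matrix(rnorm(50 * 10), 50, 10)
  m <- make_mat(v, scale = "log2")
  expect_length(detect_outliers_pca(m), 0)
  ## brute-force check on a small matrix with one shifted sample
  v2 <- matrix(rnorm(10 * 5), 10, 5)
  v2[7, ] <- v2[7, ] + 20
  m2 <- make_mat(v2, scale = "log2")
  flagged <- detect_outliers_pca(m2, n_pcs = 2, sd_limit = 2)
  pc <- prcomp(v2, center = TRUE, scale. = TRUE)
  oracle <- rownames(m2$values)[abs(pc$x[, 1]) > 2 * sd(pc$x[, 1]) |
                                  abs(pc$x[, 2]) > 2 * sd(pc$x[, 2])]
  expect_setequal(flagged, oracle)
  expect_true(rownames(m2$values)[7] %in% flagged)
  ## sd_limit 0 flags everyone
  expect_length(detect_outliers_pca(m, sd_limit = 0), 50)
  expect_error(detect_outliers_pca(make_mat(v[1:2, ], scale = "log2")), "3 samples")
})

test_that("z-scaling uses the sample sd, is idempotent, and names zero-variance features", {
  m <- make_mat(matrix(c(1, 2, 3), 3, 1), scale = "log2")
  out <- zscale_features(m)
  expect_equal(unname(out$values[, 1]), c(-1, 0, 1))   # sample sd of 1,2,3 is 1
  expect_equal(mean(out$values), 0, tolerance = 1e-12)
  expect_equal(sd(out$values), 1, tolerance = 1e-12)
  twice <- zscale_features(out)
  expect_equal(twice$values, out$values, tolerance = 1e-12)
  bad <- make_mat(cbind(A = c(1, 1, 1), B = c(1, 2, 3)), scale = "log2")
  colnames(bad$values) <- c("flatA", "okB")
  expect_error(zscale_features(bad), "flatA")
})

test_that("probe-to-gene collapsing averages log2 values and warns per unmapped probe", {
  v <- cbind(p1 = c(2, 4), p2 = c(4, 6), p3 = c(1, 1), p4 = c(9, 9))
  m <- make_mat(v, scale = "log2")
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("G1", "G1", "G2"))
  expect_warning(out <- collapse_probes_to_genes(m, map), "p4")
  expect_equal(unname(out$values[, "G1"]), c(3, 5))
  expect_equal(unname(out$values[, "G2"]), c(1, 1))   # one-probe gene is identity
  expect_error(collapse_probes_to_genes(m, map[0, ]), "empty")
  ## three unmapped probes give three warnings
  w <- capture_warnings(collapse_probes_to_genes(m, map[1, , drop = FALSE]))
  expect_length(w, 3)
})

test_that("the full preprocessing pipeline runs in fixed order and reports deltas", {
  co <- small_cohort(40, 60, 0, seed = 6)
  om <- simulate_omics(co, omics_spec(n_features = 50,
                                      target_trait = "bmi_at_sampling",
                                      rA = 0.2, rE = 0.1))
  res <- preprocess_omics(om)
  expect_named(res$reports, c("filter", "impute", "combat", "outliers"))
  expect_equal(res$matrix$scale, "log2")
  expect_equal(unname(colMeans(res$matrix$values)), rep(0, ncol(res$matrix$values)),
               tolerance = 1e-10)
  expect_equal(unname(apply(res$matrix$values, 2, sd)),
               rep(1, ncol(res$matrix$values)), tolerance = 1e-10)
  ## dropped + retained = input feature count
  expect_equal(length(res$reports$filter$dropped) + ncol(res$matrix$values), 50)
  ## the shipped kit-depletion exclusion list is usable
  kit <- readLines(system.file("extdata", "kit_depleted_proteins.txt",
                               package = "twinomics"))
  kit <- kit[!grepl("^#", kit) & nzchar(kit)]
  expect_length(kit, 16)
})

test_that("omics TSV round-trips through write and read", {
  co <- small_cohort(5, 5, 0, seed = 23)
  om <- simulate_omics(co, omics_spec(n_features = 4, missing_censor_quantile = 0))
  path <- tempfile(fileext = ".tsv")
  write_omics_tsv(om, path)
  back <- read_omics_tsv(path, scale = "raw")
  expect_equal(back$values, om$values, tolerance = 1e-8)
  expect_equal(as.character(back$batch), as.character(om$batch))
})
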