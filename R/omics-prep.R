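#' Construct an omics matrix container
#'
#' Light samples-by-features container used throughout the preprocessing
#' pipeline: a numeric matrix with sample ids as row names and feature ids as
#' column names, a batch label per sample, per-feature metadata, and a scale
#' flag. Missing entries are `NA` in the matrix, never silent zeros.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param batch factor or vector of batch labels, one per sample (optional).
#' @param feature_info data frame with at least `feature_id` and `class`
#'   (`"protein"`, `"metabolite"`, `"gene_expression"` or `"probe"`).
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, batch = NULL, feature_info = NULL,
                         scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("X%04d", seq_len(ncol(values)))
  if (!is.null(batch)) {
    check_that(length(batch) == nrow(values), "batch", "one label per sample required")
    batch <- factor(batch)
  }
  if (is.null(feature_info)) {
    feature_info <- data.frame(feature_id = colnames(values), class = "protein",
                               stringsAsFactors = FALSE)
  }
  check_that(nrow(feature_info) == ncol(values), "feature_info",
             "one row per feature required")
  structure(list(values = values, batch = batch, feature_info = feature_info,
                 scale = scale),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("Omics matrix:", nrow(x$values), "samples x", ncol(x$values), "features",
      sprintf("(%s scale)\n", x$scale))
  if (!is.null(x$batch)) cat("  batches:", paste(levels(x$batch), collapse = ", "), "\n")
  miss <- mean(is.na(x$values))
  cat("  missing:", sprintf("%.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

prep_report <- function(stage, dropped = character(0), fraction_imputed = 0,
                        outliers = character(0), details = list()) {
  structure(list(stage = stage, dropped = dropped,
                 fraction_imputed = fraction_imputed, outliers = outliers,
                 details = details),
            class = "prep_report")
}

#' Log2-transform an omics matrix
#'
#' @param matrix an [omics_matrix()] on the raw scale; all observed values
#'   must be strictly positive.
#' @return The matrix on the log2 scale; the missingness mask is untouched.
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (matrix$scale == "log2") stop("matrix is already log2-scaled", call. = FALSE)
  bad <- which(!is.na(matrix$values) & matrix$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 10), 1, function(r) {
      paste0(rownames(matrix$values)[r[1]], "/", colnames(matrix$values)[r[2]])
    })
    stop("nonpositive observed values at: ", paste(cells, collapse = ", "),
         if (nrow(bad) > 10) " ..." else "", call. = FALSE)
  }
  matrix$values <- log2(matrix$values)
  matrix$scale <- "log2"
  matrix
}

#' Remove features by an exclusion list
#'
#' Applies an a-priori feature exclusion (for example, the abundant plasma
#' proteins depleted by the sample-preparation kit; see
#' `system.file("extdata", "kit_depleted_proteins.txt", package = "twinomics")`)
#' before missingness filtering.
#'
#' @param matrix an [omics_matrix()].
#' @param ids feature ids to drop; ids absent from the matrix are ignored.
#' @return `list(matrix =, report =)`.
#' @export
exclude_features <- function(matrix, ids) {
  stopifnot(inherits(matrix, "omics_matrix"))
  drop <- intersect(colnames(matrix$values), ids)
  keep <- setdiff(colnames(matrix$values), drop)
  matrix$values <- matrix$values[, keep, drop = FALSE]
  matrix$feature_info <- matrix$feature_info[matrix$feature_info$feature_id %in% keep, ,
                                             drop = FALSE]
  list(matrix = matrix, report = prep_report("exclude", dropped = drop))
}

#' Filter features by missingness
#'
#' Drops features whose missing fraction strictly exceeds `max_frac`; a
#' feature at exactly the threshold is retained.
#'
#' @param matrix an [omics_matrix()].
#' @param max_frac maximum tolerated missing fraction (default 0.10).
#' @return `list(matrix =, report =)`; the report lists dropped feature ids.
#' @export
filter_missingness <- function(matrix, max_frac = 0.10) {
  stopifnot(inherits(matrix, "omics_matrix"))
  check_that(max_frac >= 0 && max_frac <= 1, "max_frac", "must lie in [0, 1]")
  frac <- colMeans(is.na(matrix$values))
  drop <- colnames(matrix$values)[frac > max_frac]
  keep <- setdiff(colnames(matrix$values), drop)
  matrix$values <- matrix$values[, keep, drop = FALSE]
  matrix$feature_info <- matrix$feature_info[matrix$feature_info$feature_id %in% keep, ,
                                             drop = FALSE]
  list(matrix = matrix,
       report = prep_report("filter_missingness", dropped = drop,
                            details = list(missing_fraction = frac)))
}

#' Impute missing values by the lowest observed value per batch
#'
#' Each missing cell is replaced by the minimum observed value of that
#' feature within the sample's batch, emulating detection-limit missingness.
#' When a batch has no observed value for a feature, the feature's global
#' minimum is used.
#'
#' @param matrix an [omics_matrix()] with batch labels.
#' @return `list(matrix =, report =)`; the report records the imputed
#'   fraction.
#' @export
impute_min_per_batch <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (is.null(matrix$batch)) stop("batch labels required for per-batch imputation",
                                  call. = FALSE)
  v <- matrix$values
  all_missing <- colSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("features with zero observed values anywhere: ",
         paste(colnames(v)[all_missing], collapse = ", "), call. = FALSE)
  }
  frac <- mean(is.na(v))
  gmin <- apply(v, 2, min, na.rm = TRUE)
  for (b in levels(matrix$batch)) {
    idx <- which(matrix$batch == b)
    sub <- v[idx, , drop = FALSE]
    bmin <- suppressWarnings(apply(sub, 2, min, na.rm = TRUE))
    bmin[!is.finite(bmin)] <- gmin[!is.finite(bmin)]
    na_ind <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_ind) > 0) sub[na_ind] <- bmin[na_ind[, 2]]
    v[idx, ] <- sub
  }
  matrix$values <- v
  list(matrix = matrix,
       report = prep_report("impute_min_per_batch", fraction_imputed = frac))
}

#' Adjust batch effects by parametric empirical Bayes
#'
#' Location/scale batch adjustment in the ComBat family (delegated to
#' \code{sva::ComBat}): features are standardized, per-batch additive and
#' multiplicative effects are estimated and shrunk toward across-batch priors,
#' then removed. Requires a complete matrix (run after imputation) and at
#' least two batches with two or more samples each.
#'
#' @param matrix a complete [omics_matrix()] with batch labels.
#' @return `list(matrix =, report =)`; the report records per-batch mean
#'   shifts before and after adjustment.
#' @export
combat_adjust <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (is.null(matrix$batch)) stop("batch labels required", call. = FALSE)
  if (nlevels(droplevels(matrix$batch)) < 2) {
    stop("at least 2 batches required for batch adjustment", call. = FALSE)
  }
  sizes <- table(droplevels(matrix$batch))
  if (any(sizes < 2)) {
    stop("batch of size 1 found (", paste(names(sizes)[sizes < 2], collapse = ", "),
         "); merge it with another batch or skip adjustment", call. = FALSE)
  }
  if (anyNA(matrix$values)) stop("matrix has missing values; impute first", call. = FALSE)
  pre <- tapply(rowMeans(matrix$values), matrix$batch, mean)
  invisible(utils::capture.output(suppressMessages(
    adj <- t(sva::ComBat(dat = t(matrix$values), batch = droplevels(matrix$batch),
                         par.prior = TRUE, prior.plots = FALSE)))))
  post <- tapply(rowMeans(adj), matrix$batch, mean)
  matrix$values <- adj
  list(matrix = matrix,
       report = prep_report("combat_adjust",
                            details = list(batch_means_pre = pre,
                                           batch_means_post = post)))
}

#' Flag outlying samples on leading principal components
#'
#' PCA of the standardized feature matrix; a sample is flagged when the
#' absolute score on any of the first `n_pcs` components exceeds `sd_limit`
#' standard deviations of that component.
#'
#' @param matrix a complete [omics_matrix()].
#' @param n_pcs number of leading components screened (default 2).
#' @param sd_limit threshold in component standard deviations (default 5).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outliers_pca <- function(matrix, n_pcs = 2, sd_limit = 5) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (nrow(matrix$values) < 3) stop("need at least 3 samples for PCA screening",
                                    call. = FALSE)
  if (anyNA(matrix$values)) stop("matrix has missing values; impute first", call. = FALSE)
  keep <- apply(matrix$values, 2, stats::sd) > 0
  pc <- stats::prcomp(matrix$values[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sds <- apply(scores, 2, stats::sd)
  flagged <- rowSums(abs(scores) > matrix(sds * sd_limit, nrow(scores), k,
                                          byrow = TRUE)) > 0
  rownames(matrix$values)[flagged]
}

#' Z-scale features to zero mean and unit (sample) standard deviation
#'
#' Uses the sample (n-1) standard deviation, so one unit corresponds to one
#' sd of the observed distribution. Idempotent up to floating-point error.
#'
#' @param matrix an [omics_matrix()].
#' @return The scaled matrix.
#' @export
zscale_features <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  sds <- apply(matrix$values, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("zero-variance features: ",
         paste(colnames(matrix$values)[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  }
  matrix$values <- scale(matrix$values)
  attr(matrix$values, "scaled:center") <- NULL
  attr(matrix$values, "scaled:scale") <- NULL
  matrix
}

#' Collapse probe-level expression to gene level
#'
#' Per gene, the value is the arithmetic mean of its probes' log2 values.
#' Probes absent from the map are dropped, one warning each.
#'
#' @param matrix an [omics_matrix()] whose features are probes.
#' @param probe_to_gene data frame with columns `probe` and `gene`.
#' @return An [omics_matrix()] of gene-level values.
#' @export
collapse_probes_to_genes <- function(matrix, probe_to_gene) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (is.null(probe_to_gene) || nrow(probe_to_gene) == 0) {
    stop("empty probe-to-gene map", call. = FALSE)
  }
  check_that(all(c("probe", "gene") %in% names(probe_to_gene)),
             "probe_to_gene", "needs columns 'probe' and 'gene'")
  probes <- colnames(matrix$values)
  unmapped <- setdiff(probes, probe_to_gene$probe)
  for (p in unmapped) warning("probe not in map, dropped: ", p, call. = FALSE)
  mapped <- probe_to_gene[probe_to_gene$probe %in% probes, , drop = FALSE]
  genes <- unique(mapped$gene)
  out <- vapply(genes, function(g) {
    cols <- mapped$probe[mapped$gene == g]
    rowMeans(matrix$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(matrix$values)))
  out <- as.matrix(out)
  colnames(out) <- genes
  rownames(out) <- rownames(matrix$values)
  omics_matrix(out, batch = matrix$batch,
               feature_info = data.frame(feature_id = genes,
                                         class = "gene_expression",
                                         stringsAsFactors = FALSE),
               scale = matrix$scale)
}

#' Run the full omics preprocessing pipeline
#'
#' Fixed stage order: log2 transform, a-priori exclusion list, missingness
#' filter, per-batch minimum imputation, empirical-Bayes batch adjustment,
#' PCA outlier screen, z-scaling. Batch adjustment runs on unscaled log2
#' values; scaling comes last.
#'
#' @param matrix a raw-scale [omics_matrix()] with batch labels.
#' @param exclude feature ids removed before filtering (default: none).
#' @param max_missing_frac missingness filter threshold (default 0.10).
#' @param n_pcs,sd_limit outlier-screen settings.
#' @param drop_outliers whether flagged samples are removed (default TRUE).
#' @return `list(matrix =, reports =, outliers =)` with one report per stage.
#' @export
preprocess_omics <- function(matrix, exclude = character(0),
                             max_missing_frac = 0.10, n_pcs = 2, sd_limit = 5,
                             drop_outliers = TRUE) {
  reports <- list()
  m <- log2_transform(matrix)
  if (length(exclude) > 0) {
    st <- exclude_features(m, exclude); m <- st$matrix
    reports$exclude <- st$report
  }
  st <- filter_missingness(m, max_missing_frac); m <- st$matrix
  reports$filter <- st$report
  st <- impute_min_per_batch(m); m <- st$matrix
  reports$impute <- st$report
  st <- combat_adjust(m); m <- st$matrix
  reports$combat <- st$report
  outliers <- detect_outliers_pca(m, n_pcs = n_pcs, sd_limit = sd_limit)
  if (drop_outliers && length(outliers) > 0) {
    keep <- !(rownames(m$values) %in% outliers)
    m$values <- m$values[keep, , drop = FALSE]
    m$batch <- droplevels(m$batch[keep])
  }
  reports$outliers <- prep_report("detect_outliers_pca", outliers = outliers)
  m <- zscale_features(m)
  list(matrix = m, reports = reports, outliers = outliers)
}

#' Read / write an omics matrix as TSV
#'
#' The TSV layout is samples in rows with an `id` column, a `batch` column,
#' and one column per feature.
#'
#' @param matrix an [omics_matrix()] (for writing).
#' @param path file path.
#' @param scale scale flag to record when reading.
#' @return `read_omics_tsv` returns an [omics_matrix()];
#'   `write_omics_tsv` returns `path` invisibly.
#' @export
write_omics_tsv <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix$values),
                   batch = if (is.null(matrix$batch)) NA else as.character(matrix$batch),
                   matrix$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @export
read_omics_tsv <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_that(all(c("id", "batch") %in% names(df)), "omics tsv",
             "needs 'id' and 'batch' columns")
  v <- as.matrix(df[, setdiff(names(df), c("id", "batch")), drop = FALSE])
  rownames(v) <- df$id
  omics_matrix(v, batch = df$batch, scale = scale)
}
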