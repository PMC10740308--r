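#' Residualize polygenic scores on genetic principal components
#'
#' OLS residual of each score on the genetic PCs (plus platform indicators
#' when present), then z-scaled to mean zero and unit variance. The
#' residualized score is exactly orthogonal to the PCs.
#'
#' @param prs data frame with a `prs` column (or columns named in `scores`),
#'   PC columns `pc1`, `pc2`, ... and optionally a `platform` column.
#' @param scores names of the score columns to residualize (default `"prs"`).
#' @return `prs` with the score columns replaced by residualized, scaled
#'   values.
#' @export
residualize_prs <- function(prs, scores = "prs") {
  pc_cols <- grep("^pc[0-9]+$", names(prs), value = TRUE)
  check_that(length(pc_cols) > 0, "prs", "no genetic PC columns (pc1, pc2, ...)")
  X <- as.matrix(prs[pc_cols])
  if ("platform" %in% names(prs) && length(unique(prs$platform)) > 1) {
    X <- cbind(X, stats::model.matrix(~factor(prs$platform))[, -1, drop = FALSE])
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    stop("collinear PC/platform design: rank ", qrX$rank, " < ", ncol(X) + 1,
         call. = FALSE)
  }
  for (sc in scores) {
    r <- qr.resid(qrX, prs[[sc]])
    if (stats::sd(r) < 1e-12) {
      stop("score '", sc, "' is fully explained by the PCs: zero-variance residual",
           call. = FALSE)
    }
    prs[[sc]] <- as.numeric(scale(r))
  }
  prs
}

#' Mixed-model association scan with a polygenic score as predictor
#'
#' Runs, per omics feature, the same twin-clustered mixed model as
#' [run_association_scan()] but with the z-scored feature as outcome and the
#' residualized polygenic score as the fixed predictor of interest.
#' Bonferroni control is over the number of features.
#'
#' @param pheno a [make_assoc_pheno()] table.
#' @param prs a [residualize_prs()] table with an `id` column.
#' @param omics an [omics_matrix()].
#' @param score score column name in `prs`.
#' @param alpha family-wise level.
#' @return An `association_table` (see [run_association_scan()]).
#' @export
prs_association_scan <- function(pheno, prs, omics, score = "prs", alpha = 0.05) {
  stopifnot(inherits(omics, "omics_matrix"))
  ids <- Reduce(intersect, list(pheno$id, prs$id, rownames(omics$values)))
  ph <- pheno[match(ids, pheno$id), , drop = FALSE]
  sc <- prs[[score]][match(ids, prs$id)]
  V <- omics$values[ids, , drop = FALSE]
  m <- ncol(V)
  rows <- lapply(seq_len(m), function(j) {
    tryCatch({
      ok <- stats::complete.cases(V[, j], sc)
      y <- zscore(V[ok, j], colnames(V)[j])
      X <- cbind(assoc_design(ph[ok, , drop = FALSE]),
                 prs = zscore(sc[ok], score))
      fit <- fit_lmm(y, X, ph$family_id[ok], ph$zygosity[ok])
      st <- satterthwaite_test(fit, "prs")
      data.frame(feature = colnames(V)[j], estimate = st$estimate, se = st$se,
                 t = st$t, df = st$df, p = st$p, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(feature = colnames(V)[j], estimate = NA_real_, se = NA_real_,
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- bonferroni_adjust(tab$p, m)
  tab$significant <- !is.na(tab$p_bonferroni) & tab$p_bonferroni < alpha
  tab <- tab[order(tab$p, tab$feature, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "m") <- m
  attr(tab, "threshold") <- alpha / m
  attr(tab, "outcome") <- paste0("features ~ ", score)
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Reduce a correlated lipoprotein block to principal components
#'
#' PCA of the (complete, scaled) lipoprotein features; the top `k` scores are
#' named `LIPO.PC1` ... `LIPO.PCk`. Each component is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param matrix an [omics_matrix()].
#' @param block_ids feature ids forming the block.
#' @param k number of components (default 3).
#' @return `list(scores = matrix, variance_fraction = numeric)`.
#' @export
reduce_lipoproteins_pca <- function(matrix, block_ids, k = 3) {
  stopifnot(inherits(matrix, "omics_matrix"))
  check_that(all(block_ids %in% colnames(matrix$values)), "block_ids",
             "not all ids present in the matrix")
  check_that(k <= length(block_ids), "k", "more components than block features")
  V <- matrix$values[, block_ids, drop = FALSE]
  if (anyNA(V)) stop("lipoprotein block has missing values; impute first", call. = FALSE)
  pc <- stats::prcomp(V, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("LIPO.PC", seq_len(k))
  list(scores = scores, variance_fraction = vf[seq_len(k)],
       variance_fraction_all = vf)
}

## The 8 residualization covariates of the network nodes.
network_covariates <- function(pheno) {
  age_c <- pheno$age_at_sampling - mean(pheno$age_at_sampling)
  sexM <- as.numeric(pheno$sex == "M")
  cbind(bmi_slope = pheno$bmi_slope, bmi_intercept = pheno$bmi_intercept,
        bmi_at_sampling = pheno$bmi_at_sampling,
        age = age_c, age2 = age_c^2, sexM = sexM,
        `sexM:age` = sexM * age_c, `sexM:age2` = sexM * age_c^2)
}

#' Residualize network nodes on the trajectory and demographic covariates
#'
#' Each node is linearly regressed on the 8 covariates (BMI slope, BMI
#' intercept, BMI at blood sampling, age, age squared, sex, sex-by-age and
#' sex-by-age-squared); the residuals are exactly orthogonal to all of them.
#'
#' @param nodes numeric matrix of node values (samples x nodes) with sample
#'   ids as row names.
#' @param pheno a [make_assoc_pheno()] table covering the samples.
#' @return Matrix of residualized nodes.
#' @export
residualize_nodes <- function(nodes, pheno) {
  nodes <- as.matrix(nodes)
  ids <- intersect(rownames(nodes), pheno$id)
  nodes <- nodes[ids, , drop = FALSE]
  ph <- pheno[match(ids, pheno$id), , drop = FALSE]
  X <- cbind(1, network_covariates(ph))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient covariate matrix (rank ", qrX$rank, " of ", ncol(X), ")",
         call. = FALSE)
  }
  res <- qr.resid(qrX, nodes)
  degen <- apply(res, 2, stats::sd) < 1e-10
  if (any(degen)) {
    stop("degenerate nodes (zero residual variance): ",
         paste(colnames(nodes)[degen], collapse = ", "), call. = FALSE)
  }
  res
}

#' Build a significance-classed correlation network
#'
#' All pairwise Pearson correlations between residualized nodes
#' (pairwise-complete samples), with t-transform p-values at n - 2 df and
#' Bonferroni control over the number of node pairs. Edges are classed
#' `bonferroni_pos`, `bonferroni_neg`, `nominal_pos`, `nominal_neg` or
#' `null`.
#'
#' @param nodes residualized node matrix (samples x nodes).
#' @param node_class optional character vector of node classes (protein,
#'   prs, lipoprotein_pc, lmwm) used as vertex attributes.
#' @param alpha significance level (default 0.05).
#' @return An object of class `omics_network`: `edges` data frame (`node1`,
#'   `node2`, `r`, `n`, `p`, `p_bonferroni`, `class`), `n_nodes`, `m_pairs`,
#'   and `graph` (an igraph object).
#' @export
build_network <- function(nodes, node_class = NULL, alpha = 0.05) {
  nodes <- as.matrix(nodes)
  p <- ncol(nodes)
  check_that(p >= 3, "nodes", "need at least 3 nodes")
  const <- apply(nodes, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    stop("constant nodes: ", paste(colnames(nodes)[const], collapse = ", "),
         call. = FALSE)
  }
  m_pairs <- p * (p - 1) / 2
  comb <- utils::combn(p, 2)
  edges <- data.frame(node1 = colnames(nodes)[comb[1, ]],
                      node2 = colnames(nodes)[comb[2, ]],
                      r = NA_real_, n = NA_integer_, p = NA_real_,
                      stringsAsFactors = FALSE)
  for (e in seq_len(ncol(comb))) {
    x <- nodes[, comb[1, e]]; y <- nodes[, comb[2, e]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    r <- stats::cor(x[ok], y[ok])
    tval <- r * sqrt((n - 2) / (1 - r^2))
    edges$r[e] <- r
    edges$n[e] <- n
    edges$p[e] <- 2 * stats::pt(-abs(tval), n - 2)
  }
  edges$p_bonferroni <- bonferroni_adjust(edges$p, m_pairs)
  edges$class <- ifelse(edges$p_bonferroni < alpha,
                        ifelse(edges$r > 0, "bonferroni_pos", "bonferroni_neg"),
                        ifelse(edges$p < alpha,
                               ifelse(edges$r > 0, "nominal_pos", "nominal_neg"),
                               "null"))
  g <- igraph::graph_from_data_frame(
    edges[edges$class != "null", c("node1", "node2", "r", "p", "class")],
    directed = FALSE,
    vertices = data.frame(name = colnames(nodes),
                          class = node_class %||% rep("node", p)))
  structure(list(edges = edges, n_nodes = p, m_pairs = m_pairs,
                 alpha = alpha, graph = g),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat("Multi-omics correlation network:", x$n_nodes, "nodes,",
      x$m_pairs, "candidate edges\n")
  print(table(x$edges$class))
  invisible(x)
}

#' Write a network to GraphML
#'
#' @param network an [build_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "omics_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
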