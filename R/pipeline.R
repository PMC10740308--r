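#' Validate pipeline input tables
#'
#' Schema and cross-reference checks on the phenotype, omics and PRS tables:
#' required columns, zygosity codes, duplicated ids, twin-pairs-plus-
#' singletons family structure, and id coverage between tables. Violations
#' are split into hard errors and warnings.
#'
#' @param pheno individual-level phenotype data frame (`id`, `family_id`,
#'   `zygosity`, `sex` at minimum).
#' @param omics optional [omics_matrix()]; sample ids must appear in `pheno`.
#' @param prs optional PRS data frame with an `id` column.
#' @return `list(ok = logical, errors = character, warnings = character)`.
#' @export
validate_inputs <- function(pheno, omics = NULL, prs = NULL) {
  errors <- character(0); warns <- character(0)
  req <- c("id", "family_id", "zygosity", "sex")
  miss <- setdiff(req, names(pheno))
  if (length(miss) > 0) {
    errors <- c(errors, paste("phenotype table missing columns:",
                              paste(miss, collapse = ", ")))
  } else {
    dup <- pheno$id[duplicated(pheno$id)]
    if (length(dup) > 0) {
      errors <- c(errors, paste("duplicated individual ids:",
                                paste(unique(dup), collapse = ", ")))
    }
    badz <- !(pheno$zygosity %in% c("MZ", "DZ") | is.na(pheno$zygosity))
    if (any(badz)) {
      errors <- c(errors, paste0("invalid zygosity at rows: ",
                                 paste(which(badz), collapse = ", ")))
    }
    sizes <- table(pheno$family_id)
    if (any(sizes > 2)) {
      errors <- c(errors, paste("families with more than 2 members:",
                                paste(names(sizes)[sizes > 2], collapse = ", ")))
    }
    extra <- setdiff(names(pheno),
                     c(req, grep("^(age|height|weight|bmi|tmi)", names(pheno),
                                 value = TRUE)))
    if (length(extra) > 0) {
      warns <- c(warns, paste("unused phenotype columns:",
                              paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(omics)) {
    unknown <- setdiff(rownames(omics$values), pheno$id)
    if (length(unknown) > 0) {
      errors <- c(errors, paste("omics samples absent from phenotype table:",
                                paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(prs)) {
    if (!("id" %in% names(prs))) {
      errors <- c(errors, "PRS table missing 'id' column")
    } else {
      unknown <- setdiff(prs$id, pheno$id)
      if (length(unknown) > 0) {
        errors <- c(errors, paste("PRS ids absent from phenotype table:",
                                  paste(unknown, collapse = ", ")))
      }
    }
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warns)
}

#' Run the full simulation-to-network pipeline
#'
#' Orchestrates the stages in fixed order — simulate, preprocess, growth
#' modelling, association scans, twin modelling, network — writing each
#' stage's artifacts (plain TSV/JSON) before the next starts, and returning
#' a run manifest. Reruns with an identical config and seed reproduce the
#' same outputs.
#'
#' @param config nested list: `seed` (required), `out_dir`, `stages`
#'   (character subset of simulate/preprocess/growth/assoc/twin/network,
#'   default all), and optional `cohort`, `growth`, `omics`, `prs` argument
#'   lists passed to [cohort_spec()], [growth_spec()], [omics_spec()],
#'   [prs_spec()], plus `lgcm` options and `n_twin_traits` (number of
#'   top-scan features carried into twin modelling, default 5).
#' @return A `run_manifest` list (config hash, per-stage counts, timings,
#'   warnings) invisibly; artifacts on disk under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  check_that(!is.null(config$seed), "seed", "mandatory when simulating")
  out_dir <- config$out_dir %||% tempfile("twinomics_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "preprocess", "growth", "assoc",
                                 "twin", "network")
  manifest <- list(config_hash = stable_hash(config),
                   version = as.character(utils::packageVersion("twinomics")),
                   seed = config$seed, stages = list())
  t_all <- proc.time()[3]
  stage_log <- function(name, counts, t0) {
    manifest$stages[[name]] <<- c(list(elapsed_s = round(proc.time()[3] - t0, 2)),
                                  counts)
    message(sprintf("[%s] done (%.1fs): %s", name, proc.time()[3] - t0,
                    paste(names(counts), unlist(counts), sep = "=", collapse = ", ")))
  }

  set.seed(config$seed)
  cohort <- omics <- prs <- growth <- pheno <- NULL

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    cspec <- do.call(cohort_spec, config$cohort %||% list())
    cohort <- generate_cohort(cspec)
    cohort <- simulate_bmi_trajectories(cohort, do.call(growth_spec,
                                                        config$growth %||% list()))
    ospec <- do.call(omics_spec, config$omics %||% list(target_trait = "bmi_at_sampling",
                                                        rA = 0.2, rE = 0.1))
    omics <- simulate_omics(cohort, ospec)
    prs <- simulate_prs(cohort, do.call(prs_spec, config$prs %||% list()))
    utils::write.table(cohort_long(cohort), file.path(out_dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_omics_tsv(omics, file.path(out_dir, "omics.tsv"))
    utils::write.table(prs, file.path(out_dir, "prs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(cohort = unclass(cspec), omics = unclass(ospec)[
      !vapply(unclass(ospec), is.function, TRUE)]),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, null = "null",
      digits = NA)
    stage_log("simulate", list(individuals = nrow(cohort),
                               features = ncol(omics$values)), t0)
  }
  if (is.null(cohort)) {
    manifest$elapsed_s <- round(proc.time()[3] - t_all, 2)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(structure(manifest, class = "run_manifest")))
  }
  if ("preprocess" %in% stages && !is.null(omics)) {
    t0 <- proc.time()[3]
    prep <- preprocess_omics(omics)
    omics <- prep$matrix
    write_omics_tsv(omics, file.path(out_dir, "omics_preprocessed.tsv"))
    jsonlite::write_json(list(dropped = prep$reports$filter$dropped,
                              fraction_imputed = prep$reports$impute$fraction_imputed,
                              outliers = prep$outliers),
                         file.path(out_dir, "prep_report.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("preprocess", list(features = ncol(omics$values),
                                 outliers = length(prep$outliers)), t0)
  }
  if ("growth" %in% stages) {
    t0 <- proc.time()[3]
    sp <- config$lgcm %||% list()
    fit_log <- fit_lgcm(cohort, do.call(lgcm_spec, utils::modifyList(
      list(scheme = "logarithmic"), sp)))
    fit_lin <- fit_lgcm(cohort, do.call(lgcm_spec, utils::modifyList(
      list(scheme = "linear"), sp)))
    sel <- select_scheme(fit_indices(fit_lin), fit_indices(fit_log))
    fit <- if (sel$scheme == "linear") fit_lin else fit_log
    growth <- extract_growth_factors(fit)
    pheno <- make_assoc_pheno(cohort, growth)
    utils::write.table(growth, file.path(out_dir, "growth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ix <- fit_indices(fit)
    jsonlite::write_json(list(scheme = sel$scheme, good_fit = sel$good_fit,
                              cfi = ix$cfi, tli = ix$tli, rmsea = ix$rmsea,
                              alpha = as.list(fit$alpha)),
                         file.path(out_dir, "growth_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("growth", list(scheme = sel$scheme, n = fit$n_used), t0)
  }
  assoc <- NULL
  if ("assoc" %in% stages && !is.null(pheno)) {
    t0 <- proc.time()[3]
    assoc <- run_association_scan(pheno, omics, "bmi_at_sampling")
    utils::write.table(assoc, file.path(out_dir, "assoc_bmi.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_log("assoc", list(features = attr(assoc, "m"),
                            significant = sum(assoc$significant, na.rm = TRUE)), t0)
  }
  if ("twin" %in% stages && !is.null(pheno)) {
    t0 <- proc.time()[3]
    traits <- utils::head(assoc$feature[!is.na(assoc$p)],
                          config$n_twin_traits %||% 5)
    dat <- data.frame(pheno, stringsAsFactors = FALSE)
    rows <- lapply(c("bmi_at_sampling", traits), function(tr) {
      d <- dat
      d[[tr]] <- if (tr %in% names(d)) d[[tr]] else
        omics$values[match(d$id, rownames(omics$values)), tr]
      tp <- make_twin_pairs(d[!is.na(d$zygosity), ], tr,
                            covariates = c("age_at_sampling"))
      sat <- twin_correlations(tp)
      fam <- choose_model_family(sat)
      fits <- lapply(intersect(fam$candidates, c("ACE", "AE", "CE", "E")),
                     function(m) fit_univariate(tp, m))
      best <- select_by_aic(fits)
      data.frame(trait = tr, model = best$model, h2 = best$h2, c2 = best$c2,
                 e2 = best$e2, rMZ = sat$rMZ, rDZ = sat$rDZ,
                 aic = best$aic, stringsAsFactors = FALSE)
    })
    twin_tab <- do.call(rbind, rows)
    utils::write.table(twin_tab, file.path(out_dir, "twin.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_log("twin", list(traits = nrow(twin_tab)), t0)
  }
  if ("network" %in% stages && !is.null(pheno)) {
    t0 <- proc.time()[3]
    prs_r <- residualize_prs(prs)
    k <- min(10, ncol(omics$values))
    ids <- intersect(pheno$id, rownames(omics$values))
    nodes <- cbind(omics$values[ids, seq_len(k), drop = FALSE],
                   prs = prs_r$prs[match(ids, prs_r$id)])
    rownames(nodes) <- ids
    net <- build_network(residualize_nodes(nodes, pheno))
    utils::write.table(net$edges, file.path(out_dir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network_graphml(net, file.path(out_dir, "network.graphml"))
    stage_log("network", list(nodes = net$n_nodes, pairs = net$m_pairs), t0)
  }
  manifest$elapsed_s <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(manifest, class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run", x$config_hash, "- seed", x$seed, "\n")
  for (nm in names(x$stages)) {
    cat("  ", nm, ": ",
        paste(names(x$stages[[nm]]), unlist(x$stages[[nm]]), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
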