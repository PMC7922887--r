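#' Pipeline configuration
#'
#' Defaults follow the two-step design: univariate FDR level 0.10,
#' pathway-analysis q cutoffs 0.15 (untargeted) and 0.10 (targeted),
#' mean-centering for untargeted tables and autoscaling for targeted
#' panels, five-fold cross-validation for model optimization, 500
#' bootstrap subsets at significance level 0.05 for stability selection,
#' 1000 permutations for the MCC p-values, and a 10 ppm annotation
#' tolerance.
#'
#' @param delta_univariate FDR level for univariate relevance.
#' @param delta_ora_untargeted,delta_ora_targeted ORA q cutoffs.
#' @param a_max maximum latent variables tried in model optimization.
#' @param k_fold cross-validation folds.
#' @param n_perm permutations for the MCC p-values.
#' @param r2_threshold QC calibration retention threshold.
#' @param max_missing_fraction missingness filter level.
#' @param stability a [stability_config()]; built from `seed` when `NULL`.
#' @param tolerance_ppm annotation mass tolerance.
#' @param seed RNG seed (mandatory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(delta_univariate = 0.10,
                            delta_ora_untargeted = 0.15,
                            delta_ora_targeted = 0.10,
                            a_max = 3, k_fold = 5, n_perm = 1000,
                            r2_threshold = 0.7, max_missing_fraction = 0.5,
                            stability = NULL, tolerance_ppm = 10,
                            seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  for (d in c(delta_univariate, delta_ora_untargeted, delta_ora_targeted))
    if (d < 0 || d >= 1) stop("delta levels must lie in [0, 1)")
  if (is.null(stability)) stability <- stability_config(seed = seed + 1L)
  structure(list(delta_univariate = delta_univariate,
                 delta_ora_untargeted = delta_ora_untargeted,
                 delta_ora_targeted = delta_ora_targeted,
                 a_max = a_max, k_fold = k_fold, n_perm = n_perm,
                 r2_threshold = r2_threshold,
                 max_missing_fraction = max_missing_fraction,
                 stability = stability, tolerance_ppm = tolerance_ppm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the untargeted discovery arm of the pipeline
#'
#' Preprocessing (QC calibration where QC rows are present, probabilistic
#' quotient normalization, missingness filtering and half-minimum
#' imputation, log transform), PCA outlier report, univariate relevance at
#' the configured FDR level, PLS-DA with the number of latent variables
#' optimized by cross-validated MCC, permutation p-values for the in-fit
#' and cross-validated MCC, bootstrap stability selection, set-union merge
#' of the univariate and multivariate relevant features (with a provenance
#' column), adduct-based annotation, and pathway over-representation
#' analysis of the annotated metabolites.
#'
#' @param table a [feature_table()] with two study groups.
#' @param config a [pipeline_config()].
#' @param db metabolite database (bundled one when `NULL`).
#' @param log_transform analyze log-intensities (default TRUE; the
#'   multiplicative intensity model makes log scale the natural choice).
#' @param verbose print stage-by-stage counts.
#' @return A list of class `untargeted_result` with every stage artifact.
#' @export
run_untargeted <- function(table, config, db = NULL, log_transform = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "pipeline_config"))
  if (is.null(db)) db <- load_metabolite_db()
  say <- function(...) if (verbose) message(sprintf(...))
  grp <- table$sample_meta$group[is_study_sample(table)]
  if (length(unique(grp)) != 2)
    stop("validation: study samples must carry exactly two group labels")

  calibration <- NULL
  if (any(table$sample_meta$sample_type == "QC")) {
    calibration <- fit_qc_calibration(table, config$r2_threshold)
    table <- apply_calibration_filter(table, calibration)
    say("QC calibration: %d features retained", ncol(table$intensities))
  }
  pqn <- pqn_normalize(table)
  table <- impute_and_filter(pqn$table, config$max_missing_fraction)
  say("after missingness filter: %d features", ncol(table$intensities))

  study <- is_study_sample(table)
  X <- table$intensities[study, , drop = FALSE]
  if (log_transform) X <- log(X)
  y <- factor(table$sample_meta$group[study])

  outliers <- detect_outliers(X)
  say("outliers flagged: %d", sum(outliers$outlier))

  uni <- relevant_features(X, delta = config$delta_univariate, group = y)
  say("univariate relevant: %d", sum(uni$relevant))

  seeds <- child_seeds(config$seed, 4L)
  sel_a <- select_n_components(X, y, config$a_max, k = config$k_fold,
                               seed = seeds[1], scale = "mean_center")
  model <- plsda(X, y, ncomp = sel_a$ncomp, scale = "mean_center")
  cv <- cross_validate_mcc(X, y, sel_a$ncomp, k = config$k_fold,
                           seed = seeds[2], scale = "mean_center")
  perm_fit <- permutation_test_mcc(X, y, sel_a$ncomp, "mcc_fit",
                                   n_perm = config$n_perm, seed = seeds[3],
                                   scale = "mean_center")
  perm_cv <- permutation_test_mcc(X, y, sel_a$ncomp, "mcc_cv",
                                  k = config$k_fold,
                                  n_perm = config$n_perm, seed = seeds[4],
                                  scale = "mean_center")
  say("PLS-DA: A = %d, MCC = %.2f (p = %.3g), MCC_5fold = %.2f (p = %.3g)",
      sel_a$ncomp, model$mcc_fit, perm_fit$p_value, cv$mcc_cv,
      perm_cv$p_value)

  stab <- select_relevant(X, y, sel_a$ncomp, config$stability,
                          scale = "mean_center")
  say("stability selection relevant: %d", length(stab$relevant))

  uni_rel <- uni$feature_id[uni$relevant]
  merged <- union(uni_rel, stab$relevant)
  provenance <- ifelse(merged %in% uni_rel & merged %in% stab$relevant,
                       "both",
                       ifelse(merged %in% uni_rel, "univariate",
                              "multivariate"))
  merged_df <- data.frame(feature_id = merged, provenance = provenance,
                          stringsAsFactors = FALSE)

  ann <- NULL; ora <- NULL
  if (length(merged)) {
    fm <- table$feature_meta[match(merged, table$feature_meta$feature_id), ]
    dir <- stats::setNames(uni$direction, uni$feature_id)
    ann <- annotate_features(fm, db, config$tolerance_ppm, direction = dir)
    hits <- unique(ann$hmdb_id[ann$annotated])
    if (length(hits))
      ora <- run_ora(hits, db, delta = config$delta_ora_untargeted)
    say("annotated: %d features; flagged pathways: %d",
        sum(ann$annotated), if (is.null(ora)) 0L else sum(ora$flagged))
  }

  structure(list(calibration = calibration, pqn = pqn, outliers = outliers,
                 univariate = uni, ncomp = sel_a$ncomp, model = model,
                 cv = cv, permutation_fit = perm_fit,
                 permutation_cv = perm_cv, stability = stab,
                 merged = merged_df, annotation = ann, ora = ora,
                 config = config),
            class = "untargeted_result")
}

#' @export
print.untargeted_result <- function(x, ...) {
  cat("untargeted pipeline result\n")
  cat(sprintf("  univariate relevant: %d\n", sum(x$univariate$relevant)))
  cat(sprintf("  PLS-DA: A = %d, MCC = %.2f (p = %.3g), MCC_5fold = %.2f\n",
              x$ncomp, x$model$mcc_fit, x$permutation_fit$p_value,
              x$cv$mcc_cv))
  cat(sprintf("  stability relevant: %d; merged: %d\n",
              length(x$stability$relevant), nrow(x$merged)))
  if (!is.null(x$ora))
    cat(sprintf("  flagged pathways: %d\n", sum(x$ora$flagged)))
  invisible(x)
}

#' Run the targeted validation arm of the pipeline
#'
#' For a named-metabolite concentration panel: autoscaling, univariate
#' relevance at the configured FDR level, PLS-DA (components by
#' cross-validated MCC) with permutation p-value, bootstrap stability
#' selection, and pathway over-representation of the relevant metabolites.
#' Annotation is skipped because the identities are known.
#'
#' @param concentrations numeric matrix, samples x named metabolites.
#' @param group two-class labels per sample.
#' @param config a [pipeline_config()].
#' @param db metabolite database; metabolite columns are mapped to HMDB ids
#'   by name for the pathway analysis.
#' @param verbose print stage-by-stage counts.
#' @return A list of class `targeted_result`.
#' @export
run_targeted <- function(concentrations, group, config, db = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(db)) db <- load_metabolite_db()
  say <- function(...) if (verbose) message(sprintf(...))
  X <- as.matrix(concentrations)
  y <- factor(group)
  if (nlevels(y) != 2) stop("validation: exactly two groups required")

  uni <- relevant_features(X, delta = config$delta_univariate, group = y)
  say("univariate relevant: %d", sum(uni$relevant))

  seeds <- child_seeds(config$seed + 2L, 4L)
  sel_a <- select_n_components(X, y, config$a_max, k = config$k_fold,
                               seed = seeds[1], scale = "autoscale")
  model <- plsda(X, y, ncomp = sel_a$ncomp, scale = "autoscale")
  cv <- cross_validate_mcc(X, y, sel_a$ncomp, k = config$k_fold,
                           seed = seeds[2], scale = "autoscale")
  perm_fit <- permutation_test_mcc(X, y, sel_a$ncomp, "mcc_fit",
                                   n_perm = config$n_perm, seed = seeds[3],
                                   scale = "autoscale")
  perm_cv <- permutation_test_mcc(X, y, sel_a$ncomp, "mcc_cv",
                                  k = config$k_fold,
                                  n_perm = config$n_perm, seed = seeds[4],
                                  scale = "autoscale")
  stab <- select_relevant(X, y, sel_a$ncomp, config$stability,
                          scale = "autoscale")

  rel <- union(uni$feature_id[uni$relevant], stab$relevant)
  ora <- NULL
  if (length(rel)) {
    ids <- vapply(rel, function(nm) {
      hit <- db_lookup(db, nm)
      if (nrow(hit)) hit$hmdb_id[1] else NA_character_
    }, character(1))
    ids <- ids[!is.na(ids)]
    if (length(ids))
      ora <- run_ora(unique(ids), db, delta = config$delta_ora_targeted)
  }
  say("relevant metabolites: %d; flagged pathways: %d", length(rel),
      if (is.null(ora)) 0L else sum(ora$flagged))

  structure(list(univariate = uni, ncomp = sel_a$ncomp, model = model,
                 cv = cv, permutation_fit = perm_fit,
                 permutation_cv = perm_cv, stability = stab,
                 relevant = rel, ora = ora, config = config),
            class = "targeted_result")
}

#' @export
print.targeted_result <- function(x, ...) {
  cat("targeted pipeline result\n")
  cat(sprintf("  univariate relevant: %d\n", sum(x$univariate$relevant)))
  cat(sprintf("  PLS-DA: A = %d, MCC = %.2f (p = %.3g), MCC_5fold = %.2f\n",
              x$ncomp, x$model$mcc_fit, x$permutation_fit$p_value,
              x$cv$mcc_cv))
  cat(sprintf("  relevant metabolites: %d\n", length(x$relevant)))
  if (!is.null(x$ora))
    cat(sprintf("  flagged pathways: %d\n", sum(x$ora$flagged)))
  invisible(x)
}
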