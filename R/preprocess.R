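#' Fit per-feature QC dilution calibration models
#'
#' For every feature, ordinary least squares of the QC intensities on the
#' nominal dilution fraction. Features whose calibration is poor
#' (coefficient of determination below `r2_threshold`) or that have fewer
#' than three non-missing QC observations are marked not retained. The
#' rationale is that a feature whose signal does not track the known QC
#' dilutions is not behaving quantitatively and should not enter the
#' analysis.
#'
#' @param table a [feature_table()] containing QC rows at two or more
#'   distinct nominal dilutions.
#' @param r2_threshold minimum R-squared to retain a feature (default 0.7).
#' @return A list of class `qc_calibration` with per-feature `slope`,
#'   `intercept`, `r2`, `n_obs` and logical `retained`.
#' @export
fit_qc_calibration <- function(table, r2_threshold = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  qc <- table$sample_meta$sample_type == "QC"
  if (!any(qc)) stop("no QC rows in the table")
  d <- table$sample_meta$nominal_dilution[qc]
  if (length(unique(d[!is.na(d)])) < 2)
    stop("QC rows at a single dilution level: slope unidentifiable")
  Y <- table$intensities[qc, , drop = FALSE]
  p <- ncol(Y)
  slope <- intercept <- r2 <- rep(NA_real_, p)
  n_obs <- integer(p)
  for (j in seq_len(p)) {
    ok <- !is.na(Y[, j]) & !is.na(d)
    n_obs[j] <- sum(ok)
    if (n_obs[j] >= 2 && length(unique(d[ok])) >= 2) {
      x <- d[ok]; y <- Y[ok, j]
      sxx <- sum((x - mean(x))^2)
      b <- sum((x - mean(x)) * (y - mean(y))) / sxx
      a <- mean(y) - b * mean(x)
      ssr <- sum((y - (a + b * x))^2)
      sst <- sum((y - mean(y))^2)
      slope[j] <- b; intercept[j] <- a
      r2[j] <- if (sst > 0) 1 - ssr / sst else 0
      # guard tiny negative values from cancellation
      r2[j] <- min(max(r2[j], 0), 1)
    }
  }
  retained <- !is.na(r2) & r2 >= r2_threshold & n_obs >= 3 &
    !is.na(slope) & slope > 0
  structure(list(feature_id = table$feature_meta$feature_id, slope = slope,
                 intercept = intercept, r2 = r2, n_obs = n_obs,
                 retained = retained, r2_threshold = r2_threshold),
            class = "qc_calibration")
}

#' @export
print.qc_calibration <- function(x, ...) {
  cat(sprintf("qc_calibration: %d/%d features retained (R2 >= %.2f)\n",
              sum(x$retained), length(x$retained), x$r2_threshold))
  invisible(x)
}

#' Apply the QC calibration filter (and optional response-factor correction)
#'
#' Restricts the table to features retained by the calibration and, when
#' `correct = TRUE`, divides each retained feature by its calibration slope
#' so that a QC sample at dilution d has expected corrected intensity d.
#'
#' @param table a [feature_table()].
#' @param model a [fit_qc_calibration()] result fitted on the same features.
#' @param correct divide intensities by the per-feature slope (default TRUE);
#'   with `FALSE` the calibration only filters features.
#' @return The filtered (and corrected) [feature_table()].
#' @export
apply_calibration_filter <- function(table, model, correct = TRUE) {
  stopifnot(inherits(table, "feature_table"), inherits(model, "qc_calibration"))
  if (!identical(model$feature_id, table$feature_meta$feature_id))
    stop("calibration model was fitted on a different feature set")
  keep <- which(model$retained)
  if (!length(keep))
    stop("no features retained by the QC calibration; review r2_threshold")
  out <- table[, keep]
  if (correct)
    out$intensities <- sweep(out$intensities, 2, model$slope[keep], "/")
  out
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample multiplicative dilution effects: the reference profile
#' is the feature-wise median over study samples; each sample's quotient
#' median (its estimated dilution factor) is the median over features of
#' sample/reference, ignoring missing values and zero-reference features;
#' the sample is divided by that factor. QC and blank rows are normalized
#' against the same study-sample reference.
#'
#' @param table a [feature_table()] with at least 3 study samples.
#' @return A list of class `pqn_result` with the normalized `table`, the
#'   `reference_profile` and the per-sample `quotient_median`.
#' @export
pqn_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  study <- is_study_sample(table)
  if (sum(study) < 3) stop("PQN requires at least 3 study samples")
  X <- table$intensities
  ref <- apply(X[study, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  if (!any(ref > 0, na.rm = TRUE))
    stop("reference profile has no positive entries")
  usable <- !is.na(ref) & ref > 0
  q <- rep(NA_real_, nrow(X))
  for (i in seq_len(nrow(X))) {
    r <- X[i, usable] / ref[usable]
    r <- r[!is.na(r)]
    if (!length(r))
      stop("sample '", table$sample_meta$sample_id[i],
           "' shares no non-missing features with the reference")
    q[i] <- stats::median(r)
    if (!is.finite(q[i]) || q[i] <= 0)
      stop("non-positive quotient median for sample '",
           table$sample_meta$sample_id[i], "'")
  }
  out <- table
  out$intensities <- X / q
  structure(list(table = out, reference_profile = ref,
                 quotient_median = stats::setNames(q,
                                                   table$sample_meta$sample_id)),
            class = "pqn_result")
}

#' @export
print.pqn_result <- function(x, ...) {
  cat("pqn_result: quotient medians in [",
      sprintf("%.3f", min(x$quotient_median)), ", ",
      sprintf("%.3f", max(x$quotient_median)), "]\n", sep = "")
  invisible(x)
}

#' Missingness filtering and half-minimum imputation
#'
#' Removes features missing in more than `max_missing_fraction` of the study
#' samples, then imputes remaining missing entries with half the feature's
#' minimum observed intensity (the conventional stand-in for values below
#' the detection limit).
#'
#' @param table a [feature_table()].
#' @param max_missing_fraction maximum tolerated fraction of missing study
#'   values per feature, in `[0, 1)` (default 0.5).
#' @return The filtered and imputed [feature_table()].
#' @export
impute_and_filter <- function(table, max_missing_fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (max_missing_fraction < 0 || max_missing_fraction >= 1)
    stop("max_missing_fraction must lie in [0, 1)")
  study <- is_study_sample(table)
  miss <- colMeans(is.na(table$intensities[study, , drop = FALSE]))
  keep <- which(miss <= max_missing_fraction)
  if (!length(keep)) {
    warning("all features removed by the missingness filter")
    return(table[, integer(0)])
  }
  out <- table[, keep]
  X <- out$intensities
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- min(X[!na, j]) / 2
  }
  out$intensities <- X
  out
}

#' Column scaling for multivariate analysis
#'
#' Mean-centering for untargeted feature tables, autoscaling (unit variance,
#' n-1 denominator) for targeted concentration panels. Zero-variance columns
#' are left centered and flagged rather than divided by zero.
#'
#' @param x numeric matrix or [feature_table()] (study samples are scaled).
#' @param mode `"mean_center"` or `"autoscale"`.
#' @return The scaled matrix with attributes `center`, `scale` and
#'   `zero_variance` (logical per column).
#' @export
scale_features <- function(x, mode = c("mean_center", "autoscale")) {
  mode <- match.arg(mode)
  X <- if (inherits(x, "feature_table"))
    x$intensities[is_study_sample(x), , drop = FALSE] else as.matrix(x)
  if (nrow(X) < 2) stop("scaling requires at least 2 samples")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- rep(1, ncol(X))
  zv <- rep(FALSE, ncol(X))
  if (mode == "autoscale") {
    sds <- apply(X, 2, stats::sd)
    zv <- sds == 0 | is.na(sds)
    scl <- ifelse(zv, 1, sds)
    Xc <- sweep(Xc, 2, scl, "/")
  }
  attr(Xc, "center") <- ctr
  attr(Xc, "scale") <- scl
  attr(Xc, "zero_variance") <- zv
  attr(Xc, "mode") <- mode
  Xc
}

#' Invert [scale_features()]
#'
#' @param x a matrix produced by [scale_features()].
#' @return The matrix on the original scale.
#' @export
unscale_features <- function(x) {
  out <- sweep(x, 2, attr(x, "scale"), "*")
  out <- sweep(out, 2, attr(x, "center"), "+")
  attributes(out)[c("center", "scale", "zero_variance", "mode")] <- NULL
  out
}
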