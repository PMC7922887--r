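#' Fit a PCA model for outlier detection
#'
#' Principal component analysis of a scaled data matrix, with components
#' ordered by decreasing explained variance and a deterministic sign
#' convention (the largest-magnitude loading entry of each component is
#' positive).
#'
#' @param X numeric matrix (samples x features), already centered/scaled as
#'   appropriate; the model centers it again defensively.
#' @param a_pca number of components; defaults to the smallest number
#'   covering at least 80 percent of the total variance, capped at 3. The
#'   cap keeps enough residual directions for a stable Q limit when the
#'   sample count is far below the feature count.
#' @return A list of class `pca_model` with `loadings`, `scores`,
#'   `eigenvalues` (score variances, n-1 denominator), `explained`
#'   (fractions), `center`, and `all_eigenvalues`.
#' @export
fit_pca <- function(X, a_pca = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank_x <- sum(ev > max(ev) * 1e-12)
  if (is.null(a_pca)) {
    a_pca <- which(cumsum(ev) / sum(ev) >= 0.8)[1]
    a_pca <- min(a_pca, 3L, rank_x)
  }
  if (a_pca > min(n - 1, ncol(X)))
    stop("a_pca exceeds min(n_samples - 1, n_features)")
  P <- pc$rotation[, seq_len(a_pca), drop = FALSE]
  # sign convention: largest-magnitude loading entry positive
  for (a in seq_len(a_pca)) {
    k <- which.max(abs(P[, a]))
    if (P[k, a] < 0) P[, a] <- -P[, a]
  }
  Xc <- sweep(X, 2, pc$center)
  Tm <- Xc %*% P
  # loadings are orthonormal, so the residual sum of squares per sample is
  # the total centered SS minus the modelled SS
  rss <- rowSums(Xc^2) - rowSums(Tm^2)
  rss[rss < 0] <- 0
  structure(list(loadings = P, scores = Tm, residual_ss = rss,
                 eigenvalues = ev[seq_len(a_pca)],
                 explained = ev[seq_len(a_pca)] / sum(ev),
                 all_eigenvalues = ev, center = pc$center,
                 a_pca = a_pca, n = n, rank = rank_x),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, %.1f%% variance\n", x$a_pca,
              100 * sum(x$explained)))
  invisible(x)
}

#' Hotelling T2 statistics and control limit
#'
#' T2 for sample i is the sum over retained components of
#' score^2 / eigenvalue; the control limit at confidence `gamma` is
#' `A (n-1)(n+1) / (n (n-A))` times the F quantile with `(A, n-A)` degrees
#' of freedom.
#'
#' @param model a [fit_pca()] result.
#' @param gamma confidence level (default 0.95).
#' @return A list with per-sample `t2` and the `limit`.
#' @export
hotelling_t2 <- function(model, gamma = 0.95) {
  stopifnot(inherits(model, "pca_model"))
  A <- model$a_pca; n <- model$n
  if (n <= A) stop("Hotelling T2 requires n > A")
  if (any(model$eigenvalues <= 0))
    stop("zero eigenvalue among retained components")
  t2 <- rowSums(sweep(model$scores^2, 2, model$eigenvalues, "/"))
  lim <- A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(gamma, A, n - A)
  list(t2 = t2, limit = lim)
}

#' Q (squared prediction error) statistics and control limit
#'
#' Q for sample i is the squared norm of its reconstruction residual; the
#' control limit uses the Jackson-Mudholkar approximation computed from the
#' residual eigenvalues.
#'
#' @param model a [fit_pca()] result with fewer components than the data rank.
#' @param gamma confidence level (default 0.95).
#' @return A list with per-sample `q` and the `limit`.
#' @export
spe_q <- function(model, gamma = 0.95) {
  stopifnot(inherits(model, "pca_model"))
  resid_ev <- model$all_eigenvalues[-seq_len(model$a_pca)]
  resid_ev <- resid_ev[resid_ev > max(model$all_eigenvalues) * 1e-12]
  if (!length(resid_ev))
    stop("no residual eigenvalues: model spans the full data rank")
  th1 <- sum(resid_ev); th2 <- sum(resid_ev^2); th3 <- sum(resid_ev^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (h0 < 1e-4) h0 <- 1e-4
  z <- stats::qnorm(gamma)
  lim <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
                  1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  list(q = model$residual_ss, limit = lim)
}

#' PCA-based sample outlier detection with T2 and Q tests
#'
#' Flags a sample when either its Hotelling T2 or its squared prediction
#' error Q exceeds the corresponding control limit at confidence `gamma`.
#'
#' @param x numeric matrix or [feature_table()] (study samples are used,
#'   mean-centered).
#' @param a_pca number of PCA components (default: 80 percent variance rule).
#' @param gamma confidence level (default 0.95).
#' @return A list of class `outlier_report` with per-sample statistics,
#'   limits and flags.
#' @export
detect_outliers <- function(x, a_pca = NULL, gamma = 0.95) {
  X <- if (inherits(x, "feature_table")) {
    ids <- x$sample_meta$sample_id[is_study_sample(x)]
    scale_features(x, "mean_center")
  } else {
    ids <- rownames(x) %||% sprintf("S%02d", seq_len(nrow(x)))
    as.matrix(x)
  }
  if (!is.null(a_pca) && nrow(X) <= a_pca)
    stop("n must exceed a_pca for the T2 test")
  model <- fit_pca(X, a_pca)
  t2 <- hotelling_t2(model, gamma)
  qstat <- model$residual_ss
  if (model$a_pca < model$rank) {
    qlim <- spe_q(model, gamma)$limit
  } else {
    qlim <- Inf
    warning("model spans the full data rank; Q limit undefined, Q test skipped")
  }
  flag <- t2$t2 > t2$limit | qstat > qlim
  structure(list(sample_id = ids, t2 = t2$t2, t2_limit = t2$limit,
                 q = qstat, q_limit = qlim, outlier = flag,
                 gamma = gamma, a_pca = model$a_pca, model = model),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  n_out <- sum(x$outlier)
  cat(sprintf("outlier_report: %d component(s), gamma = %.2f, %d outlier(s)\n",
              x$a_pca, x$gamma, n_out))
  if (n_out) cat("  flagged:", paste(x$sample_id[x$outlier], collapse = ", "),
                 "\n")
  invisible(x)
}
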