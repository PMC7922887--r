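#' Stability-selection configuration
#'
#' Controls the bootstrap stability-selection procedure: within every
#' stratified bootstrap subset the PLS-DA model is refitted and a feature
#' counts as selected when its VIP reaches the subset's selection cutoff;
#' the cutoff is the larger of `vip_cutoff` and the maximum VIP obtained
#' from a refit of the same subset with the class response permuted. The
#' permuted refit calibrates the cutoff to the subset's own null VIP
#' landscape: without it, in the n << p regime some noise feature is
#' always the best-aligned with the response and is selected in virtually
#' every subset, so raw selection frequencies saturate at 1 for null and
#' signal features alike and carry no information.
#'
#' @param n_boot bootstrap subsets (default 500).
#' @param alpha significance level for the permutation-calibrated frequency
#'   threshold (default 0.05).
#' @param vip_cutoff floor of the per-subset VIP selection cutoff
#'   (default 1, the conventional "above-average influence" bar).
#' @param n_null permuted-response rounds used to build the null
#'   distribution of the maximum selection frequency (default 20).
#' @param n_boot_null bootstrap subsets per null round; defaults to
#'   `n_boot` so null and observed frequencies have the same resolution
#'   and remain exchangeable.
#' @param seed RNG seed (mandatory).
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(n_boot = 500, alpha = 0.05, vip_cutoff = 1,
                             n_null = 20, n_boot_null = n_boot,
                             seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(n_boot = n_boot, alpha = alpha, vip_cutoff = vip_cutoff,
                 n_null = n_null, n_boot_null = n_boot_null,
                 seed = as.integer(seed)),
            class = "stability_config")
}

# one stratified bootstrap pass. Per subset: refit PLS-DA, compute VIP,
# refit once more with permuted response, and mark features whose VIP
# reaches max(vip_cutoff, max permuted VIP).
boot_pass <- function(X, y, ncomp, n_boot, vip_cutoff, scale, seed) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("two classes required")
  idx_by <- split(seq_along(y), y)
  counts <- numeric(ncol(X))
  seeds <- child_seeds(seed, n_boot)
  for (b in seq_len(n_boot)) {
    counts <- counts + with_seed(seeds[b], {
      # stratified resampling at the original group sizes guarantees both
      # classes appear in every subset
      idx <- unlist(lapply(idx_by, function(ii)
        sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
      Xb <- center_scale_matrix(X[idx, , drop = FALSE], scale)
      yb <- dummy_response(y[idx])
      A <- min(ncomp, length(idx) - 1)
      v <- vip_core(nipals_core(Xb, yb, A))
      v0 <- vip_core(nipals_core(Xb, sample(yb), A))
      v >= pmax(vip_cutoff, max(v0))
    })
  }
  counts / n_boot
}

#' Bootstrap VIP selection frequencies
#'
#' Draws stratified bootstrap subsets (with replacement, at the original
#' group sizes), refits the PLS-DA model on each, and records the fraction
#' of subsets in which each feature's VIP reaches the subset's
#' permutation-calibrated cutoff (see [stability_config()]).
#'
#' @param x predictor matrix (original scale).
#' @param y two-class labels.
#' @param ncomp latent variables per refit.
#' @param cfg a [stability_config()].
#' @param scale scaling mode, as in [plsda()].
#' @return Per-feature selection frequencies in `[0, 1]`.
#' @export
bootstrap_frequencies <- function(x, y, ncomp, cfg, scale = "mean_center") {
  stopifnot(inherits(cfg, "stability_config"))
  X <- as.matrix(x)
  freq <- boot_pass(X, y, ncomp, cfg$n_boot, cfg$vip_cutoff, scale, cfg$seed)
  stats::setNames(freq, colnames(X))
}

#' Null distribution of the maximum selection frequency
#'
#' For each null round the class response is permuted and a full bootstrap
#' frequency pass is rerun; the maximum per-feature frequency is recorded.
#' The selection threshold is the empirical `1 - alpha` quantile of these
#' maxima, giving family-wise control of false selections at level alpha.
#'
#' @inheritParams bootstrap_frequencies
#' @return A list with the `threshold` and the vector of null `maxima`.
#' @export
null_frequencies <- function(x, y, ncomp, cfg, scale = "mean_center") {
  stopifnot(inherits(cfg, "stability_config"))
  if (cfg$n_null < 20) stop("n_null must be at least 20")
  X <- as.matrix(x)
  seeds <- child_seeds(cfg$seed + 1L, 2L * cfg$n_null)
  maxima <- numeric(cfg$n_null)
  for (r in seq_len(cfg$n_null)) {
    yp <- with_seed(seeds[r], sample(as.factor(y)))
    maxima[r] <- max(boot_pass(X, yp, ncomp, cfg$n_boot_null,
                               cfg$vip_cutoff, scale,
                               seeds[cfg$n_null + r]))
  }
  list(threshold = unname(stats::quantile(maxima, 1 - cfg$alpha, type = 1)),
       maxima = maxima)
}

#' Bootstrap stability selection of relevant features
#'
#' Combines [bootstrap_frequencies()] with the permutation-calibrated
#' threshold of [null_frequencies()]: features whose selection frequency
#' exceeds the threshold are declared relevant from the multivariate point
#' of view.
#'
#' @inheritParams bootstrap_frequencies
#' @return A list of class `selection_result` with `frequency`,
#'   `threshold`, `relevant` (feature ids) and the null `maxima`.
#' @export
select_relevant <- function(x, y, ncomp, cfg, scale = "mean_center") {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- sprintf("F%04d", seq_len(ncol(X)))
  freq <- bootstrap_frequencies(X, y, ncomp, cfg, scale)
  nulld <- null_frequencies(X, y, ncomp, cfg, scale)
  rel <- names(freq)[freq > nulld$threshold]
  structure(list(frequency = freq, threshold = nulld$threshold,
                 relevant = rel, null_maxima = nulld$maxima, config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: %d/%d features relevant (frequency > %.3f, alpha = %.2f)\n",
    length(x$relevant), length(x$frequency), x$threshold, x$config$alpha))
  invisible(x)
}
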