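#' Choose t-test or Mann-Whitney by a Shapiro-Wilk normality gate
#'
#' The Shapiro-Wilk test is applied to each group separately; the t-test is
#' used only when both group p-values exceed 0.10, otherwise the
#' Mann-Whitney test. A constant group (Shapiro-Wilk undefined) falls back
#' to Mann-Whitney with a warning.
#'
#' @param g1,g2 numeric vectors, one per group (at least 3 observations each).
#' @param shapiro_p gate level (default 0.10).
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
normality_gate <- function(g1, g2, shapiro_p = 0.10) {
  if (length(g1) < 3 || length(g2) < 3)
    stop("normality gate requires at least 3 observations per group")
  pv <- vapply(list(g1, g2), function(g) {
    if (stats::sd(g) == 0) {
      warning("constant group: Shapiro-Wilk undefined, using Mann-Whitney")
      return(0)
    }
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  if (all(pv > shapiro_p)) "t_test" else "mann_whitney"
}

#' Two-group test of a single feature
#'
#' Two-sided test by the chosen method: the pooled-variance two-sample
#' t-test (Welch by flag), or the Mann-Whitney test (exact null when both
#' groups have at most 20 observations and there are no ties, otherwise the
#' normal approximation with tie and continuity correction).
#'
#' @param g1,g2 numeric vectors, one per group.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @param welch use the Welch t-test instead of pooled variance.
#' @return A list with `statistic` and `p_value`.
#' @export
test_feature <- function(g1, g2, method = c("t_test", "mann_whitney"),
                         welch = FALSE) {
  method <- match.arg(method)
  if (!length(g1) || !length(g2)) stop("empty group")
  if (method == "t_test") {
    ht <- stats::t.test(g1, g2, var.equal = !welch)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    exact <- length(g1) <= 20 && length(g2) <= 20 &&
      !anyDuplicated(c(g1, g2))
    ht <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = exact, correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate q-values:
#' q_(i) = min over j >= i of (m/j) p_(j), clipped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return The q-values, in the order of `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-feature univariate relevance testing
#'
#' For every feature of a preprocessed two-group table: normality gate, the
#' gated test, then Benjamini-Hochberg adjustment across all features;
#' features with q-value at most `delta` are flagged relevant.
#'
#' @param x a [feature_table()] (study samples) or a numeric matrix plus
#'   `group`.
#' @param delta FDR level (default 0.10).
#' @param group optional group factor when `x` is a matrix.
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return A data.frame with `feature_id`, `method`, `statistic`, `p_value`,
#'   `q_value`, `direction` (which group mean is higher) and `relevant`.
#' @export
relevant_features <- function(x, delta = 0.10, group = NULL, welch = FALSE) {
  if (inherits(x, "feature_table")) {
    study <- is_study_sample(x)
    X <- x$intensities[study, , drop = FALSE]
    group <- x$sample_meta$group[study]
    ids <- x$feature_meta$feature_id
  } else {
    X <- as.matrix(x)
    ids <- colnames(X) %||% sprintf("F%04d", seq_len(ncol(X)))
  }
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly two study groups are required")
  i1 <- group == lev[1]
  res <- data.frame(feature_id = ids, method = NA_character_,
                    statistic = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  dir <- character(ncol(X))
  for (j in seq_len(ncol(X))) {
    g1 <- X[i1, j]; g2 <- X[!i1, j]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    m <- suppressWarnings(normality_gate(g1, g2))
    tt <- test_feature(g1, g2, m, welch = welch)
    res$method[j] <- m
    res$statistic[j] <- tt$statistic
    res$p_value[j] <- tt$p_value
    dir[j] <- if (mean(g1) >= mean(g2)) as.character(lev[1])
    else as.character(lev[2])
  }
  res$q_value <- bh_adjust(res$p_value)
  res$direction <- dir
  res$relevant <- res$q_value <= delta
  res
}
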