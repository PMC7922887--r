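#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the margins, the p-value is the sum of the hypergeometric
#' probabilities of all tables at most as probable as the observed one
#' (with a 1e-7 relative tolerance on the comparison) — the convention of
#' standard statistical software.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = group, columns = covariate status).
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- pr[support == a]
  min(sum(pr[pr <= p_obs * (1 + 1e-7)]), 1)
}

#' Two-sample t-test from group summary statistics
#'
#' Closed-form two-sided t-test given per-group mean, standard deviation
#' and size, for testing printed summary tables without raw data.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param flavor `"pooled"` (equal-variance) or `"welch"`.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (flavor == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) return(list(statistic = 0, df = df, p_value = 1))
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Group comparison report for a clinical covariate table
#'
#' Per covariate: categorical (0/1) covariates get Fisher's exact test on
#' the 2x2 cross-tabulation; numeric covariates are gated by per-group
#' Shapiro-Wilk (p > 0.10 in both groups: pooled t-test, otherwise
#' Mann-Whitney). Tests with p below 0.05 are flagged significant.
#'
#' @param subjects data.frame with a `group` column (two levels) and the
#'   covariates.
#' @param covariates character vector of column names to test; defaults to
#'   every column except `subject_id` and `group`.
#' @return A data.frame: covariate, type, summary per group, test, p_value,
#'   significant.
#' @export
compare_groups <- function(subjects, covariates = NULL) {
  lev <- unique(subjects$group)
  if (length(lev) != 2) stop("exactly two groups required")
  if (is.null(covariates))
    covariates <- setdiff(names(subjects), c("subject_id", "group"))
  g1 <- subjects$group == lev[1]
  rows <- lapply(covariates, function(nm) {
    v <- subjects[[nm]]
    if (is.null(v)) stop("unknown covariate: ", nm)
    if (is.numeric(v) && length(unique(stats::na.omit(v))) > 2) {
      m <- suppressWarnings(normality_gate(v[g1], v[!g1]))
      tt <- test_feature(v[g1], v[!g1], m)
      data.frame(covariate = nm, type = "numeric",
                 summary1 = sprintf("%.1f (%.1f)", mean(v[g1]),
                                    stats::sd(v[g1])),
                 summary2 = sprintf("%.1f (%.1f)", mean(v[!g1]),
                                    stats::sd(v[!g1])),
                 test = m, p_value = tt$p_value, stringsAsFactors = FALSE)
    } else if (all(v %in% c(0, 1, NA))) {
      tab <- rbind(c(sum(v[g1] == 1), sum(v[g1] == 0)),
                   c(sum(v[!g1] == 1), sum(v[!g1] == 0)))
      data.frame(covariate = nm, type = "categorical",
                 summary1 = sprintf("%d (%.0f%%)", tab[1, 1],
                                    100 * tab[1, 1] / sum(tab[1, ])),
                 summary2 = sprintf("%d (%.0f%%)", tab[2, 1],
                                    100 * tab[2, 1] / sum(tab[2, ])),
                 test = "fisher_exact",
                 p_value = fisher_exact_two_sided(tab),
                 stringsAsFactors = FALSE)
    } else {
      stop("covariate '", nm, "' is neither numeric nor binary 0/1")
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05
  out
}
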