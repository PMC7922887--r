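test_that("NIPALS satisfies its algebraic identities and exact-fit case", {
  set.seed(31)
  X <- matrix(rnorm(14 * 10), 14, 10)
  y <- rep(c("case", "control"), 7)
  m <- plsda(X, y, ncomp = 3)
  # scores mutually orthogonal, weights unit norm
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(unname(colSums(m$W^2)), rep(1, 3), tolerance = 1e-12)

  # a single predictor perfectly correlated with y: correlation 1 at A = 1
  x1 <- matrix(ifelse(y == "case", 1, -1) + 0, ncol = 1)
  # within-class score variance is exactly 0 here, so the LDA step warns
  # about its declared ridge fallback
  expect_warning(m1 <- plsda(x1, y, ncomp = 1), "ridge")
  expect_equal(cor(fitted(m1), m1$y_scaled), 1, tolerance = 1e-12)

  expect_error(plsda(X, rep("a", 14), 1), "two classes")
  expect_error(plsda(X, y, ncomp = 20), "ncomp")
})

test_that("predictions match an independent NIPALS reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(32)
  X <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("V", 1:8)))
  y <- rep(c("a", "b"), 6)
  m <- metabocc::plsda(X, y, ncomp = 3)
  Y <- matrix(m$y_scaled, ncol = 1, dimnames = list(rownames(X), "y"))
  ref <- mixOmics::pls(X, Y, ncomp = 3, scale = FALSE, mode = "regression")
  pr <- predict(ref, X)
  expect_lt(max(abs(pr$predict[, 1, 3] - fitted(m))), 1e-8)
  Xn <- matrix(rnorm(5 * 8), 5, 8,
               dimnames = list(paste0("t", 1:5), colnames(X)))
  expect_lt(max(abs(predict(ref, Xn)$predict[, 1, 3] -
                      predict(m, Xn, type = "response"))), 1e-8)
})

test_that("post-transformation isolates the predictive direction", {
  set.seed(33)
  for (r in 1:25) {
    X <- matrix(rnorm(12 * 15), 12, 15)
    y <- rep(c("a", "b"), 6)
    m <- plsda(X, y, ncomp = 2 + r %% 2)
    pt <- post_transform(m)
    # orthogonal scores have zero covariance with the response
    if (ncol(pt$to))
      expect_lt(max(abs(crossprod(pt$to, m$y_scaled))), 1e-8)
    # fitted values are unchanged by the rotation
    Tstar <- cbind(pt$tp, pt$to)
    refit <- Tstar %*% crossprod(pt$R, m$q)
    expect_lt(max(abs(refit - fitted(m))), 1e-10)
    # the rotation preserves total score variance
    expect_equal(sum(apply(Tstar, 2, var)), sum(apply(m$T, 2, var)),
                 tolerance = 1e-8)
  }
  # A = 1: tp is the single score column, to is empty
  X <- matrix(rnorm(10 * 5), 10, 5)
  m1 <- plsda(X, rep(c("a", "b"), 5), ncomp = 1)
  pt1 <- post_transform(m1)
  expect_equal(abs(pt1$tp), abs(drop(m1$T)), tolerance = 1e-12)
  expect_equal(ncol(pt1$to), 0)
})

test_that("VIP satisfies its mean-square identity and ranks signal first", {
  set.seed(34)
  X <- matrix(rnorm(16 * 40), 16, 40)
  m <- plsda(X, rep(c("a", "b"), 8), ncomp = 2)
  expect_equal(mean(vip(m)^2), 1, tolerance = 1e-10)

  # p = 1: the single feature has VIP exactly 1
  m1 <- plsda(matrix(rnorm(16), ncol = 1), rep(c("a", "b"), 8), ncomp = 1)
  expect_equal(vip(m1), 1, tolerance = 1e-12)

  # one informative feature among noise attains the max VIP almost always
  hits <- 0L
  for (r in 1:100) {
    set.seed(3400 + r)
    Xr <- matrix(rnorm(20 * 30), 20, 30)
    yr <- rep(c("a", "b"), each = 10)
    Xr[, 7] <- ifelse(yr == "a", 2, -2) + rnorm(20, 0, 0.4)
    mr <- plsda(Xr, yr, ncomp = 1)
    hits <- hits + (which.max(vip(mr)) == 7)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("LDA on scores separates, ties break as declared, matches MASS", {
  # perfectly separated 1-D scores: zero training errors
  s <- matrix(c(-3, -2.5, -2, 2, 2.5, 3), ncol = 1)
  lab <- rep(c("a", "b"), each = 3)
  expect_equal(as.character(lda_classify(s, lab, s)), lab)

  # symmetric classes, test point exactly at the midpoint: equal priors,
  # so the declared lexicographic tie rule assigns the first class
  expect_equal(as.character(lda_classify(s, lab, matrix(0))), "a")

  # closed-form check: means (0,0)/(2,0), identity covariance -> boundary
  # at x = 1; verify against MASS::lda as an independent oracle
  skip_if_not_installed("MASS")
  set.seed(35)
  Xtr <- rbind(matrix(rnorm(60 * 2), 60, 2),
               matrix(rnorm(60 * 2), 60, 2) + cbind(rep(2, 60), 0))
  ytr <- rep(c("a", "b"), each = 60)
  Xte <- cbind(runif(40, -1, 3), runif(40, -2, 2))
  ours <- lda_classify(Xtr, ytr, Xte)
  mass <- predict(MASS::lda(Xtr, grouping = ytr), Xte)$class
  expect_equal(as.character(ours), as.character(mass))
  pred_lo <- lda_classify(Xtr, ytr, matrix(c(0.5, 0), 1))
  pred_hi <- lda_classify(Xtr, ytr, matrix(c(1.5, 0), 1))
  expect_equal(as.character(c(pred_lo, pred_hi)), c("a", "b"))
})

test_that("MCC follows its closed form", {
  expect_equal(mcc(rbind(c(9, 0), c(1, 9))), 0.9)
  expect_equal(mcc(rbind(c(10, 0), c(0, 10))), 1)
  expect_equal(mcc(rbind(c(5, 5), c(5, 5))), 0)
  expect_equal(mcc(rbind(c(0, 10), c(10, 0))), -1)
  expect_equal(mcc(rbind(c(0, 0), c(3, 7))), 0)   # zero marginal convention
})

test_that("cross-validated MCC is stratified, deterministic and sane", {
  sep <- separated_xy(n_per = 10, delta = 4, sd = 0.3)
  cv <- cross_validate_mcc(sep$x, sep$y, 2, k = 5, seed = 41)
  expect_equal(cv$mcc_cv, 1)
  cv2 <- cross_validate_mcc(sep$x, sep$y, 2, k = 5, seed = 41)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$mcc_cv, cv2$mcc_cv)
  # folds are stratified: every fold holds members of both classes
  for (f in 1:5)
    expect_equal(length(unique(sep$y[cv$folds == f])), 2)
  expect_error(cross_validate_mcc(sep$x[1:6, ], sep$y[1:6], 1, k = 5,
                                  seed = 1), "at least k")
})

test_that("null cross-validated MCC centers at zero", {
  set.seed(42)
  vals <- replicate(40, {
    X <- matrix(rnorm(20 * 25), 20, 25)
    cross_validate_mcc(X, rep(c("a", "b"), 10), 2, k = 5,
                       seed = sample.int(1e6, 1))$mcc_cv
  })
  expect_lt(abs(mean(vals)), 0.15)
})

test_that("in-fit MCC is optimistic relative to cross-validation on average", {
  set.seed(43)
  d <- replicate(60, {
    X <- matrix(rnorm(16 * 30), 16, 30)
    y <- rep(c("a", "b"), 8)
    X[, 1] <- X[, 1] + ifelse(y == "a", 1, -1)
    m <- plsda(X, y, ncomp = 2)
    m$mcc_fit - cross_validate_mcc(X, y, 2, k = 4,
                                   seed = sample.int(1e6, 1))$mcc_cv
  })
  expect_gte(mean(d), 0)
})

test_that("permutation p-values hit the add-one floor and are deterministic", {
  sep <- separated_xy(n_per = 8, delta = 5, sd = 0.2)
  pt <- permutation_test_mcc(sep$x, sep$y, 2, "mcc_cv", n_perm = 49,
                             seed = 51)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p_value, 1 / 50)
  pt2 <- permutation_test_mcc(sep$x, sep$y, 2, "mcc_cv", n_perm = 49,
                              seed = 51)
  expect_identical(pt$null, pt2$null)
  expect_error(permutation_test_mcc(sep$x, sep$y, 2, "auc", n_perm = 9,
                                    seed = 1), "arg")
  expect_error(permutation_test_mcc(sep$x, sep$y, 2, n_perm = 0, seed = 1),
               "n_perm")
})

test_that("component selection maximizes CV MCC with smallest-A ties", {
  sep <- separated_xy(n_per = 10, delta = 4, sd = 0.3)
  expect_equal(select_n_components(sep$x, sep$y, 1, seed = 61)$ncomp, 1)

  # two informative orthogonal directions: A = 2 wins
  set.seed(62)
  n <- 30
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 40, sd = 1), n, 40)
  X[, 1] <- X[, 1] + ifelse(y == "a", 1.2, -1.2)
  X[, 2] <- X[, 2] + rep(c(2, -2), n / 2)  # strong y-unrelated structure
  X[, 3] <- X[, 3] + ifelse(y == "a", 1.2, -1.2) * rep(c(1, -1), n / 2)
  sel <- select_n_components(X, y, 3, seed = 63)
  expect_gte(sel$ncomp, 2)
  set.seed(64)
  Xs <- matrix(rnorm(12 * 3), 12, 3)
  expect_warning(select_n_components(Xs, rep(c("a", "b"), 6), 8, seed = 1),
                 "capped")
})

test_that("plsda methods print, summarize, predict and plot", {
  sep <- separated_xy()
  m <- plsda(sep$x, sep$y, ncomp = 2)
  expect_output(print(m), "PLS-DA model")
  expect_output(print(summary(m)), "R2Y")
  expect_equal(length(coef(m)), ncol(sep$x))
  expect_equal(as.character(predict(m, type = "class")),
               as.character(m$fitted_class))
  expect_equal(dim(predict(m, sep$x, type = "scores")), c(16, 2))
  expect_equal(fitted(m) + residuals(m), m$y_scaled, tolerance = 1e-12)
  pdf(NULL)
  expect_silent(plot(m))
  dev.off()
})
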