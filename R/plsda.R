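#' PLS-DA fitted by NIPALS
#'
#' Partial least squares discriminant analysis for two classes: the class is
#' dummy-coded as a single +1/-1 column and autoscaled, the predictors are
#' scaled by the requested mode, and latent variables are extracted
#' sequentially by NIPALS with deflation of X. Class membership is assessed
#' by linear discriminant analysis on the model scores.
#'
#' @param x numeric matrix, samples x features.
#' @param y two-class factor or character vector (length `nrow(x)`).
#' @param ncomp number of latent variables A (default 2).
#' @param scale `"mean_center"` (untargeted convention) or `"autoscale"`
#'   (targeted convention).
#' @param tol NIPALS convergence tolerance (default 1e-10).
#' @param max_iter NIPALS iteration cap (default 500).
#' @return An object of class `plsda` with weights `W`, loadings `P`,
#'   scores `T`, y-loadings `q`, the per-component explained response sum
#'   of squares `ssy`, the scaling parameters, the LDA classifier on the
#'   scores, fitted classes and the in-fit confusion matrix / MCC.
#' @seealso [post_transform()], [vip()], [cross_validate_mcc()],
#'   [permutation_test_mcc()]
#' @export
plsda <- function(x, y, ncomp = 2, scale = c("mean_center", "autoscale"),
                  tol = 1e-10, max_iter = 500) {
  scale <- match.arg(scale)
  X <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2)
    stop("plsda requires exactly two classes (got ", nlevels(y), ")")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(x)")
  n <- nrow(X); p <- ncol(X)
  if (ncomp > min(n - 1, p))
    stop("ncomp exceeds min(n - 1, n_features)")

  Xs <- scale_features(X, scale)
  ydum <- ifelse(y == levels(y)[1], 1, -1)
  y_center <- mean(ydum)
  y_scale <- stats::sd(ydum)
  if (y_scale == 0) stop("single class in y")
  ys <- (ydum - y_center) / y_scale

  core <- nipals_core(Xs, ys, ncomp, tol = tol, max_iter = max_iter)
  W <- core$W; P <- core$P; Tm <- core$T; q <- core$q; ssy <- core$ssy
  rot <- W %*% solve(crossprod(P, W))   # X_scaled %*% rot = T for new data
  fitted_y <- drop(Tm %*% q)

  lda <- lda_fit(Tm, y)
  pred_class <- lda_predict(lda, Tm)
  cm <- confusion_matrix(y, pred_class)

  structure(list(W = W, P = P, T = Tm, q = q, ssy = ssy, rotation = rot,
                 ncomp = ncomp, levels = levels(y), y = y,
                 y_scaled = ys, y_center = y_center, y_scale = y_scale,
                 x_center = attr(Xs, "center"), x_scale = attr(Xs, "scale"),
                 scale_mode = scale, fitted_response = fitted_y,
                 lda = lda, fitted_class = pred_class,
                 confusion = cm, mcc_fit = mcc(cm),
                 call = match.call()),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d latent variable(s), %d samples x %d features\n",
              x$ncomp, nrow(x$T), nrow(x$W)))
  cat(sprintf("  classes: %s vs %s\n", x$levels[1], x$levels[2]))
  cat(sprintf("  MCC (in fit): %.3f\n", x$mcc_fit))
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  r2y <- object$ssy / sum(object$y_scaled^2)
  out <- list(ncomp = object$ncomp, r2y_per_component = r2y,
              r2y_cum = cumsum(r2y), mcc_fit = object$mcc_fit,
              confusion = object$confusion)
  class(out) <- "summary.plsda"
  out
}

#' @export
print.summary.plsda <- function(x, ...) {
  cat("PLS-DA summary\n")
  tab <- rbind(`R2Y` = x$r2y_per_component, `R2Y (cum)` = x$r2y_cum)
  colnames(tab) <- paste0("LV", seq_len(x$ncomp))
  print(round(tab, 4))
  cat(sprintf("MCC (in fit): %.3f\n", x$mcc_fit))
  cat("Confusion (rows = observed):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) {
  # coefficients on the scaled-X / scaled-y regression; returned per feature
  b <- drop(object$rotation %*% object$q)
  stats::setNames(b, rownames(object$W) %||% NULL)
}

#' Predict from a PLS-DA model
#'
#' @param object a [plsda()] fit.
#' @param newdata numeric matrix on the original predictor scale; the
#'   training data when omitted.
#' @param type `"class"` (LDA assignment on the scores), `"response"`
#'   (fitted dummy response on the autoscaled scale) or `"scores"`.
#' @param ... ignored.
#' @return Predicted classes (factor), responses or a score matrix.
#' @export
predict.plsda <- function(object, newdata = NULL,
                          type = c("class", "response", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Tn <- object$T
  } else {
    Xn <- as.matrix(newdata)
    Xn <- sweep(Xn, 2, object$x_center)
    Xn <- sweep(Xn, 2, object$x_scale, "/")
    Tn <- Xn %*% object$rotation
  }
  switch(type,
         scores = Tn,
         response = drop(Tn %*% object$q),
         class = lda_predict(object$lda, Tn))
}

#' @export
fitted.plsda <- function(object, ...) object$fitted_response

#' @export
residuals.plsda <- function(object, ...)
  object$y_scaled - object$fitted_response

#' Score scatter plot of a (post-transformed) PLS-DA model
#'
#' Plots the predictive score tp against the first orthogonal score to
#' (or against the sample index for a one-component model), colouring the
#' two classes.
#'
#' @param x a [plsda()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, ...) {
  pt <- post_transform(x)
  grp <- x$y
  pch <- ifelse(grp == x$levels[1], 19, 21)
  if (ncol(pt$to) >= 1) {
    graphics::plot(pt$tp, pt$to[, 1], pch = pch,
                   xlab = "tp (predictive)", ylab = "to 1 (orthogonal)", ...)
  } else {
    graphics::plot(seq_along(pt$tp), pt$tp, pch = pch,
                   xlab = "sample", ylab = "tp (predictive)", ...)
  }
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  graphics::legend("topright", legend = x$levels, pch = c(19, 21), bty = "n")
  invisible(x)
}

#' Post-transform a PLS-DA model into predictive and orthogonal scores
#'
#' Rotates the score space by an orthogonal matrix so that a single
#' direction (tp) carries all the covariance between the scores and the
#' dummy response, while the remaining A-1 directions (to) have zero
#' covariance with it. Because the rotation is orthogonal and the
#' prediction depends on the scores only through their span, fitted values
#' are unchanged.
#'
#' @param model a [plsda()] fit.
#' @return A list of class `plsda_pt` with `tp` (length-n predictive score),
#'   `to` (n x (A-1) orthogonal scores) and the rotation matrix `R`
#'   (`scores %*% R = cbind(tp, to)`).
#' @export
post_transform <- function(model) {
  stopifnot(inherits(model, "plsda"))
  A <- model$ncomp
  if (A < 1) stop("post-transformation needs at least one component")
  v <- crossprod(model$T, model$y_scaled)[, 1]  # covariance direction
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("scores carry no covariance with the response")
  if (A == 1) {
    R <- matrix(sign(v), 1, 1)
    tp <- drop(model$T) * sign(v)
    return(structure(list(tp = tp, to = matrix(0, nrow(model$T), 0), R = R),
                     class = "plsda_pt"))
  }
  qrres <- qr(cbind(v / nv, diag(A)))
  R <- qr.Q(qrres)[, seq_len(A), drop = FALSE]
  if (sum(R[, 1] * v) < 0) R <- -R
  Tstar <- model$T %*% R
  structure(list(tp = Tstar[, 1], to = Tstar[, -1, drop = FALSE], R = R),
            class = "plsda_pt")
}

#' Variable influence on projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ) with p
#' the number of features and SSY_a the response sum of squares explained
#' by component a. The mean of VIP^2 over features is exactly 1.
#'
#' @param model a [plsda()] fit.
#' @return Numeric vector of VIP scores, one per feature.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  if (sum(model$ssy) <= 0) stop("model explains no response variance")
  W2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  p <- nrow(model$W)
  drop(sqrt(p * (W2 %*% model$ssy) / sum(model$ssy)))
}

# ---- internal NIPALS core --------------------------------------------------

# sequential NIPALS extraction with X (and y) deflation; X and y arrive
# already scaled. Returns the bare latent structure.
nipals_core <- function(Xs, ys, ncomp, tol = 1e-10, max_iter = 500) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ssy <- numeric(ncomp)
  Xd <- Xs
  yd <- ys
  for (a in seq_len(ncomp)) {
    u <- yd
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) stop("ncomp exceeds the rank of x")
      w <- w / nw
      tt <- drop(Xd %*% w)
      qa <- sum(yd * tt) / sum(tt^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
      u <- yd * qa
    }
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < n * 1e-24) stop("ncomp exceeds the rank of x")
    pa <- crossprod(Xd, tt)[, 1] / tt2
    qa <- sum(yd * tt) / tt2
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt; q[a] <- qa
    ssy[a] <- qa^2 * tt2
    Xd <- Xd - tcrossprod(tt, pa)
    yd <- yd - tt * qa
  }
  list(W = W, P = P, T = Tm, q = q, ssy = ssy)
}

# fast column scaling without attribute bookkeeping (hot path)
center_scale_matrix <- function(X, mode) {
  n <- nrow(X)
  Xc <- X - rep(colMeans(X), each = n)
  if (mode == "autoscale") {
    s <- sqrt(colSums(Xc^2) / (n - 1))
    s[s == 0 | is.na(s)] <- 1
    Xc <- Xc / rep(s, each = n)
  }
  Xc
}

# autoscaled +1/-1 dummy response
dummy_response <- function(y) {
  ydum <- ifelse(y == levels(y)[1], 1, -1)
  s <- stats::sd(ydum)
  if (s == 0) stop("single class in y")
  (ydum - mean(ydum)) / s
}

# VIP from the bare latent structure
vip_core <- function(core) {
  W2 <- sweep(core$W^2, 2, colSums(core$W^2), "/")
  drop(sqrt(nrow(core$W) * (W2 %*% core$ssy) / sum(core$ssy)))
}

# ---- LDA on the score space ------------------------------------------------

lda_fit <- function(scores, labels, ridge = 1e-8) {
  labels <- as.factor(labels)
  lev <- levels(labels)
  if (length(lev) != 2) stop("two classes required in training labels")
  S <- as.matrix(scores)
  mu <- rbind(colMeans(S[labels == lev[1], , drop = FALSE]),
              colMeans(S[labels == lev[2], , drop = FALSE]))
  n1 <- sum(labels == lev[1]); n2 <- sum(labels == lev[2])
  C1 <- stats::cov(S[labels == lev[1], , drop = FALSE])
  C2 <- stats::cov(S[labels == lev[2], , drop = FALSE])
  Sp <- ((n1 - 1) * C1 + (n2 - 1) * C2) / (n1 + n2 - 2)
  Sp[is.na(Sp)] <- 0
  inv <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular pooled covariance: ridge-regularizing with epsilon 1e-8")
    Sp <- Sp + diag(ridge * max(mean(diag(Sp)), 1), ncol(Sp))
    inv <- solve(Sp)
  }
  list(levels = lev, mu = mu, inv = inv,
       prior = c(n1, n2) / (n1 + n2))
}

lda_predict <- function(fit, scores) {
  S <- as.matrix(scores)
  d <- sapply(1:2, function(k) {
    m <- fit$mu[k, ]
    drop(S %*% fit$inv %*% m) - 0.5 * drop(m %*% fit$inv %*% m) +
      log(fit$prior[k])
  })
  d <- matrix(d, nrow = nrow(S))
  pick <- ifelse(d[, 1] > d[, 2], 1L,
                 ifelse(d[, 2] > d[, 1], 2L, NA_integer_))
  if (anyNA(pick)) {   # ties: larger prior, then lexicographic order
    tie_to <- if (fit$prior[1] > fit$prior[2]) 1L
    else if (fit$prior[2] > fit$prior[1]) 2L
    else order(fit$levels)[1]
    pick[is.na(pick)] <- tie_to
  }
  factor(fit$levels[pick], levels = fit$levels)
}

#' Two-class LDA on model scores
#'
#' Linear discriminant analysis with pooled covariance, as used to assign
#' class membership from PLS-DA scores. Ties are broken toward the class
#' with the larger prior, then lexicographically; a singular pooled
#' covariance is ridge-regularized (epsilon 1e-8) with a warning.
#'
#' @param scores_train,labels_train training scores and two-class labels.
#' @param scores_test scores to classify.
#' @return Factor of predicted labels.
#' @export
lda_classify <- function(scores_train, labels_train, scores_test) {
  fit <- lda_fit(scores_train, labels_train)
  lda_predict(fit, scores_test)
}

# ---- MCC, cross-validation, permutation tests ------------------------------

confusion_matrix <- function(observed, predicted) {
  observed <- as.factor(observed)
  lev <- levels(observed)
  predicted <- factor(predicted, levels = lev)
  cm <- table(observed = observed, predicted = predicted)
  matrix(as.numeric(cm), 2, 2, dimnames = dimnames(cm))
}

#' Matthews correlation coefficient of a 2x2 confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that the value is 0 when any marginal is 0. The matrix is
#' read as rows = observed class, columns = predicted class.
#'
#' @param cm 2x2 matrix of non-negative counts.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(all(dim(cm) == 2), all(cm >= 0))
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) stop("each class must have at least k members")
  folds <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' MCC under stratified k-fold cross-validation
#'
#' The entire modelling chain (scaling, NIPALS PLS, LDA on the scores) is
#' re-estimated inside each training fold; held-out predictions are pooled
#' into a single confusion matrix from which one MCC is computed. Folds are
#' stratified by class and deterministic under the seed.
#'
#' @param x predictor matrix (original scale).
#' @param y two-class labels.
#' @param ncomp number of latent variables.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment (mandatory).
#' @param scale scaling mode, as in [plsda()].
#' @return A list with `mcc_cv`, the pooled `confusion`, and `folds`.
#' @export
cross_validate_mcc <- function(x, y, ncomp, k = 5, seed = NULL,
                               scale = "mean_center") {
  X <- as.matrix(x)
  y <- as.factor(y)
  folds <- stratified_folds(y, k, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- plsda(X[tr, , drop = FALSE], y[tr],
                 ncomp = min(ncomp, sum(tr) - 1), scale = scale)
    pred[!tr] <- predict(fit, X[!tr, , drop = FALSE], type = "class")
  }
  cm <- confusion_matrix(y, pred)
  list(mcc_cv = mcc(cm), confusion = cm, folds = folds)
}

#' Permutation test for MCC statistics
#'
#' Permutes the class response, recomputes the full statistic (in-fit MCC or
#' cross-validated MCC, including all refitting) for each permutation, and
#' returns the add-one p-value `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param x predictor matrix.
#' @param y two-class labels.
#' @param ncomp number of latent variables.
#' @param statistic `"mcc_fit"` or `"mcc_cv"`.
#' @param n_perm number of permutations (default 1000).
#' @param k folds for `"mcc_cv"` (default 5).
#' @param seed RNG seed (mandatory).
#' @param scale scaling mode, as in [plsda()].
#' @return A list with `observed`, `p_value`, and the `null` distribution.
#' @export
permutation_test_mcc <- function(x, y, ncomp,
                                 statistic = c("mcc_fit", "mcc_cv"),
                                 n_perm = 1000, k = 5, seed = NULL,
                                 scale = "mean_center") {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be at least 1")
  X <- as.matrix(x)
  y <- as.factor(y)
  seeds <- child_seeds(seed, n_perm + 2L)
  stat_fun <- function(yy, s) {
    if (statistic == "mcc_fit") plsda(X, yy, ncomp = ncomp, scale = scale)$mcc_fit
    else cross_validate_mcc(X, yy, ncomp, k = k, seed = s, scale = scale)$mcc_cv
  }
  observed <- stat_fun(y, seeds[1])
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- with_seed(seeds[b + 1L], sample(y))
    null[b] <- stat_fun(yp, seeds[b + 2L])
  }
  list(observed = observed,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       null = null, statistic = statistic)
}

#' Choose the number of latent variables by cross-validated MCC
#'
#' Evaluates A = 1..A_max by stratified k-fold cross-validation and returns
#' the A maximizing the cross-validated MCC, breaking ties toward the
#' smallest A. An A_max above the data rank is capped with a warning.
#'
#' @param x predictor matrix.
#' @param y two-class labels.
#' @param a_max largest number of components to try.
#' @param k folds (default 5).
#' @param seed RNG seed (mandatory; the same folds are used for every A).
#' @param scale scaling mode.
#' @return A list with the chosen `ncomp` and the `mcc_cv` per candidate A.
#' @export
select_n_components <- function(x, y, a_max, k = 5, seed = NULL,
                                scale = "mean_center") {
  if (a_max < 1) stop("a_max must be at least 1")
  X <- as.matrix(x)
  cap <- min(nrow(X) - ceiling(nrow(X) / k) - 1, ncol(X))
  if (a_max > cap) {
    warning("a_max exceeds the usable rank; capped at ", cap)
    a_max <- cap
  }
  mccs <- vapply(seq_len(a_max), function(a)
    cross_validate_mcc(X, y, a, k = k, seed = seed, scale = scale)$mcc_cv,
    numeric(1))
  list(ncomp = which.max(mccs), mcc_cv = mccs)
}
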