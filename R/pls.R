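# NIPALS partial least squares (PLS2) between an ROI panel (predictors X)
# and seed voxel time courses (responses Y).  The decomposition is
#   X = T P' + E,   Y = U Q' + F,
# with the first pair of score columns maximizing cov(T1, U1).  Weight
# vectors W (unit norm, applied to the deflated X) are kept explicitly;
# Y-side weights Q are unit norm, so crossprod(T1, U1) equals the leading
# singular value of X'Y.

#' Fit a two-block PLS decomposition
#'
#' NIPALS PLS2 with component-wise deflation.  Columns of `X` and `Y` are
#' centered internally (means recorded).  Component signs are aligned so
#' that each Y-score column correlates non-negatively with the row mean of
#' the centered responses; without a convention, PLS components have
#' arbitrary sign and cross-subject loading statistics would be meaningless.
#'
#' @param X t x m predictor matrix (ROI panel).
#' @param Y t x n response matrix (seed voxel time courses).
#' @param ncomp Number of components c (must satisfy c <= min(t - 1, m)).
#' @param tol Convergence tolerance on the weight vector.
#' @param max_iter Maximum NIPALS iterations per component.
#' @param sign_align Apply the sign convention (default `TRUE`).
#' @return An object of class `pls` with elements `T`, `U` (t x c scores),
#'   `P` (m x c X-loadings), `Q` (n x c unit-norm Y-loadings), `W` (m x c
#'   unit-norm X-weights), `C` (n x c Y-regression loadings on T), `E`, `F`
#'   (residual matrices), `x_center`, `y_center`, `cov_scores` (per
#'   component `crossprod(T_a, U_a)/(t-1)`), `ncomp`, and dimension labels.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' Y <- X %*% matrix(rnorm(8), 4, 2) + 0.1 * matrix(rnorm(100), 50, 2)
#' fit <- fit_pls(X, Y, ncomp = 2)
#' fit
#' @export
fit_pls <- function(X, Y, ncomp = 2, tol = 1e-12, max_iter = 500,
                    sign_align = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  t_n <- nrow(X)
  if (nrow(Y) != t_n) ppn_data_error("X and Y must share timepoints")
  m <- ncol(X); n <- ncol(Y)
  if (m < 1 || n < 1) ppn_data_error("X and Y need at least one column")
  if (!is_count(ncomp) || ncomp > min(t_n - 1, m))
    ppn_config_error(sprintf("ncomp must be a count <= min(t - 1, m) = %d",
                             min(t_n - 1, m)))
  sdx <- apply(X, 2L, stats::sd)
  sdy <- apply(Y, 2L, stats::sd)
  if (any(sdx == 0))
    ppn_data_error(paste0("constant predictor column(s): ",
                          paste(colnames(X, do.NULL = FALSE)[sdx == 0],
                                collapse = ", ")))
  if (any(sdy == 0))
    ppn_data_error(paste0("constant response column(s): ",
                          paste(colnames(Y, do.NULL = FALSE)[sdy == 0],
                                collapse = ", ")))
  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2L, x_center, "-")
  Yc <- sweep(Y, 2L, y_center, "-")
  Xd <- Xc; Yd <- Yc
  Tm <- matrix(0, t_n, ncomp); Um <- matrix(0, t_n, ncomp)
  P <- matrix(0, m, ncomp); Q <- matrix(0, n, ncomp)
  W <- matrix(0, m, ncomp); C <- matrix(0, n, ncomp)
  iters <- integer(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2L, stats::var))]
    w_old <- rep(0, m)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt)[, 1]
      q <- q / sqrt(sum(q^2))
      u <- Yd %*% q
      if (sum((w - w_old)^2) < tol^2) break
      w_old <- w
    }
    iters[a] <- it
    tt_ss <- sum(tt^2)
    p <- crossprod(Xd, tt)[, 1] / tt_ss
    cc <- crossprod(Yd, tt)[, 1] / tt_ss
    Tm[, a] <- tt; Um[, a] <- u
    W[, a] <- w; P[, a] <- p; Q[, a] <- q; C[, a] <- cc
    Xd <- Xd - tcrossprod(tt, p)
    Yd <- Yd - tcrossprod(tt, cc)
  }
  fit <- structure(list(
    T = Tm, U = Um, P = P, Q = Q, W = W, C = C,
    E = Xd, F = Yc - tcrossprod(Um, Q),
    x_center = x_center, y_center = y_center,
    ncomp = ncomp, n_timepoints = t_n, iters = iters,
    x_names = colnames(X, do.NULL = FALSE, prefix = "x"),
    y_names = colnames(Y, do.NULL = FALSE, prefix = "y"),
    y_rowmean = rowMeans(Yc)
  ), class = "pls")
  if (sign_align) fit <- align_pls_signs(fit)
  fit$cov_scores <- colSums(fit$T * fit$U) / (t_n - 1)
  rownames(fit$P) <- fit$x_names; rownames(fit$W) <- fit$x_names
  rownames(fit$Q) <- fit$y_names; rownames(fit$C) <- fit$y_names
  fit
}

# Flip each component so cor(U[, a], rowMeans(Yc)) >= 0; tie-break on the
# sign of sum(Q[, a]) when the correlation is numerically zero.
align_pls_signs <- function(fit) {
  rm_y <- fit$y_rowmean
  for (a in seq_len(fit$ncomp)) {
    s <- sum(fit$U[, a] * rm_y)
    if (abs(s) < 1e-12) s <- sum(fit$Q[, a])
    if (s < 0) {
      fit$T[, a] <- -fit$T[, a]; fit$U[, a] <- -fit$U[, a]
      fit$P[, a] <- -fit$P[, a]; fit$Q[, a] <- -fit$Q[, a]
      fit$W[, a] <- -fit$W[, a]; fit$C[, a] <- -fit$C[, a]
    }
  }
  # F is unchanged under joint (U, Q) flips only if recomputed:
  fit$F <- fit$F  # U Q' is invariant to the joint flip; nothing to do
  fit
}

#' @export
print.pls <- function(x, ...) {
  cat(sprintf("PLS2 decomposition: %d timepoints, %d predictors, %d responses, %d component(s)\n",
              x$n_timepoints, length(x$x_names), length(x$y_names), x$ncomp))
  cat("  score covariances:", paste(signif(x$cov_scores, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.pls <- function(object, ...) {
  xvar <- colSums(object$P^2) * colSums(object$T^2) /
    sum((object$E + tcrossprod(object$T, object$P))^2)
  out <- list(ncomp = object$ncomp, cov_scores = object$cov_scores,
              x_variance_explained = xvar, iters = object$iters)
  class(out) <- "summary.pls"
  out
}

#' @export
print.summary.pls <- function(x, ...) {
  cat(sprintf("PLS2 summary (%d components)\n", x$ncomp))
  df <- data.frame(component = seq_len(x$ncomp),
                   score_cov = signif(x$cov_scores, 4),
                   x_var_explained = signif(x$x_variance_explained, 4),
                   nipals_iters = x$iters)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Regression coefficients of the fitted PLS model
#'
#' @param object A `pls` fit.
#' @param ... Unused.
#' @return m x n matrix B such that `fitted(Y) = center + Xc %*% B`.
#' @export
coef.pls <- function(object, ...) {
  B <- object$W %*% solve(crossprod(object$P, object$W), t(object$C))
  dimnames(B) <- list(object$x_names, object$y_names)
  B
}

#' Predict responses from a fitted PLS model
#'
#' @param object A `pls` fit.
#' @param newdata t' x m predictor matrix; defaults to the training
#'   predictors.
#' @param ... Unused.
#' @return t' x n matrix of predicted responses.
#' @export
predict.pls <- function(object, newdata = NULL, ...) {
  B <- coef(object)
  if (is.null(newdata)) {
    Xc <- object$E + tcrossprod(object$T, object$P)
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object$x_names))
      ppn_data_error("newdata must have the training predictor columns")
    Xc <- sweep(newdata, 2L, object$x_center, "-")
  }
  sweep(Xc %*% B, 2L, object$y_center, "+")
}

#' @export
fitted.pls <- function(object, ...) predict(object)

#' @export
residuals.pls <- function(object, ...) {
  Yc <- object$F + tcrossprod(object$U, object$Q)
  sweep(Yc, 2L, object$y_center, "+") - fitted(object)
}

#' Representative seed signal
#'
#' Returns the subject-specific representative time course of the
#' multi-voxel seed: the first Y-score column (sign-aligned, scaled to unit
#' variance).  The first Y-loading column acts as a spatial filter over seed
#' voxels; with `newdata`, that filter is applied to another segment's seed
#' voxel matrix (e.g. a stimulation condition) to obtain the representative
#' signal for that segment.
#'
#' @param fit A `pls` fit.
#' @param newdata Optional t' x n seed voxel matrix to project through the
#'   fitted spatial filter (columns centered by their own means).
#' @return Numeric vector of length t (or t') with unit standard deviation.
#' @export
representative_signal <- function(fit, newdata = NULL) {
  if (!inherits(fit, "pls")) ppn_config_error("fit must be a pls object")
  if (is.null(newdata)) {
    u <- fit$U[, 1]
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(fit$y_names))
      ppn_data_error("newdata must have the fitted seed voxel columns")
    yc <- sweep(newdata, 2L, colMeans(newdata), "-")
    u <- (yc %*% fit$Q[, 1])[, 1]
  }
  u / stats::sd(u)
}
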