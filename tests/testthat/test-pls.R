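test_that("a response contained in X is captured exactly by one component", {
  set.seed(1)
  # centered orthonormal predictors: the cross-covariance with column 2 is
  # then exactly the unit vector on column 2
  X <- qr.Q(qr(scale(matrix(rnorm(90), 30, 3), scale = FALSE)))
  Y <- X[, 2, drop = FALSE]
  fit <- fit_pls(X, Y, ncomp = 1)
  w <- abs(fit$W[, 1])
  expect_gt(w[2], 0.99)
  expect_lt(max(w[c(1, 3)]), 0.1)
  expect_lt(max(abs(fit$F)), 1e-8)
})

test_that("first-component score covariance matches the SVD oracle", {
  set.seed(2)
  X <- matrix(rnorm(80), 20, 4)
  B <- matrix(rnorm(8), 4, 2)
  Y <- X %*% B + 0.1 * matrix(rnorm(40), 20, 2)
  fit <- fit_pls(X, Y, ncomp = 2)
  sv <- svd(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)))
  expect_lt(abs(fit$cov_scores[1] - sv$d[1] / (nrow(X) - 1)), 1e-6)
})

test_that("first-component weights equal the leading singular vector of X'Y", {
  set.seed(3)
  for (i in 1:25) {
    m <- sample(2:6, 1); n <- sample(1:6, 1); t_n <- sample(15:40, 1)
    X <- matrix(rnorm(t_n * m), t_n, m)
    Y <- matrix(rnorm(t_n * n), t_n, n)
    fit <- fit_pls(X, Y, ncomp = 1)
    v1 <- svd(crossprod(scale(X, scale = FALSE),
                        scale(Y, scale = FALSE)))$u[, 1]
    angle <- acos(min(1, abs(sum(fit$W[, 1] * v1))))
    expect_lt(angle, 1e-6)
  }
})

test_that("a response orthogonal to X yields a null decomposition", {
  set.seed(4)
  X <- matrix(rnorm(150), 50, 3)
  Y0 <- matrix(rnorm(100), 50, 2)
  Y <- qr.resid(qr(cbind(1, X)), Y0) + 1e-8 * matrix(rnorm(100), 50, 2)
  fit <- fit_pls(X, Y, ncomp = 1)
  expect_lt(abs(fit$cov_scores[1]), 1e-4)
  pred <- predict(fit)
  r2 <- 1 - sum((Y - pred)^2) / sum(scale(Y, scale = FALSE)^2)
  expect_lt(r2, 0.01)
})

test_that("X-scores are mutually orthogonal and the model reconstructs", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  Y <- X %*% matrix(rnorm(10), 5, 2) + matrix(rnorm(80), 40, 2)
  fit <- fit_pls(X, Y, ncomp = 3)
  ct <- crossprod(fit$T)
  expect_lt(max(abs(ct[upper.tri(ct)])) / max(diag(ct)), 1e-8)
  Xc <- scale(X, scale = FALSE)
  expect_equal(fit$T %*% t(fit$P) + fit$E, Xc,
               ignore_attr = TRUE, tolerance = 1e-10)
  Yc <- scale(Y, scale = FALSE)
  expect_equal(fit$U %*% t(fit$Q) + fit$F, Yc,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("with a single response the fit matches a univariate PLS1 oracle", {
  set.seed(6)
  X <- matrix(rnorm(120), 30, 4)
  y <- X %*% rnorm(4) + rnorm(30)
  fit <- fit_pls(X, y, ncomp = 3)
  expect_equal(drop(predict(fit)), pls1_oracle(X, drop(y), 3),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate inputs raise informative errors", {
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(fit_pls(X, rnorm(20), 1), "constant predictor.*b")
  expect_error(fit_pls(matrix(rnorm(40), 20, 2),
                       cbind(v = rep(2, 20)), 1), "constant response")
  expect_error(fit_pls(matrix(rnorm(40), 20, 2), rnorm(20), 5), "ncomp")
})

test_that("representative signal is invariant to voxel ordering", {
  set.seed(7)
  X <- matrix(rnorm(200), 50, 4)
  Y <- matrix(rnorm(250), 50, 5)
  f1 <- fit_pls(X, Y, 1)
  f2 <- fit_pls(X, Y[, c(3, 1, 5, 2, 4)], 1)
  expect_equal(representative_signal(f1), representative_signal(f2),
               tolerance = 1e-10)
})

test_that("a single voxel's representative signal is the voxel itself", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  y <- cbind(rnorm(50))
  fit <- fit_pls(X, y, 1)
  rep_sig <- representative_signal(fit)
  z <- drop(scale(y))
  expect_equal(abs(cor(rep_sig, z)), 1, tolerance = 1e-10)
  expect_gte(cor(rep_sig, drop(y)), 0)
})

test_that("the representative signal denoises a shared latent", {
  set.seed(9)
  hits <- 0
  latent <- rnorm(241)
  Y <- latent + matrix(rnorm(241 * 20), 241, 20)
  X <- cbind(latent + rnorm(241), matrix(rnorm(241 * 5), 241, 5))
  fit <- fit_pls(X, Y, 1)
  rep_sig <- representative_signal(fit)
  r_rep <- abs(cor(rep_sig, latent))
  r_vox <- abs(cor(Y, latent))
  expect_gte(sum(r_rep > r_vox), 18)
})

test_that("sign convention keeps the score aligned with the mean voxel", {
  set.seed(10)
  for (i in 1:10) {
    X <- matrix(rnorm(150), 30, 5)
    Y <- matrix(rnorm(90), 30, 3)
    fit <- fit_pls(X, Y, 1)
    expect_gte(cor(fit$U[, 1], rowMeans(scale(Y, scale = FALSE))), 0)
  }
})

test_that("scaling the responses leaves loadings and scores' shape alone", {
  set.seed(11)
  X <- matrix(rnorm(200), 40, 5)
  Y <- matrix(rnorm(120), 40, 3)
  f1 <- fit_pls(X, Y, 2)
  f2 <- fit_pls(X, 5 * Y, 2)
  expect_equal(f1$P, f2$P, tolerance = 1e-9)
  expect_equal(representative_signal(f1), representative_signal(f2),
               tolerance = 1e-9)
})

test_that("prediction machinery is self-consistent", {
  set.seed(12)
  X <- matrix(rnorm(200), 40, 5)
  Y <- X %*% matrix(rnorm(15), 5, 3) + 0.2 * matrix(rnorm(120), 40, 3)
  fit <- fit_pls(X, Y, 2)
  B <- coef(fit)
  manual <- sweep(scale(X, scale = FALSE) %*% B, 2, fit$y_center, "+")
  expect_equal(predict(fit), manual, tolerance = 1e-10)
  expect_equal(fitted(fit) + residuals(fit), Y + 0 * Y,
               ignore_attr = TRUE, tolerance = 1e-10)
})
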