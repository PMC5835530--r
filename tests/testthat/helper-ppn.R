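# Shared fixtures and small independent oracles, built in code.

# A small null cohort spec (no couplings, no condition effects).
tiny_null_spec <- function(n_subjects = 4, rng_seed = 1) {
  cohort_spec(n_subjects = n_subjects, rng_seed = rng_seed)
}

# A small planted-coupling spec used across module tests.
tiny_coupled_spec <- function(rng_seed = 1, coupling = 0.5,
                              n_subjects = 5) {
  cohort_spec(
    n_subjects = n_subjects,
    coupled_left = c("Left-Cerebellum-Cortex" = coupling,
                     "Left-Hippocampus" = coupling),
    coupled_right = c("Right-Pallidum" = coupling,
                      "Right-Amygdala" = coupling),
    rng_seed = rng_seed
  )
}

# Independent univariate PLS1 oracle (NIPALS with deflation), used to check
# the multivariate code path in the single-response case.
pls1_oracle <- function(X, y, ncomp) {
  mu <- mean(y)
  X <- scale(X, scale = FALSE); y <- y - mu
  Ws <- matrix(0, ncol(X), ncomp); Ps <- matrix(0, ncol(X), ncomp)
  qs <- numeric(ncomp)
  Xd <- X; yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)[, 1]
    w <- w / sqrt(sum(w^2))
    tt <- Xd %*% w
    p <- crossprod(Xd, tt)[, 1] / sum(tt^2)
    q <- sum(yd * tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, p)
    yd <- yd - tt * q
    Ws[, a] <- w; Ps[, a] <- p; qs[a] <- q
  }
  B <- Ws %*% solve(crossprod(Ps, Ws), qs)
  drop(X %*% B) + mu
}

# Draw t samples from a Gaussian with a given precision matrix.
rmvnorm_prec <- function(t_n, omega) {
  sigma <- solve(omega)
  L <- chol(sigma)
  matrix(rnorm(t_n * nrow(omega)), t_n) %*% L
}

# Population partial correlation of variable 1 against each of the others,
# straight from the precision matrix.
partial_from_precision <- function(omega) {
  -omega[1, -1] / sqrt(omega[1, 1] * diag(omega)[-1])
}
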