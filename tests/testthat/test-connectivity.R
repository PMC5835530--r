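test_that("estimates recover the population partial correlations", {
  # matrix-inversion oracle on a known precision matrix
  omega <- matrix(c(2, -0.6, 0.3, 0,
                    -0.6, 2, -0.4, 0.2,
                    0.3, -0.4, 2, -0.5,
                    0, 0.2, -0.5, 2), 4, 4)
  truth <- partial_from_precision(omega)
  set.seed(1)
  x <- rmvnorm_prec(5000, omega)
  est <- partial_correlation(x[, 1], x[, -1])
  expect_lt(max(abs(est - truth)), 0.03)
})

test_that("null estimates stay inside the sampling envelope", {
  set.seed(2)
  t_n <- 241; k <- 4
  nrep <- 400
  inside <- vapply(seq_len(nrep), function(i) {
    seed <- rnorm(t_n)
    regs <- matrix(rnorm(t_n * k), t_n, k)
    r <- partial_correlation(seed, regs)
    mean(abs(r) < 2 / sqrt(t_n - k))
  }, numeric(1))
  frac <- mean(inside)
  expect_gt(frac, 0.92)
  expect_lt(frac, 0.985)
})

test_that("perfect and null associations give partial r of 1 and 0", {
  set.seed(3)
  seed <- rnorm(200)
  regs <- cbind(copy = seed, noise = rnorm(200))
  r <- partial_correlation(seed, regs)
  expect_equal(unname(r["copy"]), 1, tolerance = 1e-10)
  expect_equal(unname(r["noise"]), 0, tolerance = 1e-10)
})

test_that("residual and precision computations agree to 1e-10", {
  set.seed(4)
  for (i in 1:30) {
    k <- sample(2:8, 1)
    t_n <- sample(40:120, 1)
    seed <- rnorm(t_n)
    regs <- matrix(rnorm(t_n * k), t_n, k)
    a <- partial_correlation(seed, regs, method = "residual")
    b <- partial_correlation(seed, regs, method = "precision")
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("region permutation permutes the output correspondingly", {
  set.seed(5)
  seed <- rnorm(100)
  regs <- matrix(rnorm(500), 100, 5)
  colnames(regs) <- paste0("r", 1:5)
  perm <- c(4, 2, 5, 1, 3)
  r1 <- partial_correlation(seed, regs)
  r2 <- partial_correlation(seed, regs[, perm])
  expect_equal(r2, r1[perm], tolerance = 1e-12)
})

test_that("p-value transform matches a numerically integrated t tail", {
  expect_equal(unname(partial_corr_pvalues(0, 100, 3)), 1)
  r <- 0.5; t_n <- 103; nc <- 1
  df <- t_n - 2 - nc
  tv <- r * sqrt(df / (1 - r^2))
  oracle <- 2 * integrate(function(x) dt(x, df), tv, Inf,
                          rel.tol = 1e-10)$value
  expect_equal(unname(partial_corr_pvalues(r, t_n, nc)), oracle,
               tolerance = 1e-6)
  # monotone decreasing in |r| at fixed df
  grid <- seq(0, 0.95, by = 0.05)
  ps <- partial_corr_pvalues(grid, 120, 4)
  expect_true(all(diff(ps) < 0))
  expect_equal(unname(partial_corr_pvalues(1, 50, 2)), 0)
})

test_that("profiles flag significance consistently with alpha", {
  set.seed(6)
  seed <- rnorm(180)
  regs <- cbind(a = seed + rnorm(180), b = rnorm(180), c = rnorm(180))
  prof <- connectivity_profile(seed, regs, alpha = 0.05,
                               subject_id = "S01", condition = "rest",
                               seed_side = "left")
  expect_identical(prof$significant, prof$p < 0.05)
  expect_true(prof$significant[prof$roi == "a"])
  expect_equal(attr(prof, "n_controlled"), 2L)
})

test_that("overall connectivity sums |r| over significant connections", {
  mk_prof <- function(side, r, sig) {
    out <- data.frame(subject_id = "S01", condition = "rest",
                      seed_side = side, roi = paste0("roi", seq_along(r)),
                      partial_r = r, p = ifelse(sig, 0.01, 0.5),
                      significant = sig, stringsAsFactors = FALSE)
    class(out) <- c("connectivity_profile", "data.frame")
    out
  }
  left <- mk_prof("left", c(0.5, -0.3, 0.1), c(TRUE, TRUE, FALSE))
  right <- mk_prof("right", c(-0.2, 0.05), c(TRUE, FALSE))
  ov <- overall_connectivity(left, right)
  expect_equal(ov$value, 1.0)
  # swapping sides leaves the statistic unchanged
  expect_equal(overall_connectivity(right, left)$value, 1.0)
  # adding one significant connection of |r| = 0.1 adds exactly 0.1
  right2 <- mk_prof("right", c(-0.2, 0.1), c(TRUE, TRUE))
  expect_equal(overall_connectivity(left, right2)$value, 1.1)
  # no significant connections -> 0
  none <- mk_prof("left", c(0.2), FALSE)
  none_r <- mk_prof("right", c(0.1), FALSE)
  expect_equal(overall_connectivity(none, none_r)$value, 0)
})

test_that("degenerate connectivity inputs are rejected", {
  expect_error(partial_correlation(rnorm(10), matrix(rnorm(90), 10, 9)),
               "t > k")
  expect_error(partial_correlation(rep(1, 50), matrix(rnorm(100), 50, 2)),
               "constant")
  set.seed(7)
  seed <- rnorm(50)
  regs <- matrix(rnorm(100), 50, 2)
  regs <- cbind(regs, regs[, 1])  # collinear conditioning set
  expect_error(partial_correlation(seed, regs, method = "residual"),
               "ridge")
  expect_error(partial_correlation(seed, regs, method = "precision"),
               "ridge")
  expect_message(partial_correlation(seed, regs, method = "precision",
                                     ridge = 1e-6), "ridge")
})
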