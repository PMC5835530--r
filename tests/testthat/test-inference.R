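test_that("a zero-mean difference yields t = 0, p = 1", {
  res <- condition_contrast(c(1, -1, 1, -1), rep(0, 4))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_identical(res$direction, "none")
})

test_that("contrast statistics match their closed form", {
  set.seed(1)
  d <- rnorm(23, 0.3, 0.1)
  res <- condition_contrast(d, rep(0, 23), contrast = "noisy-rest")
  tv <- mean(d) / (sd(d) / sqrt(23))
  expect_equal(res$t, tv, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(tv), 22), tolerance = 1e-10)
  expect_equal(res$mean_difference, mean(d), tolerance = 1e-12)
  expect_identical(res$direction, "increase")
})

test_that("the contrast test is calibrated under the null", {
  set.seed(2)
  nrep <- 2000
  rej <- vapply(seq_len(nrep), function(i) {
    condition_contrast(rnorm(23), rep(0, 23))$p < 0.05
  }, logical(1))
  ci <- qbinom(c(0.025, 0.975), nrep, 0.05) / nrep
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("swapping conditions flips t and the mean, not p", {
  set.seed(3)
  on <- rnorm(12, 0.4); off <- rnorm(12)
  a <- condition_contrast(on, off)
  b <- condition_contrast(off, on)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$mean_difference, -b$mean_difference, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("degenerate contrasts raise classed errors", {
  expect_error(condition_contrast(rep(1, 10), rep(0, 10)),
               class = "ppn_degenerate_error")
  expect_error(condition_contrast(c(1, 2), c(0, 0)), "at least 3")
})

make_profiles <- function(r_mat, condition) {
  # r_mat: subjects x rois matrix for one side
  do.call(rbind, lapply(seq_len(nrow(r_mat)), function(s) {
    data.frame(subject_id = sprintf("S%02d", s), condition = condition,
               seed_side = "left", roi = colnames(r_mat),
               partial_r = r_mat[s, ], stringsAsFactors = FALSE)
  }))
}

test_that("per-connection contrasts find a planted change with its sign", {
  set.seed(4)
  base <- matrix(rnorm(23 * 3, 0.3, 0.08), 23, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  up <- base + matrix(rnorm(23 * 3, 0, 0.05), 23, 3)
  up[, "B"] <- up[, "B"] + 0.25
  res <- per_connection_contrasts(make_profiles(up, "noisy"),
                                  make_profiles(base, "rest"),
                                  contrast = "noisy-rest")
  row <- res[res$roi == "B", ]
  expect_true(row$significant)
  expect_identical(row$direction, "increase")
  # an independent paired t.test gives the same statistic
  ht <- t.test(up[, "B"] - base[, "B"])
  expect_equal(row$t, unname(ht$statistic), tolerance = 1e-10)
})

test_that("identical conditions surface per-connection degeneracy", {
  set.seed(5)
  base <- matrix(rnorm(30, 0.3, 0.1), 10, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  expect_error(per_connection_contrasts(make_profiles(base, "noisy"),
                                        make_profiles(base, "rest")),
               class = "ppn_degenerate_error")
  flagged <- per_connection_contrasts(make_profiles(base, "noisy"),
                                      make_profiles(base, "rest"),
                                      on_degenerate = "flag")
  expect_true(all(flagged$degenerate))
  expect_true(all(is.na(flagged$t)))
})

test_that("unpaired subjects are dropped with a warning", {
  set.seed(6)
  on <- matrix(rnorm(20, 0.5, 0.2), 10, 2,
               dimnames = list(NULL, c("A", "B")))
  off <- matrix(rnorm(20, 0.1, 0.2), 10, 2,
                dimnames = list(NULL, c("A", "B")))
  p_on <- make_profiles(on, "noisy")
  p_off <- make_profiles(off, "rest")
  p_off <- p_off[p_off$subject_id != "S03", ]
  expect_warning(res <- per_connection_contrasts(p_on, p_off),
                 "unpaired")
  expect_true(all(res$n_subjects == 9))
})

test_that("a noiseless LEDD effect is recovered exactly", {
  set.seed(7)
  covs <- data.frame(ledd = runif(23, 200, 2000), updrs = rnorm(23, 22, 12),
                     updrs_state = sample(c("on", "off"), 23, TRUE))
  rep_ <- suppressWarnings(covariate_regression(2 * covs$ledd, covs))
  est <- rep_$coefficients
  expect_equal(est$estimate[est$term == "ledd"], 2, tolerance = 1e-8)
  expect_lt(rep_$ledd_p, 1e-10)
})

test_that("a simulated UPDRS effect is recovered on average", {
  set.seed(8)
  coefs <- vapply(1:500, function(i) {
    covs <- data.frame(ledd = rnorm(23), updrs = rnorm(23),
                       updrs_state = rbinom(23, 1, 0.5))
    y <- 0.5 * covs$updrs + rnorm(23)
    est <- covariate_regression(y, covs)$coefficients
    est$estimate[est$term == "updrs"]
  }, numeric(1))
  expect_lt(abs(mean(coefs) - 0.5), 0.05)
})

test_that("the LEDD test is calibrated when connectivity is independent", {
  set.seed(9)
  rej <- vapply(1:500, function(i) {
    covs <- data.frame(ledd = rnorm(23), updrs = rnorm(23),
                       updrs_state = rbinom(23, 1, 0.5))
    covariate_regression(rnorm(23), covs)$ledd_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("collinear covariates are named in the error", {
  covs <- data.frame(ledd = rep(1000, 10), updrs = rnorm(10),
                     updrs_state = rep(1, 10))
  expect_error(covariate_regression(rnorm(10), covs), "collinear")
})

test_that("severity correlation handles exact and sampled relations", {
  x <- c(1, 3, 7, 10, 15)
  res <- severity_correlation(-x, x)
  expect_equal(res$r, -1, tolerance = 1e-12)
  set.seed(10)
  rho <- -0.39
  rs <- vapply(1:5000, function(i) {
    u <- rnorm(23); v <- rho * u + sqrt(1 - rho^2) * rnorm(23)
    severity_correlation(v, u)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.02)
})

test_that("the severity p-value is calibrated under independence", {
  set.seed(11)
  rej <- vapply(1:5000, function(i) {
    severity_correlation(rnorm(23), rnorm(23))$p < 0.05
  }, logical(1))
  ci <- qbinom(c(0.025, 0.975), 5000, 0.05) / 5000
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
  expect_error(severity_correlation(rep(1, 10), rnorm(10)),
               class = "ppn_degenerate_error")
})
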