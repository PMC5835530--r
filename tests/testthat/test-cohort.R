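test_that("cohort spec validation enforces the documented invariants", {
  expect_error(cohort_spec(n_subjects = 0), "count")
  expect_error(cohort_spec(passband = c(0.08, 0.01)), "Nyquist")
  expect_error(cohort_spec(passband = c(0.01, 0.3)), "Nyquist")
  expect_error(cohort_spec(coupled_left = c(0.5)), "named")
  expect_error(cohort_spec(coupled_left = c("NoSuchRegion" = 0.5)),
               "roi_labels")
  expect_error(cohort_spec(condition_effects = list(noisy = list())),
               "exactly")
})

test_that("identical spec and seed regenerate an identical cohort", {
  spec <- tiny_coupled_spec(rng_seed = 11, n_subjects = 3)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
})

test_that("uncoupled cohorts show only noise-level seed-ROI correlations", {
  spec <- tiny_null_spec(n_subjects = 1, rng_seed = 5)
  subj <- generate_cohort(spec)$subjects[[1]]
  blk <- subj$conditions$rest
  z <- subj$truth$latents$rest$left
  r <- drop(cor(z, blk$roi_panel))
  # band-limited series have ~2 * n_bins effective dof, not t
  n_bins <- floor(0.07 * spec$n_timepoints_rest * spec$tr)
  envelope <- 2 / sqrt(2 * n_bins)
  expect_gt(mean(abs(r) < envelope), 0.85)
  expect_lt(abs(mean(r)), 0.06)
})

test_that("deterministic coupling reaches the planted correlation", {
  spec <- cohort_spec(n_subjects = 1, voxel_noise_sd = 0,
                      coupled_left = c("Left-Caudate" = 0.9),
                      n_confounds = 0, rng_seed = 2)
  subj <- generate_cohort(spec)$subjects[[1]]
  blk <- subj$conditions$rest
  seed_mean <- rowMeans(blk$seed_left)
  r <- cor(seed_mean, blk$roi_panel[, "Left-Caudate"])
  expect_lt(abs(r - 0.9), 0.06)
  # zero voxel noise: every voxel equals the latent exactly
  expect_equal(max(abs(blk$seed_left - subj$truth$latents$rest$left)), 0,
               tolerance = 1e-10)
})

test_that("mean sample correlation matches the closed-form mixing weight", {
  # closed form: roi = w z + sqrt(1 - w^2) e with unit-variance parts,
  # so E[cor(z, roi)] = w = 0.6
  spec <- cohort_spec(n_subjects = 200, n_confounds = 0,
                      coupled_left = c("Left-Putamen" = 0.6),
                      n_timepoints_stim = 101, n_seed_voxels_left = 2,
                      n_seed_voxels_right = 2, rng_seed = 31)
  co <- generate_cohort(spec)
  rs <- vapply(co$subjects, function(s) {
    cor(s$truth$latents$rest$left,
        s$conditions$rest$roi_panel[, "Left-Putamen"])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.03)
})

test_that("cohort has the study layout: n subjects x 3 conditions", {
  co <- generate_cohort(cohort_spec(n_subjects = 23, rng_seed = 4))
  expect_length(co$subjects, 23)
  for (s in co$subjects[c(1, 23)]) {
    expect_named(s$conditions, c("rest", "noisy", "sinusoidal"))
    expect_equal(nrow(s$conditions$rest$roi_panel), 241)
    expect_equal(nrow(s$conditions$noisy$roi_panel), 151)
    expect_equal(ncol(s$conditions$rest$roi_panel), 58)
  }
  expect_equal(nrow(co$covariates), 23)
  expect_true(all(co$covariates$updrs >= 0 & co$covariates$updrs <= 108))
  expect_true(all(co$covariates$ledd >= 0))
})

test_that("negative severity slope induces a negative UPDRS-coupling link", {
  spec <- tiny_coupled_spec(rng_seed = 9)
  spec$n_subjects <- 500
  spec$severity_slope <- -0.4
  co <- generate_cohort(spec, signals = FALSE)
  ct <- cor.test(co$covariates$updrs, co$truth$total_coupling)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-6)
})

test_that("generated signals keep >= 90% of power inside the passband", {
  # containment is a property of the BOLD-like signal model itself; the
  # artifactual low-frequency confound admixture is recorded separately and
  # is exactly what the cleaning stage removes
  spec <- tiny_coupled_spec(rng_seed = 12, n_subjects = 1)
  spec$n_confounds <- 0
  blk <- generate_cohort(spec)$subjects[[1]]$conditions$rest
  x <- cbind(blk$roi_panel, blk$seed_left)
  x <- sweep(x, 2, colMeans(x))
  pw <- Mod(mvfft(x))^2
  f <- (seq_len(nrow(x)) - 1) / (nrow(x) * spec$tr)
  f <- pmin(f, 1 / spec$tr - f)
  inb <- f >= spec$passband[1] - 1e-9 & f <= spec$passband[2] + 1e-9
  frac <- colSums(pw[inb, ]) / colSums(pw)
  expect_true(all(frac >= 0.9))
})

test_that("empirical partial correlations converge to manifest targets", {
  # long realization: composite length for the FFT synthesis path
  spec <- cohort_spec(
    n_subjects = 1, n_timepoints_rest = 50400, n_confounds = 0,
    coupled_left = c("Left-Cerebellum-Cortex" = 0.5,
                     "Left-Hippocampus" = 0.4),
    coupled_right = c("Right-Pallidum" = 0.6, "Right-Amygdala" = 0.35),
    n_seed_voxels_left = 2, n_seed_voxels_right = 2,
    n_timepoints_stim = 101, rng_seed = 77)
  co <- generate_cohort(spec)
  subj <- co$subjects[[1]]
  union_set <- co$truth$union_rois
  for (side in c("left", "right")) {
    z <- subj$truth$latents$rest[[side]]
    emp <- partial_correlation(z, subj$conditions$rest$roi_panel[, union_set])
    target <- co$truth$partial_r_targets$rest[[side]]
    expect_lt(max(abs(emp - target[union_set])), 0.02)
  }
})

test_that("cohort round-trips through the TSV/JSON directory format", {
  spec <- tiny_coupled_spec(rng_seed = 21, n_subjects = 3)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$covariates$updrs, co$covariates$updrs,
               tolerance = 1e-9)
  m0 <- co$subjects[[2]]$conditions$noisy$roi_panel
  m1 <- back$subjects[[2]]$conditions$noisy$roi_panel
  expect_equal(unname(m1), unname(m0), tolerance = 1e-9)
  expect_identical(colnames(m1), colnames(m0))
})
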