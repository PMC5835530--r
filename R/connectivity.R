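# Partial-correlation connectivity between the representative seed signal
# and the selected ROI panel, with the overall-connectivity summary.

#' Partial correlations between a seed series and a region panel
#'
#' Element i is the correlation between `seed` and region i after linearly
#' removing the other k-1 regions from both (the regression-residual
#' definition, the package default).  The `"precision"` method computes the
#' equivalent closed form \eqn{-\Omega_{si}/\sqrt{\Omega_{ss}\Omega_{ii}}}
#' from the inverse of the joint sample covariance; the two agree to
#' numerical precision on nonsingular inputs.  If a residual has (numerically)
#' zero variance — e.g. the seed is an exact linear combination of the
#' controls — the corresponding partial correlation is reported as 0.
#'
#' @param seed Numeric vector, length t.
#' @param regions t x k numeric matrix.
#' @param method `"residual"` (default) or `"precision"`.
#' @param ridge Nonnegative ridge added to the normal equations /
#'   covariance diagonal when the conditioning set is ill-conditioned; its
#'   use is signalled with a message.
#' @return Numeric vector of length k (named after region columns).
#' @examples
#' z <- rnorm(200)
#' regs <- cbind(a = z + rnorm(200), b = rnorm(200))
#' partial_correlation(z, regs)
#' @export
partial_correlation <- function(seed, regions,
                                method = c("residual", "precision"),
                                ridge = 0) {
  method <- match.arg(method)
  regions <- as.matrix(regions)
  t_n <- length(seed)
  k <- ncol(regions)
  if (nrow(regions) != t_n)
    ppn_data_error("seed and regions must share timepoints")
  if (t_n <= k + 2)
    ppn_data_error("need t > k + 2 timepoints for k conditioning regions")
  sds <- apply(regions, 2L, stats::sd)
  if (stats::sd(seed) == 0 || any(sds == 0))
    ppn_data_error("constant column in seed or regions")
  labs <- colnames(regions, do.NULL = FALSE, prefix = "roi")
  if (method == "precision") {
    S <- stats::cov(cbind(seed, regions))
    if (ridge > 0) {
      S <- S + diag(ridge, nrow(S))
      message(sprintf("ridge regularization applied (lambda = %.3g)", ridge))
    }
    Om <- tryCatch(solve(S), error = function(e) ppn_data_error(
      "singular joint covariance; retry with ridge > 0"))
    r <- -Om[1, -1] / sqrt(Om[1, 1] * diag(Om)[-1])
    names(r) <- labs
    return(r)
  }
  seed_c <- seed - mean(seed)
  regs_c <- sweep(regions, 2L, colMeans(regions), "-")
  r <- numeric(k)
  for (i in seq_len(k)) {
    z <- regs_c[, -i, drop = FALSE]
    if (ncol(z) == 0L) {
      rs <- seed_c; ri <- regs_c[, i]
    } else {
      if (ridge > 0) {
        g <- crossprod(z) + diag(ridge * t_n, ncol(z))
        bs <- solve(g, crossprod(z, cbind(seed_c, regs_c[, i])))
        res <- cbind(seed_c, regs_c[, i]) - z %*% bs
      } else {
        qz <- qr(z)
        if (qz$rank < ncol(z))
          ppn_data_error(
            "collinear conditioning regions; retry with ridge > 0")
        res <- qr.resid(qz, cbind(seed_c, regs_c[, i]))
      }
      rs <- res[, 1]; ri <- res[, 2]
    }
    ss <- sqrt(sum(rs^2)); si <- sqrt(sum(ri^2))
    tiny_s <- ss < 1e-10 * sqrt(sum(seed_c^2))
    tiny_i <- si < 1e-10 * sqrt(sum(regs_c[, i]^2))
    r[i] <- if (tiny_s || tiny_i) 0 else sum(rs * ri) / (ss * si)
  }
  if (ridge > 0)
    message(sprintf("ridge regularization applied (lambda = %.3g)", ridge))
  names(r) <- labs
  r
}

#' P-values for partial correlation coefficients
#'
#' Two-sided p from the t-transform \eqn{r\sqrt{df/(1-r^2)}} with
#' \eqn{df = t - 2 - n_{controlled}}.  Nominal degrees of freedom are used;
#' for strongly band-limited series this is optimistic (see the package
#' vignette), and an autocorrelation-corrected effective df is available in
#' [connectivity_profile()].
#'
#' @param r Vector of partial correlations.
#' @param n Number of timepoints.
#' @param n_controlled Number of conditioning variables.
#' @return Vector of two-sided p-values.
#' @export
partial_corr_pvalues <- function(r, n, n_controlled) {
  df <- n - 2 - n_controlled
  if (df < 1) ppn_data_error("t - 2 - n_controlled must be >= 1")
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  tv <- r[!exact] * sqrt(df / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(-abs(tv), df = df)
  names(p) <- names(r)
  p
}

# Bartlett-style effective sample size for a pair of autocorrelated series:
# n_eff = n / (1 + 2 * sum_l rho_x(l) rho_y(l)), lags truncated at n/4.
effective_n <- function(x, y) {
  n <- length(x)
  lmax <- floor(n / 4)
  ax <- stats::acf(x, lag.max = lmax, plot = FALSE)$acf[-1]
  ay <- stats::acf(y, lag.max = lmax, plot = FALSE)$acf[-1]
  max(8, n / (1 + 2 * sum(ax * ay)))
}

#' Connectivity profile of one seed side
#'
#' Partial correlations of the representative seed signal against every
#' selected ROI (conditioning on the other selected ROIs), with two-sided
#' p-values and a significance mask at `alpha`.
#'
#' @param seed Representative seed series (length t).
#' @param regions t x k matrix of selected-ROI time courses.
#' @param alpha Per-connection significance level (uncorrected, two-sided).
#' @param method,ridge Passed to [partial_correlation()].
#' @param bartlett Use an autocorrelation-corrected effective sample size in
#'   the p-value transform (default `FALSE`: nominal df).
#' @param subject_id,condition,seed_side Metadata carried into the result.
#' @return Object of class `connectivity_profile`: a data frame (`roi`,
#'   `partial_r`, `p`, `significant`) with metadata attributes
#'   `n_timepoints` and `n_controlled`.
#' @export
connectivity_profile <- function(seed, regions, alpha = 0.05,
                                 method = "residual", ridge = 0,
                                 bartlett = FALSE,
                                 subject_id = NA_character_,
                                 condition = NA_character_,
                                 seed_side = NA_character_) {
  regions <- as.matrix(regions)
  r <- partial_correlation(seed, regions, method = method, ridge = ridge)
  n_ctrl <- ncol(regions) - 1L
  if (bartlett) {
    p <- vapply(seq_along(r), function(i) {
      ne <- max(n_ctrl + 3, effective_n(seed, regions[, i]))
      partial_corr_pvalues(r[i], ne, n_ctrl)
    }, numeric(1))
    names(p) <- names(r)
  } else {
    p <- partial_corr_pvalues(r, length(seed), n_ctrl)
  }
  out <- data.frame(
    subject_id = subject_id, condition = condition, seed_side = seed_side,
    roi = names(r), partial_r = unname(r), p = unname(p),
    significant = unname(p) < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_timepoints") <- length(seed)
  attr(out, "n_controlled") <- n_ctrl
  attr(out, "alpha") <- alpha
  class(out) <- c("connectivity_profile", "data.frame")
  out
}

#' Overall seed connectivity
#'
#' Sums the absolute values of the significant partial-correlation
#' coefficients from both seed sides into a single non-negative scalar per
#' subject and condition.
#'
#' @param left_profile,right_profile `connectivity_profile`s of the two
#'   seed sides for the same subject and condition.
#' @return List with `subject_id`, `condition`, `value`, and
#'   `contributing_connections` (data frame of side/roi/partial_r).
#' @export
overall_connectivity <- function(left_profile, right_profile) {
  for (pr in list(left_profile, right_profile))
    if (!inherits(pr, "connectivity_profile"))
      ppn_config_error("inputs must be connectivity_profile objects")
  same <- function(a, b) identical(a, b) || (is.na(a) && is.na(b))
  if (!same(left_profile$subject_id[1], right_profile$subject_id[1]) ||
      !same(left_profile$condition[1], right_profile$condition[1]))
    ppn_data_error("profiles must refer to the same subject and condition")
  both <- rbind(as.data.frame(left_profile), as.data.frame(right_profile))
  contrib <- both[both$significant, c("seed_side", "roi", "partial_r")]
  list(subject_id = left_profile$subject_id[1],
       condition = left_profile$condition[1],
       value = sum(abs(contrib$partial_r)),
       contributing_connections = contrib)
}
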