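# Group-level inference: stimulation-vs-rest contrasts on overall and
# per-connection connectivity, covariate regression, severity correlation.
# Closed-form tests are delegated to stats::t.test / lm / cor.test.

#' Stimulation-vs-rest contrast on overall connectivity
#'
#' Computes per-subject differences (stimulation minus rest) of the overall
#' connectivity values and performs a one-sample t-test of the differences
#' against zero (equivalently, a paired t-test of the two conditions).
#'
#' @param overall_on,overall_off Per-subject overall connectivity under the
#'   stimulation and rest condition (paired: same subject order, or matching
#'   names).
#' @param contrast Label for the contrast (e.g. `"noisy-rest"`).
#' @return Object of class `contrast_result`: `contrast`, `level`
#'   (`"overall"`), `n_subjects`, `mean_difference`, `t`, `p`, `direction`.
#' @export
condition_contrast <- function(overall_on, overall_off,
                               contrast = "stim-rest") {
  if (!is.null(names(overall_on)) && !is.null(names(overall_off))) {
    common <- intersect(names(overall_on), names(overall_off))
    overall_on <- overall_on[common]; overall_off <- overall_off[common]
  }
  if (length(overall_on) != length(overall_off))
    ppn_data_error("on/off values must be paired by subject")
  d <- overall_on - overall_off
  if (length(d) < 3L) ppn_data_error("need at least 3 paired subjects")
  if (stats::sd(d) == 0)
    ppn_degenerate_error("zero variance of paired differences")
  ht <- stats::t.test(d, mu = 0)
  structure(list(
    contrast = contrast, level = "overall", n_subjects = length(d),
    mean_difference = mean(d), t = unname(ht$statistic),
    p = ht$p.value,
    direction = if (mean(d) > 0) "increase" else if (mean(d) < 0)
      "decrease" else "none"
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s (%s, n = %d): mean diff %.4f, t = %.3f, p = %.4g (%s)\n",
              x$contrast, x$level, x$n_subjects, x$mean_difference, x$t,
              x$p, x$direction))
  invisible(x)
}

#' Per-connection stimulation contrasts
#'
#' Paired t-test per (seed side, ROI) of the partial-correlation change
#' between a stimulation condition and rest across subjects.
#'
#' @param profiles_on,profiles_off Long-format data frames of connectivity
#'   profiles (columns `subject_id`, `seed_side`, `roi`, `partial_r`) for
#'   the stimulation and rest condition; typically rbind-ed
#'   [connectivity_profile()]s.
#' @param alpha Significance level on the (optionally adjusted) p-values.
#' @param correction `"none"` (default) or `"BH"`.
#' @param sided `"two"` (default) or `"one"` (one-sided in the direction of
#'   the observed mean change).
#' @param contrast Contrast label.
#' @param on_degenerate `"error"` (default): a connection whose paired
#'   differences have zero variance raises a degenerate-input error;
#'   `"flag"`: it is returned with `degenerate = TRUE` and NA statistics.
#' @return Data frame, one row per (seed_side, roi): `mean_difference`,
#'   `t`, `p`, `p_adj`, `significant`, `direction`, `n_subjects`.
#' @export
per_connection_contrasts <- function(profiles_on, profiles_off,
                                     alpha = 0.05,
                                     correction = c("none", "BH"),
                                     sided = c("two", "one"),
                                     contrast = "stim-rest",
                                     on_degenerate = c("error", "flag")) {
  correction <- match.arg(correction)
  sided <- match.arg(sided)
  on_degenerate <- match.arg(on_degenerate)
  on <- as.data.frame(profiles_on)
  off <- as.data.frame(profiles_off)
  merged <- merge(on[, c("subject_id", "seed_side", "roi", "partial_r")],
                  off[, c("subject_id", "seed_side", "roi", "partial_r")],
                  by = c("subject_id", "seed_side", "roi"),
                  suffixes = c("_on", "_off"))
  n_on <- nrow(on)
  if (nrow(merged) < n_on)
    warning(sprintf("%d unpaired connection value(s) dropped",
                    n_on - nrow(merged)))
  merged$d <- merged$partial_r_on - merged$partial_r_off
  keys <- unique(merged[, c("seed_side", "roi")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merged[merged$seed_side == keys$seed_side[i] &
                    merged$roi == keys$roi[i], ]
    d <- sub$d
    if (stats::sd(d) == 0) {
      if (on_degenerate == "error")
        ppn_degenerate_error(sprintf(
          "zero variance of paired differences for connection (%s, %s)",
          keys$seed_side[i], keys$roi[i]))
      return(data.frame(contrast = contrast,
                        seed_side = keys$seed_side[i], roi = keys$roi[i],
                        n_subjects = length(d), mean_difference = mean(d),
                        t = NA_real_, p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ht <- stats::t.test(d, mu = 0)
    p <- ht$p.value
    if (sided == "one") p <- p / 2
    data.frame(contrast = contrast, seed_side = keys$seed_side[i],
               roi = keys$roi[i], n_subjects = length(d),
               mean_difference = mean(d), t = unname(ht$statistic), p = p,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$direction <- ifelse(out$mean_difference > 0, "increase",
                          ifelse(out$mean_difference < 0, "decrease",
                                 "none"))
  out
}

#' Covariate regression on overall connectivity
#'
#' Ordinary least squares of per-subject overall connectivity on medication
#' load (LEDD), disease severity (UPDRS motor score) and the on/off state of
#' the UPDRS assessment, with intercept.  The LEDD coefficient's p-value is
#' the headline check that medication load does not drive connectivity.
#'
#' @param overall Per-subject overall connectivity values.
#' @param covariates Data frame with columns `ledd`, `updrs`,
#'   `updrs_state` (`"on"`/`"off"` or 0/1), rows aligned with `overall`.
#' @return Object of class `regression_report`: `coefficients` (estimate,
#'   std_error, t, p per term), `n`, `r_squared`, `ledd_p`.
#' @export
covariate_regression <- function(overall, covariates) {
  if (nrow(covariates) != length(overall))
    ppn_data_error("overall and covariates must align by subject")
  df <- data.frame(
    overall = overall,
    ledd = covariates$ledd,
    updrs = covariates$updrs,
    updrs_state = if (is.character(covariates$updrs_state) ||
                      is.factor(covariates$updrs_state))
      as.integer(covariates$updrs_state == "on") else
        as.numeric(covariates$updrs_state)
  )
  if (anyNA(df)) ppn_data_error("covariates must be complete")
  if (nrow(df) < 5L) ppn_data_error("need n > number of covariates + 1")
  fit <- stats::lm(overall ~ ledd + updrs + updrs_state, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    ppn_data_error(paste0("collinear covariate column(s): ",
                          paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t", "p")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs[, c("term", "estimate", "std_error",
                                          "t", "p")],
                 n = nrow(df), r_squared = sm$r.squared,
                 ledd_p = coefs$p[coefs$term == "ledd"]),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Covariate regression (n = %d, R^2 = %.3f)\n", x$n,
              x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  LEDD effect: p = %.4g\n", x$ledd_p))
  invisible(x)
}

#' Severity correlation
#'
#' Pearson correlation between per-subject overall connectivity (by default
#' the rest-condition baseline) and the UPDRS motor score, with the
#' two-sided t-based p-value.
#'
#' @param overall Per-subject overall connectivity values.
#' @param updrs Per-subject UPDRS motor scores.
#' @return List with `r`, `p`, `n`.
#' @export
severity_correlation <- function(overall, updrs) {
  if (length(overall) != length(updrs))
    ppn_data_error("overall and updrs must align by subject")
  if (length(overall) < 3L) ppn_data_error("need at least 3 subjects")
  if (stats::sd(overall) == 0 || stats::sd(updrs) == 0)
    ppn_degenerate_error("constant input to severity correlation")
  ht <- stats::cor.test(overall, updrs, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(overall))
}
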