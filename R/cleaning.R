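# Temporal preprocessing of extracted time-series matrices: nuisance
# regression, polynomial detrending, zero-phase bandpass filtering.

#' Cleaning configuration
#'
#' @param detrend_order Polynomial trend order to remove (0, 1 or 2; the
#'   default 2 removes linear and quadratic drifts).
#' @param passband Length-2 Hz band retained by the bandpass step.
#' @param tr Sampling interval (repetition time) in seconds.
#' @param derivatives,squares Confound expansion flags: append first
#'   temporal differences and/or element-wise squares of each confound
#'   column.
#' @param do_regression,do_detrend,do_bandpass Per-step switches.
#' @param filter_order Butterworth prototype order of the zero-phase
#'   bandpass (default 4).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(detrend_order = 2, passband = c(0.01, 0.08),
                            tr = 1.985, derivatives = TRUE, squares = TRUE,
                            do_regression = TRUE, do_detrend = TRUE,
                            do_bandpass = TRUE, filter_order = 4) {
  if (!detrend_order %in% 0:2)
    ppn_config_error("detrend_order must be 0, 1 or 2")
  nyq <- 1 / (2 * tr)
  if (!(passband[1] > 0 && passband[1] < passband[2] && passband[2] < nyq))
    ppn_config_error(sprintf(
      "passband must satisfy 0 < low < high < Nyquist (%.4g Hz)", nyq))
  structure(list(detrend_order = detrend_order,
                 passband = as.numeric(passband), tr = tr,
                 derivatives = isTRUE(derivatives),
                 squares = isTRUE(squares),
                 do_regression = isTRUE(do_regression),
                 do_detrend = isTRUE(do_detrend),
                 do_bandpass = isTRUE(do_bandpass),
                 filter_order = filter_order),
            class = "cleaning_config")
}

#' Expand a confound matrix
#'
#' Appends, per the configuration flags, the first temporal differences
#' (backward difference, first row padded with 0) and the element-wise
#' squares of every confound column, mirroring the usual nuisance-regressor
#' expansion of motion parameters.
#'
#' @param confounds t x q numeric matrix (q may be 0).
#' @param config A [cleaning_config()].
#' @return A t x q' matrix with q' = q * (1 + derivatives + squares).
#' @export
expand_confounds <- function(confounds, config = cleaning_config()) {
  confounds <- as.matrix(confounds)
  if (ncol(confounds) == 0L) return(confounds)
  if (nrow(confounds) < 3L) ppn_data_error("need at least 3 timepoints")
  out <- confounds
  if (config$derivatives) {
    d <- rbind(0, diff(confounds))
    colnames(d) <- paste0(colnames(confounds, do.NULL = FALSE,
                                   prefix = "c"), "_dt")
    out <- cbind(out, d)
  }
  if (config$squares) {
    s <- confounds^2
    colnames(s) <- paste0(colnames(confounds, do.NULL = FALSE,
                                   prefix = "c"), "_sq")
    out <- cbind(out, s)
  }
  out
}

# Zero-phase bandpass applied in the frequency domain: multiply each Fourier
# coefficient by the squared-magnitude response of an analog Butterworth
# bandpass prototype (the response a forward-backward IIR pass would have),
# which introduces no phase shift by construction and vectorizes over
# columns.  Columns are demeaned first so no DC leaks through.
butter_bandpass_gain <- function(f, low, high, order) {
  f0sq <- low * high
  bw <- high - low
  g <- numeric(length(f))
  nz <- f > 0
  x <- (f[nz]^2 - f0sq) / (f[nz] * bw)
  g[nz] <- 1 / (1 + x^(2 * order))
  g
}

bandpass_matrix <- function(x, tr, passband, order = 4) {
  x <- as.matrix(x)
  n <- nrow(x)
  x <- sweep(x, 2L, colMeans(x), "-")
  # zero-pad to a 2-3-5-smooth length: prime run lengths make the FFT slow,
  # and padding avoids circular wrap-around of the filter response
  np <- stats::nextn(n, c(2, 3, 5))
  if (np > n) x <- rbind(x, matrix(0, np - n, ncol(x)))
  fs <- 1 / tr
  f <- c(0, seq_len(np - 1)) * fs / np
  f <- pmin(f, fs - f)  # two-sided frequency axis
  g <- butter_bandpass_gain(f, passband[1], passband[2], order)
  xf <- stats::mvfft(x)
  out <- Re(stats::mvfft(xf * g, inverse = TRUE)) / np
  out[seq_len(n), , drop = FALSE]
}

#' Clean a time-series matrix
#'
#' Per column: project out the confound columns and polynomial trend terms
#' by least squares, then apply a zero-phase bandpass to the configured
#' band.  The regression and detrend steps share one design matrix
#' (intercept + polynomial trend + confounds), so the projection is a single
#' orthogonal projection and is idempotent.  Collinear design columns are
#' dropped with a warning.
#'
#' @param ts t x k numeric matrix of time series (one column per signal).
#' @param confounds t x q' matrix of (already expanded) nuisance regressors,
#'   or `NULL`.
#' @param config A [cleaning_config()].
#' @return Cleaned t x k matrix (column means ~ 0).
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' xc <- clean_timeseries(x, NULL, cleaning_config(tr = 2))
#' @export
clean_timeseries <- function(ts, confounds = NULL,
                             config = cleaning_config()) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  if (is.null(confounds)) confounds <- matrix(0, n, 0L)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != n)
    ppn_data_error("ts and confounds must share the number of timepoints")
  q <- if (config$do_regression) ncol(confounds) else 0L
  dorder <- if (config$do_detrend) config$detrend_order else 0L
  if (n <= 2 * (q + dorder + 1))
    ppn_data_error(sprintf(
      "time series too short (t = %d) for %d nuisance + %d trend terms",
      n, q, dorder))
  design <- matrix(1, n, 1L)
  if (dorder > 0) {
    tt <- seq_len(n)
    design <- cbind(design, stats::poly(tt, dorder))
  }
  if (q > 0) design <- cbind(design, confounds)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- qr_d$pivot[(qr_d$rank + 1L):ncol(design)]
    warning(sprintf("dropping %d collinear design column(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    design <- design[, qr_d$pivot[seq_len(qr_d$rank)], drop = FALSE]
    qr_d <- qr(design)
  }
  out <- ts - qr.fitted(qr_d, ts)
  if (config$do_bandpass)
    out <- bandpass_matrix(out, config$tr, config$passband,
                           config$filter_order)
  dimnames(out) <- dimnames(ts)
  out
}

#' Clean every matrix of a cohort
#'
#' Applies [expand_confounds()] + [clean_timeseries()] to the ROI panel and
#' both seed-voxel matrices of every subject and condition, using each
#' block's recorded confounds.
#'
#' @param cohort A `ppn_cohort` (or any list of `subject_dataset`s in
#'   `$subjects`).
#' @param config A [cleaning_config()]; its `tr` is taken from the cohort
#'   spec when available.
#' @return The cohort with cleaned matrices (class preserved); each subject
#'   gains `cleaned = TRUE`.
#' @export
clean_cohort <- function(cohort, config = NULL) {
  if (is.null(config)) {
    config <- cleaning_config(tr = cohort$spec$tr,
                              passband = cohort$spec$passband)
  }
  cohort$subjects <- lapply(cohort$subjects, function(subj) {
    subj$conditions <- lapply(subj$conditions, function(block) {
      conf <- expand_confounds(block$confounds, config)
      # one projection + filter pass over all of the block's signals
      km <- ncol(block$roi_panel); kl <- ncol(block$seed_left)
      combined <- clean_timeseries(
        cbind(block$roi_panel, block$seed_left, block$seed_right),
        conf, config)
      block$roi_panel <- combined[, seq_len(km), drop = FALSE]
      block$seed_left <- combined[, km + seq_len(kl), drop = FALSE]
      block$seed_right <- combined[, -seq_len(km + kl), drop = FALSE]
      block
    })
    subj$cleaned <- TRUE
    subj
  })
  cohort$cleaning <- config
  cohort
}
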