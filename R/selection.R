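# Cross-subject candidate-region selection from PLS X-loadings.

# Stack one component's X-loadings across subjects into a subjects x ROI
# matrix, checking panel consistency.
loading_matrix <- function(models, component = 1) {
  if (is.matrix(models)) return(models)
  if (length(models) < 3L)
    ppn_data_error("need at least 3 subjects for loading tests")
  labs <- models[[1]]$x_names
  rows <- lapply(models, function(mfit) {
    if (!inherits(mfit, "pls"))
      ppn_config_error("models must be pls fits (or a loading matrix)")
    if (component > mfit$ncomp)
      ppn_config_error("component exceeds the fitted component count")
    if (!identical(mfit$x_names, labs))
      ppn_data_error("ROI panel ordering differs across subjects")
    mfit$P[, component]
  })
  out <- do.call(rbind, rows)
  colnames(out) <- labs
  out
}

#' Test PLS loadings across subjects
#'
#' For each ROI, a two-sided one-sample t-test across subjects of the
#' (sign-aligned) X-loading on the chosen component, against zero.  An ROI
#' is selected when its (optionally BH-adjusted) p-value falls below
#' `alpha`.  ROIs with zero cross-subject loading variance are flagged
#' degenerate: selected with p = 0 when the common loading is nonzero.
#'
#' @param models List of `pls` fits (one per subject, same seed side and
#'   identical ROI panel), or a subjects x ROI loading matrix.
#' @param component Which component's loadings to test (default 1).
#' @param alpha Significance level.
#' @param correction `"none"` (default, selection at uncorrected p < alpha
#'   over the panel) or `"BH"`.
#' @return Data frame with one row per ROI: `roi`, `mean_loading`,
#'   `sd_loading`, `t`, `p`, `p_adj`, `selected`, `degenerate`.
#' @export
test_loadings <- function(models, component = 1, alpha = 0.05,
                          correction = c("none", "BH")) {
  correction <- match.arg(correction)
  L <- loading_matrix(models, component)
  if (nrow(L) < 3L) ppn_data_error("need at least 3 subjects")
  n <- nrow(L)
  mu <- colMeans(L)
  sdv <- apply(L, 2L, stats::sd)
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), ifelse(mu != 0, Inf, 0))
  p <- ifelse(sdv > 0, 2 * stats::pt(-abs(tval), df = n - 1),
              ifelse(mu != 0, 0, 1))
  p_adj <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  data.frame(
    roi = colnames(L, do.NULL = FALSE, prefix = "roi"),
    mean_loading = mu, sd_loading = sdv, t = tval, p = p, p_adj = p_adj,
    selected = p_adj < alpha, degenerate = sdv == 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select candidate regions from both seed sides
#'
#' Runs [test_loadings()] for the left-seed and right-seed model lists and
#' forms the final candidate set as the union of the per-side selections.
#'
#' @param left_models,right_models Lists of per-subject `pls` fits (same
#'   subjects, left and right seed).
#' @param alpha Significance level.
#' @param component Component whose loadings are tested.
#' @param correction Multiplicity handling, see [test_loadings()].
#' @return Object of class `ppn_selection`: per-side statistics tables,
#'   `union_set` (ROI labels in panel order), `alpha`, `component`.
#' @export
select_candidate_regions <- function(left_models, right_models,
                                     alpha = 0.05, component = 1,
                                     correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (!is.matrix(left_models) &&
      length(left_models) != length(right_models))
    ppn_data_error("left and right model lists must cover the same subjects")
  left <- test_loadings(left_models, component, alpha, correction)
  right <- test_loadings(right_models, component, alpha, correction)
  if (!identical(left$roi, right$roi))
    ppn_data_error("left/right ROI panels differ")
  sel <- left$roi[left$selected | right$selected]
  structure(list(left = left, right = right, union_set = sel,
                 alpha = alpha, component = component,
                 correction = correction),
            class = "ppn_selection")
}

#' @export
print.ppn_selection <- function(x, ...) {
  cat(sprintf(
    "Candidate-region selection (component %d, alpha %.3g, correction %s)\n",
    x$component, x$alpha, x$correction))
  cat(sprintf("  left seed: %d selected; right seed: %d selected\n",
              sum(x$left$selected), sum(x$right$selected)))
  cat(sprintf("  union set (%d): %s\n", length(x$union_set),
              paste(x$union_set, collapse = ", ")))
  invisible(x)
}
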