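# Pipeline orchestration: simulate -> clean -> select -> connect -> infer,
# plus the optional NIfTI ROI-extraction convenience.  All cross-subject
# aggregation is by ROI label; no stage ever resamples subjects to a common
# grid.

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of every stage.  Defaults:
#' selection on the first PLS component at uncorrected alpha 0.05, partial
#' correlations conditioning on the other selected ROIs, two-sided
#' uncorrected contrasts, and analysis of all conditions on a common
#' segment length with the PLS fitted on their concatenation (see the
#' vignette on why unequal segment lengths or one-condition fitting bias
#' the overall-connectivity contrast).
#'
#' @param cohort A [cohort_spec()], a `ppn_cohort`, or a directory written
#'   by [write_cohort()].
#' @param cleaning A [cleaning_config()] (default built from the cohort's
#'   TR and passband).
#' @param selection_alpha,selection_component,selection_correction Selection
#'   stage settings.
#' @param pls_ncomp Components fitted per subject.
#' @param pls_segments `"all"` (default) fits the PLS on the concatenation
#'   of all (length-matched) conditions, so every condition is equally
#'   in-sample with respect to the learned seed filter — fitting on one
#'   condition only inflates that condition's connectivity and biases the
#'   condition contrasts; `"rest"` fits on the rest run only.
#' @param connectivity_alpha Per-connection significance level.
#' @param conditioning `"partial"` (default) or `"marginal"` (sensitivity
#'   analysis without conditioning).
#' @param ridge Ridge for ill-conditioned conditioning sets.
#' @param bartlett Autocorrelation-corrected df in per-connection p-values.
#' @param match_segment_lengths Analyze every condition on the first
#'   min-common-length timepoints (default `TRUE`).
#' @param inference_sided,inference_correction Per-connection contrast
#'   settings.
#' @param rng_seed Seed used when `cohort` is a spec to simulate.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort,
                            cleaning = NULL,
                            selection_alpha = 0.05,
                            selection_component = 1,
                            selection_correction = "none",
                            pls_ncomp = 2,
                            pls_segments = c("all", "rest"),
                            connectivity_alpha = 0.05,
                            conditioning = c("partial", "marginal"),
                            ridge = 0,
                            bartlett = FALSE,
                            match_segment_lengths = TRUE,
                            inference_sided = "two",
                            inference_correction = "none",
                            rng_seed = 1L) {
  pls_segments <- match.arg(pls_segments)
  conditioning <- match.arg(conditioning)
  if (selection_alpha < 0 || selection_alpha > 1 ||
      connectivity_alpha < 0 || connectivity_alpha > 1)
    ppn_config_error("alpha levels must be in [0, 1]")
  structure(list(cohort = cohort, cleaning = cleaning,
                 selection_alpha = selection_alpha,
                 selection_component = selection_component,
                 selection_correction = selection_correction,
                 pls_ncomp = pls_ncomp, pls_segments = pls_segments,
                 connectivity_alpha = connectivity_alpha,
                 conditioning = conditioning, ridge = ridge,
                 bartlett = bartlett,
                 match_segment_lengths = isTRUE(match_segment_lengths),
                 inference_sided = inference_sided,
                 inference_correction = inference_correction,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

# Read a pipeline config (and optionally an embedded cohort spec) from YAML.
#' Load a pipeline configuration from YAML
#'
#' The YAML may contain a `cohort:` block (passed to [cohort_spec()]; the
#' special keys `coupled_left`/`coupled_right`/`condition_effects` are taken
#' as named maps), a `cleaning:` block ([cleaning_config()] arguments) and
#' top-level pipeline settings ([pipeline_config()] arguments).
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `rng_seed`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) ppn_config_error(paste("missing config", path))
  raw <- yaml::read_yaml(path)
  cohort <- raw$cohort
  if (!is.null(seed)) raw$rng_seed <- seed
  if (is.character(cohort)) {
    cohort_obj <- cohort  # directory of TSVs
  } else {
    args <- cohort
    for (f in c("coupled_left", "coupled_right"))
      if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    if (!is.null(args$condition_effects))
      args$condition_effects <- lapply(args$condition_effects,
                                       function(s) lapply(s, unlist))
    if (!is.null(raw$rng_seed)) args$rng_seed <- raw$rng_seed
    cohort_obj <- do.call(cohort_spec, args)
  }
  cleaning <- NULL
  if (!is.null(raw$cleaning))
    cleaning <- do.call(cleaning_config, raw$cleaning)
  keep <- intersect(names(raw), setdiff(names(formals(pipeline_config)),
                                        c("cohort", "cleaning")))
  do.call(pipeline_config,
          c(list(cohort = cohort_obj, cleaning = cleaning), raw[keep]))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "ppn_error"))
      stop(structure(class = class(e),
                     list(message = sprintf("stage '%s': %s", name,
                                            conditionMessage(e)),
                          call = NULL)))
    ppn_stop(sprintf("stage '%s': %s", name, conditionMessage(e)))
  })
}

# Truncate every condition block of a (raw or cleaned) cohort to its first
# t_use timepoints.  Used to put all conditions through an identical
# pipeline: cleaning a longer run and truncating afterwards leaves
# different residual autocorrelation than cleaning the short run, which
# biases condition contrasts of the thresholded connectivity statistic.
truncate_cohort <- function(cohort, t_use) {
  cohort$subjects <- lapply(cohort$subjects, function(subj) {
    subj$conditions <- lapply(subj$conditions, function(block) {
      for (what in c("roi_panel", "seed_left", "seed_right", "confounds"))
        block[[what]] <- block[[what]][seq_len(min(t_use,
                                                   nrow(block[[what]]))), ,
                                       drop = FALSE]
      block
    })
    subj
  })
  cohort
}

# Fit per-subject, per-side PLS models on the configured segments.  With
# pls_segments = "all" on a length-matched cohort, every condition
# contributes the same number of timepoints, so no condition is more
# "in-sample" than another.
fit_subject_models <- function(cohort, config) {
  segs <- function(subj, what) {
    if (config$pls_segments == "rest") return(subj$conditions$rest[[what]])
    do.call(rbind, lapply(subj$conditions, `[[`, what))
  }
  lapply(c(left = "seed_left", right = "seed_right"), function(side_block) {
    lapply(cohort$subjects, function(subj) {
      fit_pls(segs(subj, "roi_panel"), segs(subj, side_block),
              ncomp = config$pls_ncomp)
    })
  })
}

# Per-subject/condition/side connectivity profiles on the selected panel.
# `baseline_blocks`, when given, holds separately cleaned full-length rest
# matrices per subject for the baseline (severity/medication) analyses.
profile_cohort <- function(cohort, models, union_set, config,
                           baseline_blocks = NULL) {
  conds <- names(cohort$subjects[[1]]$conditions)
  marginal <- config$conditioning == "marginal"
  rows <- list()
  overall <- list()
  baseline <- list()
  for (sid in names(cohort$subjects)) {
    subj <- cohort$subjects[[sid]]
    for (cond in c(conds, if (!is.null(baseline_blocks)) "rest_full")) {
      full_rest <- cond == "rest_full"
      block <- if (full_rest) baseline_blocks[[sid]] else
        subj$conditions[[cond]]
      profs <- lapply(c("left", "right"), function(side) {
        voxels <- block[[paste0("seed_", side)]]
        regions <- block$roi_panel[, union_set, drop = FALSE]
        rep_sig <- representative_signal(models[[side]][[sid]], voxels)
        if (marginal) {
          r <- drop(stats::cor(rep_sig, regions))
          names(r) <- colnames(regions)
          p <- partial_corr_pvalues(r, length(rep_sig), 0L)
          prof <- data.frame(subject_id = sid, condition = cond,
                             seed_side = side, roi = names(r),
                             partial_r = unname(r), p = unname(p),
                             significant = unname(p) <
                               config$connectivity_alpha,
                             stringsAsFactors = FALSE)
          class(prof) <- c("connectivity_profile", "data.frame")
          prof
        } else {
          connectivity_profile(rep_sig, regions,
                               alpha = config$connectivity_alpha,
                               ridge = config$ridge,
                               bartlett = config$bartlett,
                               subject_id = sid, condition = cond,
                               seed_side = side)
        }
      })
      names(profs) <- c("left", "right")
      ov <- overall_connectivity(profs$left, profs$right)
      if (full_rest) {
        baseline[[length(baseline) + 1L]] <-
          data.frame(subject_id = sid, value = ov$value,
                     stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- rbind(as.data.frame(profs$left),
                                           as.data.frame(profs$right))
        overall[[length(overall) + 1L]] <-
          data.frame(subject_id = sid, condition = cond, value = ov$value,
                     stringsAsFactors = FALSE)
      }
    }
  }
  overall <- do.call(rbind, overall)
  # Baseline overall connectivity: the full-length rest segment (all rest
  # data) when contrasts are computed on matched segment lengths.
  if (length(baseline)) {
    baseline <- do.call(rbind, baseline)
  } else {
    baseline <- overall[overall$condition == "rest",
                        c("subject_id", "value")]
  }
  list(profiles = do.call(rbind, rows), overall = overall,
       baseline = baseline)
}

# Clean the full-length rest block of every subject (for the baseline
# analyses, which never compare across conditions).
clean_rest_full <- function(cohort, config) {
  lapply(cohort$subjects, function(subj) {
    block <- subj$conditions$rest
    conf <- expand_confounds(block$confounds, config)
    km <- ncol(block$roi_panel); kl <- ncol(block$seed_left)
    combined <- clean_timeseries(
      cbind(block$roi_panel, block$seed_left, block$seed_right),
      conf, config)
    list(roi_panel = combined[, seq_len(km), drop = FALSE],
         seed_left = combined[, km + seq_len(kl), drop = FALSE],
         seed_right = combined[, -seq_len(km + kl), drop = FALSE])
  })
}

#' Analyze a cohort end to end
#'
#' Runs cleaning, per-subject PLS, candidate-region selection, connectivity
#' profiling and group inference on an in-memory cohort.
#'
#' @param cohort A `ppn_cohort` (raw; it is cleaned internally unless
#'   already flagged cleaned).
#' @param config A [pipeline_config()] (the `cohort` field of the config is
#'   ignored here).
#' @return Object of class `ppn_analysis` with elements `selection`,
#'   `profiles` (long data frame), `overall` (data frame), `contrasts`
#'   (overall-level contrast results), `per_connection` (data frame),
#'   `regression`, `severity`, and `config`.
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_subjects = 6,
#'                     coupled_left = c("Left-Hippocampus" = 0.6),
#'                     rng_seed = 7)
#' co <- generate_cohort(spec)
#' res <- analyze_cohort(co, pipeline_config(spec))
#' print(res)
#' }
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(cohort$spec)) {
  if (!inherits(cohort, "ppn_cohort")) ppn_config_error(
    "cohort must be a ppn_cohort")
  baseline_blocks <- NULL
  cleaned <- stage("clean", {
    cfg_clean <- config$cleaning
    if (is.null(cfg_clean))
      cfg_clean <- cleaning_config(tr = cohort$spec$tr,
                                   passband = cohort$spec$passband)
    if (isTRUE(cohort$subjects[[1]]$cleaned)) {
      if (config$match_segment_lengths) {
        t_use <- min(vapply(cohort$subjects[[1]]$conditions,
                            function(b) nrow(b$roi_panel), numeric(1)))
        baseline_blocks <- lapply(cohort$subjects, function(s)
          s$conditions$rest)
        truncate_cohort(cohort, t_use)
      } else cohort
    } else if (config$match_segment_lengths) {
      t_use <- min(vapply(cohort$subjects[[1]]$conditions,
                          function(b) nrow(b$roi_panel), numeric(1)))
      baseline_blocks <- clean_rest_full(cohort, cfg_clean)
      clean_cohort(truncate_cohort(cohort, t_use), cfg_clean)
    } else {
      clean_cohort(cohort, cfg_clean)
    }
  })
  models <- stage("pls", fit_subject_models(cleaned, config))
  selection <- stage("select", select_candidate_regions(
    models$left, models$right, alpha = config$selection_alpha,
    component = config$selection_component,
    correction = config$selection_correction))
  if (length(selection$union_set) == 0L)
    stage("connect", ppn_degenerate_error("empty candidate set"))
  conn <- stage("connect",
                profile_cohort(cleaned, models, selection$union_set, config,
                               baseline_blocks = baseline_blocks))
  inference <- stage("infer", {
    ov <- conn$overall
    get_vals <- function(cond) {
      v <- ov$value[ov$condition == cond]
      names(v) <- ov$subject_id[ov$condition == cond]
      v
    }
    rest <- get_vals("rest")
    contrasts <- lapply(c(noisy = "noisy", sinusoidal = "sinusoidal"),
                        function(cond) {
      condition_contrast(get_vals(cond), rest,
                         contrast = paste0(cond, "-rest"))
    })
    prof <- conn$profiles
    per_conn <- do.call(rbind, lapply(c("noisy", "sinusoidal"),
                                      function(cond) {
      per_connection_contrasts(
        prof[prof$condition == cond, ], prof[prof$condition == "rest", ],
        alpha = config$connectivity_alpha,
        correction = config$inference_correction,
        sided = config$inference_sided,
        contrast = paste0(cond, "-rest"),
        on_degenerate = "flag")
    }))
    base <- conn$baseline$value
    names(base) <- conn$baseline$subject_id
    covs <- cleaned$covariates[match(names(base),
                                     cleaned$covariates$subject_id), ]
    regression <- covariate_regression(unname(base), covs)
    severity <- severity_correlation(unname(base), covs$updrs)
    list(contrasts = contrasts, per_connection = per_conn,
         regression = regression, severity = severity)
  })
  structure(list(selection = selection, profiles = conn$profiles,
                 overall = conn$overall,
                 contrasts = inference$contrasts,
                 per_connection = inference$per_connection,
                 regression = inference$regression,
                 severity = inference$severity,
                 config = config),
            class = "ppn_analysis")
}

#' @export
print.ppn_analysis <- function(x, ...) {
  cat("Seed connectivity analysis\n")
  cat(sprintf("  candidate regions (union of both seeds): %d\n",
              length(x$selection$union_set)))
  for (ct in x$contrasts) print(ct)
  cat(sprintf("  severity correlation (rest): r = %.3f, p = %.4g (n = %d)\n",
              x$severity$r, x$severity$p, x$severity$n))
  cat(sprintf("  LEDD regression effect: p = %.4g\n", x$regression$ledd_p))
  sig <- x$per_connection[x$per_connection$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant per-connection changes:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s %s seed ~ %s: t = %.2f, p = %.4g (%s)\n",
                  sig$contrast[i], sig$seed_side[i], sig$roi[i], sig$t[i],
                  sig$p[i], sig$direction[i]))
  }
  invisible(x)
}

#' Run the full pipeline and write result files
#'
#' Simulates (or loads) the cohort, analyzes it, and writes the result
#' files: `selection.tsv`, `selection.json`, `connectivity.tsv`,
#' `overall.tsv`, `contrasts.tsv`, `regression.json`, `severity.json`.
#' Identical config + seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()], or the path of a YAML file for
#'   [read_pipeline_config()].
#' @param out Output directory.
#' @param seed Optional integer overriding the config's seed.
#' @return The `ppn_analysis`, invisibly; results are written to `out`.
#' @export
run_pipeline <- function(config, out, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config, seed)
  if (!inherits(config, "pipeline_config"))
    ppn_config_error("config must be a pipeline_config or YAML path")
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  cohort <- stage("simulate", {
    src <- config$cohort
    if (inherits(src, "ppn_cohort")) src
    else if (inherits(src, "cohort_spec")) {
      src$rng_seed <- config$rng_seed
      generate_cohort(src)
    } else if (is.character(src)) read_cohort(src)
    else ppn_config_error("config$cohort must be a spec, cohort or directory")
  })
  res <- analyze_cohort(cohort, config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ver <- as.character(utils::packageVersion("ppnconn"))
  sel <- rbind(cbind(seed_side = "left", res$selection$left),
               cbind(seed_side = "right", res$selection$right))
  write_table_tsv(sel[, c("seed_side", "roi", "mean_loading", "t", "p",
                          "selected")],
                  file.path(out, "selection.tsv"))
  jsonlite::write_json(
    list(version = ver, union_set = res$selection$union_set,
         alpha = res$selection$alpha, component = res$selection$component,
         correction = res$selection$correction,
         config = config_echo(config)),
    file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_table_tsv(res$profiles, file.path(out, "connectivity.tsv"))
  write_table_tsv(res$overall, file.path(out, "overall.tsv"))
  ctr <- do.call(rbind, lapply(res$contrasts, function(ct)
    data.frame(contrast = ct$contrast, level = ct$level,
               seed_side = NA, roi = NA, n_subjects = ct$n_subjects,
               mean_difference = ct$mean_difference, t = ct$t, p = ct$p,
               direction = ct$direction, stringsAsFactors = FALSE)))
  pc <- res$per_connection
  ctr <- rbind(ctr, data.frame(contrast = pc$contrast, level = "connection",
                               seed_side = pc$seed_side, roi = pc$roi,
                               n_subjects = pc$n_subjects,
                               mean_difference = pc$mean_difference,
                               t = pc$t, p = pc$p,
                               direction = pc$direction,
                               stringsAsFactors = FALSE))
  write_table_tsv(ctr, file.path(out, "contrasts.tsv"))
  jsonlite::write_json(
    list(version = ver, coefficients = res$regression$coefficients,
         n = res$regression$n, r_squared = res$regression$r_squared,
         ledd_p = res$regression$ledd_p),
    file.path(out, "regression.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(version = ver, r = res$severity$r, p = res$severity$p,
         n = res$severity$n),
    file.path(out, "severity.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(res)
}

# Config echo for serialized outputs (drop the possibly large cohort field).
config_echo <- function(config) {
  out <- unclass(config)
  out$cohort <- if (is.character(out$cohort)) out$cohort else "inline"
  out$cleaning <- if (is.null(out$cleaning)) "default" else
    unclass(out$cleaning)
  out
}

#' Extract ROI-mean time series from a 4D image
#'
#' Convenience analog of atlas-based ROI extraction: for every requested
#' label, averages the 4D BOLD series over the voxels carrying that label in
#' the (grid-aligned) integer label volume.
#'
#' @param image_4d 4D numeric array or NIfTI file path (x, y, z, t).
#' @param labels 3D integer array or NIfTI file path on the same grid.
#' @param label_map Named integer vector: `c("Region-Name" = id, ...)`;
#'   output columns follow this order.
#' @return t x m matrix, columns named by `label_map`.
#' @export
extract_roi_timeseries <- function(image_4d, labels, label_map) {
  if (is.character(image_4d) || is.character(labels)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      ppn_config_error("RNifti is required to read NIfTI files")
    if (is.character(image_4d)) image_4d <- RNifti::readNifti(image_4d)
    if (is.character(labels)) labels <- RNifti::readNifti(labels)
  }
  image_4d <- unclass(image_4d); labels <- unclass(labels)
  dims <- dim(image_4d)
  if (length(dims) != 4L) ppn_data_error("image_4d must be 4-dimensional")
  if (!identical(as.integer(dim(labels)), as.integer(dims[1:3])))
    ppn_data_error("label volume grid does not match the 4D image")
  present <- unique(as.vector(labels))
  missing <- setdiff(label_map, present)
  if (length(missing))
    ppn_data_error(paste0("label id(s) absent from the label volume: ",
                          paste(missing, collapse = ", ")))
  t_n <- dims[4]
  vol <- matrix(image_4d, prod(dims[1:3]), t_n)
  lab_vec <- as.vector(labels)
  out <- vapply(label_map, function(id) {
    colMeans(vol[lab_vec == id, , drop = FALSE])
  }, numeric(t_n))
  colnames(out) <- names(label_map)
  out
}
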