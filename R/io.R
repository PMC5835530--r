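# TSV/CSV/JSON I/O.  Dialect: tab-separated, header row of column labels,
# UTF-8, '.' decimal, numbers written with full precision (%.10g) so that
# repeated runs are byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  labs <- colnames(m, do.NULL = FALSE, prefix = "V")
  body <- apply(m, 1L, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(c(paste(labs, collapse = "\t"), body), path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  as.matrix(df)
}

write_table_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a synthetic cohort to disk
#'
#' Writes, per subject and condition, TSV matrices for the ROI panel, both
#' seed-voxel blocks and the confounds; a cohort covariates CSV; and a JSON
#' ground-truth manifest (coupled sets, population partial-correlation
#' targets, severity multipliers, seeds).
#'
#' @param cohort A `ppn_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$subjects)) {
    subj <- cohort$subjects[[sid]]
    for (cond in names(subj$conditions)) {
      block <- subj$conditions[[cond]]
      for (what in c("roi_panel", "seed_left", "seed_right", "confounds")) {
        if (ncol(as.matrix(block[[what]])) == 0L) next  # nothing to record
        write_matrix_tsv(block[[what]],
                         file.path(dir, sprintf("%s_%s_%s.tsv", sid, cond,
                                                what)))
      }
    }
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    spec = cohort$spec[setdiff(names(cohort$spec), "roi_labels")],
    roi_labels = cohort$spec$roi_labels,
    truth = list(
      coupled_rois = cohort$truth$coupled_rois,
      union_rois = cohort$truth$union_rois,
      partial_r_targets = cohort$truth$partial_r_targets,
      multipliers = cohort$truth$multipliers,
      total_coupling = cohort$truth$total_coupling,
      subject_seeds = cohort$truth$subject_seeds,
      rng_seed = cohort$truth$rng_seed
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the per-subject TSV matrices,
#'   `covariates.csv` and `ground_truth.json`.
#' @return A `ppn_cohort` (without latent ground-truth time courses).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "ground_truth.json")
  if (!file.exists(mpath)) ppn_data_error(paste("missing", mpath))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cov_df <- utils::read.csv(file.path(dir, "covariates.csv"),
                            stringsAsFactors = FALSE)
  subjects <- lapply(cov_df$subject_id, function(sid) {
    conds <- lapply(c(rest = "rest", noisy = "noisy",
                      sinusoidal = "sinusoidal"), function(cond) {
      read_block <- function(what, optional = FALSE, n_time = 0L) {
        path <- file.path(dir, sprintf("%s_%s_%s.tsv", sid, cond, what))
        if (!file.exists(path)) {
          if (optional) return(matrix(0, n_time, 0L))
          ppn_data_error(paste("missing", path))
        }
        read_matrix_tsv(path)
      }
      roi <- read_block("roi_panel")
      list(roi_panel = roi,
           seed_left = read_block("seed_left"),
           seed_right = read_block("seed_right"),
           confounds = read_block("confounds", optional = TRUE,
                                  n_time = nrow(roi)))
    })
    structure(list(subject_id = sid, group = "pd", conditions = conds,
                   covariates = as.list(cov_df[cov_df$subject_id == sid,
                                               -1, drop = FALSE]),
                   truth = NULL),
              class = "subject_dataset")
  })
  names(subjects) <- cov_df$subject_id
  spec <- manifest$spec
  spec$roi_labels <- manifest$roi_labels
  spec$passband <- as.numeric(spec$passband)
  class(spec) <- "cohort_spec"
  structure(list(subjects = subjects, covariates = cov_df,
                 truth = manifest$truth, spec = spec),
            class = "ppn_cohort")
}
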