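#' SHAP-ranked incremental feature selection
#'
#' Retrains the model under cross-validation on nested feature sets of
#' increasing size: the first step is a fixed clinical/APOE baseline set,
#' and each later step adds the next features from an importance ranking
#' (typically [mean_abs_importance()] of a full-data attribution) until
#' the step's total feature count is reached. The same fold assignment is
#' reused at every step so differences isolate the feature-set effect.
#'
#' @param x A [cohort].
#' @param ranking Character vector of features in descending importance
#'   (a `mean_abs_importance()` data frame is also accepted); must cover
#'   every non-baseline feature used.
#' @param ladder_sizes Increasing total feature counts per step; default
#'   `c(5, 10, 20, 30, 40, p)` (clipped/deduplicated to the cohort's
#'   feature count).
#' @param baseline Feature names of the fixed first step; default
#'   `c("MMSE", "APOE_E2", "APOE_E3", "APOE_E4", "SEX")`.
#' @param model_kind `"ffn"` (default) or `"linear"`.
#' @param folds A [stratified_kfold()] assignment; created from
#'   `fold_seed` when NULL.
#' @param config [ffn_config()] options applied at each step (input_dim is
#'   set per step).
#' @param fold_seed,ibs_points Passed to [cross_validate()].
#' @return Object of class `ladder_result`: data frame `steps` with one
#'   row per step `(step, n_features, mean_c_index, sd_c_index, mean_ibs,
#'   sd_ibs)` for the test split, plus `feature_sets` (list of the nested
#'   sets) and `train_steps` (same metrics on the training split).
#' @export
run_feature_ladder <- function(x, ranking,
                               ladder_sizes = NULL,
                               baseline = c("MMSE", "APOE_E2", "APOE_E3",
                                            "APOE_E4", "SEX"),
                               model_kind = c("ffn", "linear"),
                               folds = NULL, config = NULL, fold_seed = 1,
                               ibs_points = 50) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(x, "cohort"))
  if (is.data.frame(ranking)) ranking <- ranking$feature
  p <- ncol(x$features)
  if (is.null(ladder_sizes)) {
    ladder_sizes <- unique(pmin(c(5, 10, 20, 30, 40, p), p))
  }
  if (is.unsorted(ladder_sizes, strictly = TRUE)) {
    stop("ladder_sizes must be strictly increasing", call. = FALSE)
  }
  missing_base <- setdiff(baseline, x$feature_names)
  if (length(missing_base)) {
    stop(sprintf("baseline feature(s) not in cohort: %s",
                 paste(missing_base, collapse = ", ")), call. = FALSE)
  }
  if (any(ladder_sizes < length(baseline))) {
    stop("ladder sizes must be at least the baseline set size",
         call. = FALSE)
  }
  ranked_extra <- setdiff(ranking, baseline)
  unknown <- setdiff(ranked_extra, x$feature_names)
  if (length(unknown)) {
    stop(sprintf("ranking contains unknown feature(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (max(ladder_sizes) > length(baseline) + length(ranked_extra)) {
    stop("ranking does not cover enough non-baseline features for the ",
         "largest ladder step", call. = FALSE)
  }
  if (is.null(folds)) folds <- stratified_kfold(x, k = 5, seed = fold_seed)

  feature_sets <- lapply(ladder_sizes, function(sz) {
    c(baseline, utils::head(ranked_extra, sz - length(baseline)))
  })
  rows <- list(); train_rows <- list()
  for (s in seq_along(feature_sets)) {
    sub <- x[, feature_sets[[s]]]
    cv <- cross_validate(sub, model_kind = model_kind, folds = folds,
                         config = config, ibs_points = ibs_points)
    for (split in c("test", "train")) {
      d <- cv$per_fold[cv$per_fold$split == split, ]
      row <- data.frame(step = s, n_features = ladder_sizes[s],
                        mean_c_index = mean(d$c_index),
                        sd_c_index = stats::sd(d$c_index),
                        mean_ibs = mean(d$ibs), sd_ibs = stats::sd(d$ibs))
      if (split == "test") rows[[s]] <- row else train_rows[[s]] <- row
    }
  }
  structure(list(steps = do.call(rbind, rows),
                 train_steps = do.call(rbind, train_rows),
                 feature_sets = feature_sets,
                 model_kind = model_kind, folds = folds),
            class = "ladder_result")
}

#' @export
print.ladder_result <- function(x, ...) {
  cat(sprintf("<ladder_result> %s, %d steps\n", x$model_kind,
              nrow(x$steps)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Write ladder results as CSV
#'
#' Columns `(step, n_features, features_json, mean_c_index, sd_c_index,
#' mean_ibs, sd_ibs)` — the data behind performance-vs-feature-count
#' plots.
#'
#' @param ladder A `ladder_result`.
#' @param path Output path.
#' @export
write_ladder_csv <- function(ladder, path) {
  df <- ladder$steps
  df$features_json <- vapply(ladder$feature_sets, function(fs) {
    as.character(jsonlite::toJSON(fs))
  }, character(1))
  df <- df[, c("step", "n_features", "features_json", "mean_c_index",
               "sd_c_index", "mean_ibs", "sd_ibs")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
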