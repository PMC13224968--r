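#' Harrell's concordance index
#'
#' Fraction of comparable pairs ranked concordantly by the score, under the
#' convention that a larger score predicts longer survival. A pair (i, j)
#' is comparable when \eqn{t_i < t_j} and subject i had the event; it is
#' concordant when \eqn{score_i < score_j}, and score ties count 1/2.
#' Time-tied pairs are not comparable. 0.5 is chance level, 1 perfect.
#'
#' @param time,event Right-censored outcome vectors.
#' @param scores Per-subject ordering score; larger = longer predicted
#'   survival (e.g. predicted \eqn{\log\lambda} or median time — any
#'   strictly monotone transform gives the same value).
#' @return Concordance in \[0, 1\].
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 0), c(2, 1, 3))  # 2/3
#' @export
concordance_index <- function(time, event, scores) {
  n <- length(time)
  if (length(event) != n || length(scores) != n) {
    stop("time, event and scores lengths must match", call. = FALSE)
  }
  # comparable: t_i < t_j and event_i = 1
  comp <- outer(time, time, "<") & (event == 1)
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs", call. = FALSE)
  sc <- outer(scores, scores, "<")
  tie <- outer(scores, scores, "==")
  (sum(sc & comp) + 0.5 * sum(tie & comp)) / n_comp
}

#' Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimator of \eqn{G(t) = P(C > t)} where C is the
#' censoring time — i.e. a Kaplan-Meier fit in which censorings are the
#' "events". Needed for inverse-probability-of-censoring weighting (IPCW)
#' in the Brier score. Delegates the product-limit computation to
#' [survival::survfit()].
#'
#' @param time,event Right-censored outcome vectors (`event` is the event
#'   indicator of the analysis, not of the censoring process).
#' @return An object of class `censoring_km` with step-function evaluators.
#' @export
km_censoring_survival <- function(time, event) {
  if (length(time) == 0) stop("at least one subject required", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "censoring_km")
}

#' Evaluate a censoring survival curve
#'
#' @param G A `censoring_km` object.
#' @param t Evaluation times.
#' @param left If `TRUE`, evaluate the left limit \eqn{G(t^-)} (the IPCW
#'   convention for subjects observed to fail at `t`).
#' @return `G(t)` (right-continuous step function, `G(0) = 1`).
#' @export
eval_censoring_km <- function(G, t, left = FALSE) {
  stopifnot(inherits(G, "censoring_km"))
  vapply(t, function(ti) {
    if (left) idx <- which(G$time < ti) else idx <- which(G$time <= ti)
    if (!length(idx)) 1 else G$surv[max(idx)]
  }, numeric(1))
}

#' IPCW Brier score at a time point
#'
#' Graf's inverse-probability-of-censoring-weighted estimator of the
#' expected squared error of predicted survival probabilities at `t_star`:
#' subjects observed to fail by `t_star` contribute
#' \eqn{(0 - \hat S)^2 / G(t_i^-)}, subjects still at risk contribute
#' \eqn{(1 - \hat S)^2 / G(t^*)}, and subjects censored before `t_star`
#' contribute 0. The mean is over all subjects.
#'
#' @param t_star Evaluation time.
#' @param time,event Outcome vectors.
#' @param surv_hat Predicted \eqn{\hat S(t^*)} per subject, in \[0, 1\].
#' @param G Optional precomputed [km_censoring_survival()] curve.
#' @return Non-negative Brier score.
#' @examples
#' brier_score(2, c(1, 3), c(1, 1), c(0.5, 0.5))  # 0.25
#' @export
brier_score <- function(t_star, time, event, surv_hat, G = NULL) {
  if (any(surv_hat < 0 | surv_hat > 1)) {
    stop("predicted survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(G)) G <- km_censoring_survival(time, event)
  dead <- time <= t_star & event == 1
  alive <- time > t_star
  contrib <- numeric(length(time))
  if (any(dead)) {
    g <- eval_censoring_km(G, time[dead], left = TRUE)
    if (any(g <= 0)) {
      stop("censoring survival G(t-) is zero for an observed event; ",
           "use a smaller t_star", call. = FALSE)
    }
    contrib[dead] <- (0 - surv_hat[dead])^2 / g
  }
  if (any(alive)) {
    g <- eval_censoring_km(G, t_star)
    if (g <= 0) {
      stop("censoring survival G(t_star) is zero; use a smaller t_star",
           call. = FALSE)
    }
    contrib[alive] <- (1 - surv_hat[alive])^2 / g
  }
  mean(contrib)
}

#' Integrated Brier score over a time grid
#'
#' Trapezoidal integral of the IPCW Brier score over `time_grid`, divided
#' by the grid span, so a constant Brier score `b` integrates to `b`.
#'
#' @param time,event Outcome vectors.
#' @param surv_matrix Predicted survival probabilities, subjects x grid
#'   points.
#' @param time_grid Increasing evaluation times (at least 2).
#' @return The integrated Brier score (lower = better calibrated).
#' @export
integrated_brier_score <- function(time, event, surv_matrix, time_grid) {
  if (length(time_grid) < 2) {
    stop("time_grid needs at least two points", call. = FALSE)
  }
  surv_matrix <- as.matrix(surv_matrix)
  if (nrow(surv_matrix) != length(time) ||
      ncol(surv_matrix) != length(time_grid)) {
    stop("surv_matrix must be subjects x grid points", call. = FALSE)
  }
  G <- km_censoring_survival(time, event)
  bs <- vapply(seq_along(time_grid), function(j) {
    brier_score(time_grid[j], time, event, surv_matrix[, j], G = G)
  }, numeric(1))
  span <- time_grid[length(time_grid)] - time_grid[1]
  sum(diff(time_grid) * (bs[-1] + bs[-length(bs)]) / 2) / span
}

#' Default IBS evaluation grid
#'
#' Equally spaced points between the 5th and 95th percentile of the
#' observed times on the evaluation set.
#'
#' @param time Observed times.
#' @param n_points Grid resolution, default 100.
#' @export
ibs_time_grid <- function(time, n_points = 100) {
  q <- stats::quantile(time, c(0.05, 0.95), names = FALSE)
  if (q[1] >= q[2]) q <- range(time)
  seq(q[1], q[2], length.out = n_points)
}

#' Weibull survival curves for fitted models
#'
#' @param model A fitted `linear_aft` or `ffn_aft`.
#' @param x Feature matrix or [cohort].
#' @param time_grid Evaluation times.
#' @return Matrix subjects x grid of \eqn{\hat S(t)}.
#' @export
predict_survival_matrix <- function(model, x, time_grid) {
  ls <- predict_log_scale(model, x)
  shape <- if (inherits(model, "ffn_aft")) exp(model$log_shape) else model$shape
  lam <- exp(ls)
  outer(lam, time_grid, function(l, t) exp(-(t / l)^shape))
}

#' Cross-validated evaluation of an AFT model
#'
#' Trains and evaluates a model on each fold of an event-stratified
#' k-fold assignment, reporting Harrell's C-index (ranking by predicted
#' \eqn{\log\lambda}) and the IPCW integrated Brier score on both splits.
#'
#' @param x A [cohort].
#' @param model_kind `"linear"` or `"ffn"`.
#' @param folds A [stratified_kfold()] assignment (created with
#'   `fold_seed` when omitted).
#' @param config [ffn_config()] options for the FFN (its `seed` is re-derived
#'   per fold); `l2` ridge for the linear model.
#' @param fold_seed Seed used when `folds` is NULL.
#' @param ibs_points IBS grid resolution.
#' @param l2 Ridge penalty for the linear model.
#' @return A list of class `cv_result`: `per_fold` (data frame with one row
#'   per fold and split), `summary` (mean/sd per split), `model_kind`,
#'   `folds`.
#' @export
cross_validate <- function(x, model_kind = c("ffn", "linear"), folds = NULL,
                           config = NULL, fold_seed = 1, ibs_points = 50,
                           l2 = 0) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(x, "cohort"))
  if (is.null(folds)) folds <- stratified_kfold(x, k = 5, seed = fold_seed)
  stopifnot(inherits(folds, "fold_assignment"))
  rows <- list()
  for (f in 0:(folds$k - 1L)) {
    test_idx <- which(folds$fold == f)
    train_idx <- which(folds$fold != f)
    if (sum(x$event[train_idx]) < 1 || sum(x$event[test_idx]) < 1) {
      stop(sprintf("fold %d has a split without events", f), call. = FALSE)
    }
    tr <- x[train_idx, ]
    te <- x[test_idx, ]
    model <- fit_fold_model(tr, model_kind, config,
                            seed_label = sprintf("fold%d", f), l2 = l2)
    for (split in c("train", "test")) {
      co <- if (split == "train") tr else te
      ls <- predict_log_scale(model, co)
      grid <- ibs_time_grid(co$time, ibs_points)
      sm <- predict_survival_matrix(model, co, grid)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, split = split, model = model_kind,
        c_index = concordance_index(co$time, co$event, ls),
        ibs = integrated_brier_score(co$time, co$event, sm, grid),
        shape = if (inherits(model, "ffn_aft")) exp(model$log_shape)
                else model$shape)
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$split),
    function(d) data.frame(split = d$split[1], model = model_kind,
                           mean_c_index = mean(d$c_index),
                           sd_c_index = stats::sd(d$c_index),
                           mean_ibs = mean(d$ibs),
                           sd_ibs = stats::sd(d$ibs))))
  rownames(summary) <- NULL
  structure(list(per_fold = per_fold, summary = summary,
                 model_kind = model_kind, folds = folds),
            class = "cv_result")
}

fit_fold_model <- function(train, model_kind, config, seed_label, l2 = 0) {
  if (model_kind == "linear") {
    fit_linear_aft(train, l2 = l2)
  } else {
    if (is.null(config)) {
      config <- ffn_config(input_dim = ncol(train$features))
    }
    config$input_dim <- ncol(train$features)
    config$seed <- derive_seed(config$seed, seed_label)
    fit_ffn_aft(train, config = config)
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds\n", x$model_kind, x$folds$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write cross-validation results as CSV tables
#'
#' Emits a per-fold table `(fold, split, model, c_index, ibs)` with
#' appended `Mean`/`Std` rows, plus a separate summary CSV.
#'
#' @param results One `cv_result` or a list of them (e.g. FFN and linear).
#' @param path Per-fold output CSV path.
#' @param summary_path Optional summary CSV path.
#' @export
write_cv_csv <- function(results, path, summary_path = NULL) {
  if (inherits(results, "cv_result")) results <- list(results)
  per <- do.call(rbind, lapply(results, `[[`, "per_fold"))
  tails <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(split(r$per_fold, r$per_fold$split), function(d) {
      data.frame(fold = c("Mean", "Std"), split = d$split[1],
                 model = r$model_kind,
                 c_index = c(mean(d$c_index), stats::sd(d$c_index)),
                 ibs = c(mean(d$ibs), stats::sd(d$ibs)),
                 shape = NA)
    }))
  }))
  per$fold <- as.character(per$fold)
  utils::write.csv(rbind(per, tails), path, row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.csv(do.call(rbind, lapply(results, `[[`, "summary")),
                     summary_path, row.names = FALSE)
  }
  invisible(path)
}
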