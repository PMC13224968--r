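#' Exact interventional Shapley values for one instance
#'
#' Exact Shapley attribution of `model_fn`'s output at `instance`, under
#' the interventional value function
#' \eqn{v(S) = \mathrm{mean}_b\, f(x_S, b_{\setminus S})}: features in the
#' coalition S take the instance's values, the rest are filled from each
#' background row and the model output averaged. All \eqn{2^p} coalitions
#' are enumerated, so `p` is capped (default 15); use [shapley_sampled()]
#' beyond that.
#'
#' Additivity holds to numerical precision:
#' `base_value + sum(phi) == model_fn(instance)`.
#'
#' @param model_fn Function mapping a numeric matrix (rows = inputs) to a
#'   numeric vector of outputs.
#' @param instance Single feature vector.
#' @param background Matrix of background rows (the reference
#'   distribution).
#' @param max_features Enumeration cap, default 15.
#' @return List with `phi` (per-feature contributions) and `base_value`
#'   (`v(empty) =` mean model output over the background).
#' @export
shapley_exact <- function(model_fn, instance, background, max_features = 15) {
  background <- as.matrix(background)
  p <- length(instance)
  if (ncol(background) != p) {
    stop("background and instance dimensions differ", call. = FALSE)
  }
  if (p > max_features) {
    stop(sprintf(
      "exact enumeration capped at %d features (got %d); use shapley_sampled()",
      max_features, p), call. = FALSE)
  }
  m <- nrow(background)
  n_sub <- bitwShiftL(1L, p)
  # v(S) for every coalition, batched over the background
  v <- numeric(n_sub)
  for (s in 0:(n_sub - 1L)) {
    z <- background
    for (j in seq_len(p)) {
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L) z[, j] <- instance[j]
    }
    v[s + 1L] <- mean(model_fn(z))
  }
  # phi_j = sum over S not containing j of w(|S|) (v(S+j) - v(S))
  sizes <- vapply(0:(n_sub - 1L), function(s) sum(bitwAnd(
    s, bitwShiftL(1L, 0:(p - 1L))) != 0L), numeric(1))
  w <- factorial(0:(p - 1L)) * factorial(p - 1L - 0:(p - 1L)) / factorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_sub - 1L), bit) == 0L)
    phi[j] <- sum(w[sizes[without] + 1L] *
                    (v[without + bit] - v[without]))
  }
  names(phi) <- colnames(background)
  list(phi = phi, base_value = v[1L])
}

#' Permutation-sampling Shapley values for one instance
#'
#' Unbiased Monte-Carlo estimator of the interventional Shapley values of
#' [shapley_exact()]: for each sampled feature permutation, features are
#' switched from background to instance values in permutation order and
#' the successive output changes recorded as marginal contributions.
#' Because each permutation's contributions telescope from the base value
#' to `model_fn(instance)`, additivity holds exactly for any number of
#' permutations.
#'
#' @inheritParams shapley_exact
#' @param n_permutations Number of sampled permutations (default 200).
#' @param seed RNG seed (reproducible output).
#' @return List with `phi`, `base_value`, and `mc_stderr` (per-feature
#'   Monte-Carlo standard error from the across-permutation variance).
#' @export
shapley_sampled <- function(model_fn, instance, background,
                            n_permutations = 200, seed = 1) {
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("empty background", call. = FALSE)
  p <- length(instance)
  if (ncol(background) != p) {
    stop("background and instance dimensions differ", call. = FALSE)
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  contrib <- matrix(0, nrow = n_permutations, ncol = p)
  base <- mean(model_fn(background))
  with_seed(seed, {
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(p)
      z <- background
      prev <- base
      for (j in perm) {
        z[, j] <- instance[j]
        cur <- mean(model_fn(z))
        contrib[r, j] <- cur - prev
        prev <- cur
      }
    }
  })
  phi <- colMeans(contrib)
  se <- if (n_permutations > 1) {
    apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  } else {
    rep(NA_real_, p)
  }
  names(phi) <- colnames(background)
  list(phi = phi, base_value = base, mc_stderr = se)
}

#' Shapley attribution of a fitted model over a cohort
#'
#' Computes per-subject, per-feature Shapley values of the model's
#' predicted \eqn{\log\lambda} (larger = later predicted onset, so a
#' positive value means the feature pushed the prediction toward lower
#' risk). Uses exact enumeration when the feature count is small and
#' permutation sampling otherwise, with a training-data background
#' subsample as the reference distribution. Permutations are shared across
#' subjects, which lets each (permutation, coalition) model call be
#' batched over every explained subject.
#'
#' @param model A fitted `linear_aft` or `ffn_aft`, or any function
#'   mapping a feature matrix to a numeric vector.
#' @param x [cohort] or feature matrix of subjects to explain.
#' @param background Background matrix; default: up to `background_size`
#'   rows subsampled from `x` itself.
#' @param method `"auto"` (exact only for small feature counts,
#'   `p <= auto_exact_max`; permutation sampling otherwise), `"exact"`, or
#'   `"sampled"`.
#' @param n_permutations Permutations for the sampled estimator.
#' @param background_size Background subsample cap, default 100.
#' @param exact_cap Hard feature-count cap for exact enumeration.
#' @param auto_exact_max Largest feature count for which `"auto"` picks the
#'   exact method; beyond it sampling is used (enumeration over a whole
#'   cohort grows as \eqn{2^p} model calls per subject).
#' @param seed RNG seed for background subsampling and permutations.
#' @return Object of class `attribution`: `phi` (subjects x features),
#'   `base_value`, `feature_names`, `subject_ids`, `mc_stderr` (NULL for
#'   exact), `n_permutations`, `seed`.
#' @export
explain_model <- function(model, x, background = NULL,
                          method = c("auto", "exact", "sampled"),
                          n_permutations = 200, background_size = 100,
                          exact_cap = 15, auto_exact_max = 8, seed = 1) {
  method <- match.arg(method)
  feats <- if (inherits(x, "cohort")) x$features else as.matrix(x)
  ids <- if (inherits(x, "cohort")) x$subject_ids else rownames(feats)
  model_fn <- as_model_fn(model, colnames(feats))
  if (is.null(background)) {
    if (nrow(feats) > background_size) {
      idx <- with_seed(derive_seed(seed, "background"),
                       sample.int(nrow(feats), background_size))
      background <- feats[idx, , drop = FALSE]
    } else {
      background <- feats
    }
  }
  background <- as.matrix(background)
  p <- ncol(feats)
  if (method == "auto") method <- if (p <= auto_exact_max) "exact" else "sampled"
  n <- nrow(feats)
  phi <- matrix(0, n, p, dimnames = list(ids, colnames(feats)))
  se <- NULL
  if (method == "exact") {
    base <- NA_real_
    for (i in seq_len(n)) {
      res <- shapley_exact(model_fn, feats[i, ], background,
                           max_features = exact_cap)
      phi[i, ] <- res$phi
      base <- res$base_value
    }
  } else {
    res <- shapley_sampled_batch(model_fn, feats, background,
                                 n_permutations, seed)
    phi[, ] <- res$phi
    se <- res$mc_stderr
    base <- res$base_value
  }
  structure(list(phi = phi, base_value = base,
                 feature_names = colnames(feats), subject_ids = ids,
                 mc_stderr = se,
                 n_permutations = if (method == "sampled") n_permutations
                                  else NA_integer_,
                 method = method, seed = seed),
            class = "attribution")
}

# Vectorized permutation sampler: one model call per (permutation, step)
# covers all subjects x background rows at once.
shapley_sampled_batch <- function(model_fn, instances, background,
                                  n_permutations, seed) {
  n <- nrow(instances); p <- ncol(instances); m <- nrow(background)
  bg_big <- background[rep(seq_len(m), times = n), , drop = FALSE]
  row_of <- rep(seq_len(n), each = m)
  base_row <- mean(model_fn(background))
  contrib <- array(0, dim = c(n_permutations, n, p))
  with_seed(seed, {
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(p)
      z <- bg_big
      prev <- rep(base_row, n)
      for (j in perm) {
        z[, j] <- instances[row_of, j]
        cur <- drop(rowsum(model_fn(z), row_of)) / m
        contrib[r, , j] <- cur - prev
        prev <- cur
      }
    }
  })
  phi <- apply(contrib, c(2, 3), mean)
  se <- if (n_permutations > 1) {
    apply(contrib, c(2, 3), stats::sd) / sqrt(n_permutations)
  } else NULL
  list(phi = phi, base_value = base_row, mc_stderr = se)
}

as_model_fn <- function(model, feature_names) {
  if (is.function(model)) return(model)
  function(z) {
    if (is.null(colnames(z))) colnames(z) <- feature_names
    predict_log_scale(model, z)
  }
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution> %d subjects x %d features (%s), base value %.4f\n",
              nrow(x$phi), ncol(x$phi), x$method, x$base_value))
  invisible(x)
}

#' Rank features by mean absolute Shapley value
#'
#' @param attribution An [explain_model()] result.
#' @return Data frame `(rank, feature, mean_abs_shap)` in descending
#'   importance; ties broken alphabetically by feature name.
#' @export
mean_abs_importance <- function(attribution) {
  stopifnot(inherits(attribution, "attribution"))
  if (nrow(attribution$phi) == 0) stop("empty attribution", call. = FALSE)
  imp <- colMeans(abs(attribution$phi))
  ord <- order(-imp, attribution$feature_names)
  data.frame(rank = seq_along(ord),
             feature = attribution$feature_names[ord],
             mean_abs_shap = unname(imp[ord]))
}

#' Long-format table behind a SHAP beeswarm plot
#'
#' One row per subject and top-ranked feature, pairing each Shapley value
#' with the subject's observed feature value — the data behind the usual
#' beeswarm summary plot.
#'
#' @param attribution An [explain_model()] result.
#' @param x The [cohort] (or feature matrix) that was explained.
#' @param top_k Number of top features to keep (by mean |SHAP|), default 20.
#' @return Data frame `(subject, feature, feature_value, shap_value)`.
#' @export
beeswarm_table <- function(attribution, x, top_k = 20) {
  feats <- if (inherits(x, "cohort")) x$features else as.matrix(x)
  stopifnot(identical(dim(feats), dim(attribution$phi)))
  keep <- utils::head(mean_abs_importance(attribution)$feature, top_k)
  do.call(rbind, lapply(keep, function(f) {
    data.frame(subject = attribution$subject_ids %||%
                 seq_len(nrow(feats)),
               feature = f,
               feature_value = feats[, f],
               shap_value = attribution$phi[, f],
               row.names = NULL)
  }))
}

#' Data behind a SHAP dependence plot
#'
#' Per-subject rows pairing one feature's values and Shapley values with a
#' second (interaction candidate) feature's values, for plotting
#' \eqn{\phi_j} against \eqn{x_j} colored by the partner feature.
#'
#' @param attribution An [explain_model()] result.
#' @param x The explained [cohort] or feature matrix.
#' @param feature Feature whose attribution is examined.
#' @param interaction_feature Candidate interacting feature.
#' @return Data frame `(feature_value, shap_value, interaction_value)`.
#' @export
dependence_table <- function(attribution, x, feature, interaction_feature) {
  feats <- if (inherits(x, "cohort")) x$features else as.matrix(x)
  for (f in c(feature, interaction_feature)) {
    if (!f %in% colnames(feats)) {
      stop(sprintf("unknown feature '%s'", f), call. = FALSE)
    }
  }
  data.frame(feature_value = feats[, feature],
             shap_value = attribution$phi[, feature],
             interaction_value = feats[, interaction_feature],
             row.names = NULL)
}

#' Linear-baseline feature importance
#'
#' Importance of each feature in the linear Weibull AFT baseline as the
#' absolute fitted coefficient on standardized features (so binary and
#' continuous features are on a comparable scale).
#'
#' @param x A [cohort].
#' @param l2 Optional ridge penalty passed to the fit.
#' @return Data frame `(rank, feature, abs_coef)` in descending order.
#' @export
linear_importance <- function(x, l2 = 0) {
  stopifnot(inherits(x, "cohort"))
  feats <- x$features
  scl <- apply(feats, 2, stats::sd)
  scl[scl == 0] <- 1
  fs <- sweep(sweep(feats, 2, colMeans(feats), "-"), 2, scl, "/")
  fit <- fit_linear_aft(fs, x$time, x$event, l2 = l2)
  imp <- abs(fit$coefficients)
  ord <- order(-imp, names(imp))
  data.frame(rank = seq_along(ord), feature = names(imp)[ord],
             abs_coef = unname(imp[ord]))
}
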