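#' Configure the feedforward scale network
#'
#' The network maps a subject's feature vector to \eqn{\log\lambda_i}: an
#' input layer, hidden layers with SoftPlus activation (two by default),
#' and a single linear output node. Together with one shared log-shape
#' parameter this defines the neural Weibull AFT model; everything — layer
#' weights and the shape — is trained jointly by gradient descent on the
#' censored negative log-likelihood.
#'
#' @param input_dim Number of input features.
#' @param hidden_dims Integer vector of hidden-layer widths; default
#'   `c(24, 24)`. `integer(0)` gives a degenerate linear network.
#' @param epochs Number of full-batch passes, default 1000 (the training
#'   negative log-likelihood plateaus well before this on cohorts of a few
#'   thousand subjects; shorten for quick linear-signal fits).
#' @param learning_rate Step size, default 1e-2 (Adam).
#' @param optimizer `"adam"` (default) or `"gd"` (plain gradient descent,
#'   useful when a monotone loss trace is wanted).
#' @param l2_penalty Ridge penalty on the weights (not biases or shape).
#' @param validation_split Fraction of training rows held out for early
#'   stopping; 0 (default) disables early stopping.
#' @param patience Early-stopping patience in epochs (used only when
#'   `validation_split > 0`).
#' @param seed Weight-initialization / split seed.
#' @return A list of class `ffn_config`.
#' @export
ffn_config <- function(input_dim, hidden_dims = c(24, 24), epochs = 1000,
                       learning_rate = 1e-2, optimizer = c("adam", "gd"),
                       l2_penalty = 0, validation_split = 0, patience = 50,
                       seed = 1) {
  optimizer <- match.arg(optimizer)
  if (input_dim < 1) stop("input_dim must be >= 1", call. = FALSE)
  if (length(hidden_dims) && any(hidden_dims < 1)) {
    stop("hidden layer widths must be >= 1", call. = FALSE)
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 activation = "softplus",
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 l2_penalty = l2_penalty,
                 validation_split = validation_split,
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "ffn_config")
}

#' Initialize an untrained network
#'
#' Glorot-uniform weights, zero biases, and the shared shape started at
#' `k = 1` (`log k = 0`). Deterministic given the config seed.
#'
#' @param config An [ffn_config].
#' @param seed Optional override of `config$seed`.
#' @return An object of class `ffn_aft` (untrained: empty training trace).
#' @export
init_ffn <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ffn_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dims <- c(config$input_dim, config$hidden_dims, 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  with_seed(config$seed, {
    for (l in seq_along(W)) {
      fan_in <- dims[l]; fan_out <- dims[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                       nrow = fan_in, ncol = fan_out)
      b[[l]] <- numeric(fan_out)
    }
  })
  structure(list(W = W, b = b, log_shape = 0, config = config,
                 feature_names = NULL, trace = numeric(0),
                 center = NULL, scale = NULL),
            class = "ffn_aft")
}

#' @export
print.ffn_aft <- function(x, ...) {
  cat(sprintf("<ffn_aft> %d -> %s -> 1 (softplus), k = %.4f, %d parameters%s\n",
              x$config$input_dim,
              if (length(x$config$hidden_dims))
                paste(x$config$hidden_dims, collapse = " -> ") else "(linear)",
              exp(x$log_shape), count_parameters(x),
              if (length(x$trace))
                sprintf(", final NLL = %.4f", x$trace[length(x$trace)])
              else " (untrained)"))
  invisible(x)
}

#' Count learnable parameters
#'
#' Sum over layers of `(fan_in + 1) * fan_out` plus one for the shared
#' shape. For the default 55-input, (24, 24)-hidden architecture this is
#' 1970.
#'
#' @param model An `ffn_aft` model.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ffn_aft"))
  sum(vapply(seq_along(model$W),
             function(l) length(model$W[[l]]) + length(model$b[[l]]),
             numeric(1))) + 1L
}

# Forward pass returning all layer activations (needed by backprop).
ffn_forward_full <- function(model, x) {
  a <- x
  pre <- vector("list", length(model$W))
  act <- vector("list", length(model$W))
  nh <- length(model$W) - 1L
  for (l in seq_len(nh)) {
    pre[[l]] <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- softplus(pre[[l]])
    act[[l]] <- a
  }
  out <- drop(sweep(a %*% model$W[[nh + 1L]], 2, model$b[[nh + 1L]], "+"))
  list(out = out, pre = pre, act = act)
}

#' @rdname predict_log_scale
#' @export
predict_log_scale.ffn_aft <- function(model, x) {
  x <- check_feature_matrix(x, model$feature_names %||%
                              paste0("x", seq_len(model$config$input_dim)))
  if (ncol(x) != model$config$input_dim) {
    stop("feature dimension does not match the network input layer",
         call. = FALSE)
  }
  if (!is.null(model$center)) {
    x <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  }
  ffn_forward_full(model, x)$out
}

# Backpropagate d NLL / d output (vector delta over subjects) into
# gradients for every weight, bias, and accumulate nothing for shape
# (handled by the caller). Adds the L2 penalty gradient on weights.
ffn_backward <- function(model, x, fwd, delta, l2 = 0) {
  L <- length(model$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  d <- matrix(delta, ncol = 1)
  for (l in seq(L, 1)) {
    a_prev <- if (l == 1L) x else fwd$act[[l - 1L]]
    gW[[l]] <- crossprod(a_prev, d) + 2 * l2 * model$W[[l]]
    gb[[l]] <- colSums(d)
    if (l > 1L) {
      d <- (d %*% t(model$W[[l]])) * softplus_grad(fwd$pre[[l - 1L]])
    }
  }
  list(gW = gW, gb = gb)
}

#' Fit the neural Weibull AFT model
#'
#' Jointly trains the network weights and the shared shape by full-batch
#' gradient descent (Adam by default) on the censored Weibull negative
#' log-likelihood. Continuous features (columns that are not 0/1) are
#' standardized with training-set statistics stored in the model; binary
#' indicators are left untouched.
#'
#' @param x Feature matrix or [cohort].
#' @param time,event Outcome vectors (ignored when `x` is a cohort).
#' @param config An [ffn_config]; `input_dim` is filled in from the data
#'   when missing.
#' @param ... Passed to [ffn_config()] when `config` is NULL.
#' @return A trained `ffn_aft` model with the per-epoch training NLL in
#'   `$trace` and `$shape`/`$log_shape` for the fitted shared shape. A
#'   warning is emitted when the fitted shape is not above 1 (a rising
#'   hazard is the working assumption for progressive disease onset).
#' @export
fit_ffn_aft <- function(x, time = NULL, event = NULL, config = NULL, ...) {
  if (inherits(x, "cohort")) {
    time <- x$time
    event <- x$event
    feats <- x$features
  } else {
    feats <- as.matrix(x)
  }
  if (is.null(config)) config <- ffn_config(input_dim = ncol(feats), ...)
  stopifnot(inherits(config, "ffn_config"))
  if (config$input_dim != ncol(feats)) {
    stop("config input_dim does not match the feature matrix", call. = FALSE)
  }
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  if (any(event == 1 & time == 0)) {
    stop("event at t = 0 is not allowed", call. = FALSE)
  }
  model <- init_ffn(config)
  model$feature_names <- colnames(feats)

  # standardize non-binary columns on the training data
  is_binary <- apply(feats, 2, function(v) all(v %in% c(0, 1)))
  center <- ifelse(is_binary, 0, colMeans(feats))
  scl <- ifelse(is_binary, 1, apply(feats, 2, stats::sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  model$center <- center
  model$scale <- scl
  xs <- sweep(sweep(feats, 2, center, "-"), 2, scl, "/")

  idx_val <- integer(0)
  if (config$validation_split > 0) {
    with_seed(derive_seed(config$seed, "valsplit"), {
      idx_val <- sample.int(nrow(xs), max(1, round(config$validation_split *
                                                     nrow(xs))))
    })
    if (sum(event[-idx_val]) < 1 || sum(event[idx_val]) < 1) {
      idx_val <- integer(0)  # refuse a split that empties either side
    }
  }
  idx_tr <- setdiff(seq_len(nrow(xs)), idx_val)
  xt <- xs[idx_tr, , drop = FALSE]; tt <- time[idx_tr]; et <- event[idx_tr]

  params <- c(model$W, model$b, list(model$log_shape))
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  L <- length(model$W)
  trace <- numeric(0)
  best <- list(nll = Inf, model = model, epoch = 0L)
  stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    fwd <- ffn_forward_full(model, xt)
    shape <- exp(model$log_shape)
    if (!is.finite(shape) || shape <= 0 || any(!is.finite(fwd$out))) {
      stop(sprintf("training diverged (non-finite parameters) at epoch %d; reduce the learning rate",
                   epoch), call. = FALSE)
    }
    nll <- censored_neg_log_likelihood(tt, et, shape, fwd$out)
    if (!is.finite(nll)) {
      stop(sprintf("non-finite training loss at epoch %d", epoch),
           call. = FALSE)
    }
    trace <- c(trace, nll)

    g <- weibull_nll_grad(tt, et, shape, fwd$out)
    grads_wb <- ffn_backward(model, xt, fwd, g$d_log_scale,
                             l2 = config$l2_penalty)
    grads <- c(grads_wb$gW, grads_wb$gb, list(g$d_log_shape))

    if (config$optimizer == "adam") {
      for (j in seq_along(params)) {
        adam_m[[j]] <- beta1 * adam_m[[j]] + (1 - beta1) * grads[[j]]
        adam_v[[j]] <- beta2 * adam_v[[j]] + (1 - beta2) * grads[[j]]^2
        mh <- adam_m[[j]] / (1 - beta1^epoch)
        vh <- adam_v[[j]] / (1 - beta2^epoch)
        params[[j]] <- params[[j]] - lr * mh / (sqrt(vh) + eps)
      }
    } else {
      for (j in seq_along(params)) {
        params[[j]] <- params[[j]] - lr * grads[[j]]
      }
    }
    model$W <- params[seq_len(L)]
    model$b <- params[L + seq_len(L)]
    model$log_shape <- params[[2L * L + 1L]]

    if (length(idx_val)) {
      val_out <- ffn_forward_full(model, xs[idx_val, , drop = FALSE])$out
      val_nll <- censored_neg_log_likelihood(time[idx_val], event[idx_val],
                                             exp(model$log_shape), val_out)
      if (val_nll < best$nll - 1e-10) {
        best <- list(nll = val_nll, model = model, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  if (length(idx_val) && is.finite(best$nll)) {
    best$model$trace <- trace
    model <- best$model
  } else {
    model$trace <- trace
  }
  model$shape <- exp(model$log_shape)
  if (model$shape <= 1) {
    warning(sprintf(
      "fitted shape k = %.3f is not above 1: the hazard is not rising with time",
      model$shape), call. = FALSE)
  }
  model
}

#' @export
write_model_json.ffn_aft <- function(model, path) {
  obj <- list(kind = "ffn_aft",
              layer_dims = c(model$config$input_dim,
                             model$config$hidden_dims, 1L),
              weights = lapply(model$W, function(w) as.vector(w)),
              biases = model$b,
              log_shape = model$log_shape,
              center = model$center, scale = model$scale,
              feature_names = model$feature_names,
              config = unclass(model$config),
              trace = model$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
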