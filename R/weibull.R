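#' Weibull log-survival function
#'
#' Log survival probability under the scale-form Weibull distribution
#' \eqn{S(t) = \exp(-(t/\lambda)^k)}, the parameterization used throughout
#' this package: `k` is the shape (shared across subjects in the AFT models)
#' and `lambda` the per-subject scale, with larger \eqn{\lambda} meaning
#' later predicted onset.
#'
#' @param t Non-negative time(s).
#' @param shape Shape parameter \eqn{k > 0}.
#' @param scale Scale parameter \eqn{\lambda > 0}; recycled against `t`.
#' @return `log S(t) = -(t/lambda)^k`, elementwise. Zero at `t = 0`.
#' @examples
#' weibull_log_survival(1, shape = 1, scale = 1)   # -1
#' weibull_log_survival(2, shape = 2, scale = 1)   # -4
#' @export
weibull_log_survival <- function(t, shape, scale) {
  check_weibull_args(t, shape, scale, allow_zero_t = TRUE)
  -(t / scale)^shape
}

#' Weibull log-density
#'
#' Log density of the scale-form Weibull distribution,
#' \eqn{\log f(t) = \log k - \log\lambda + (k-1)(\log t - \log\lambda) - (t/\lambda)^k}.
#' Identical to `dweibull(t, shape, scale, log = TRUE)`; written out here
#' because the censored likelihood and its gradients reuse the pieces.
#'
#' @inheritParams weibull_log_survival
#' @return Log density, elementwise. `t = 0` is rejected when `shape < 1`
#'   (the density diverges there).
#' @export
weibull_log_density <- function(t, shape, scale) {
  check_weibull_args(t, shape, scale, allow_zero_t = TRUE)
  if (any(t == 0) && any(shape < 1)) {
    stop("log-density at t = 0 is undefined for shape < 1", call. = FALSE)
  }
  if (any(t == 0)) {
    stop("log-density requires t > 0", call. = FALSE)
  }
  log(shape) - log(scale) + (shape - 1) * (log(t) - log(scale)) -
    (t / scale)^shape
}

#' Weibull log-hazard
#'
#' @inheritParams weibull_log_survival
#' @return `log h(t)` with `h(t) = (k/lambda) (t/lambda)^{k-1}`.
#' @export
weibull_log_hazard <- function(t, shape, scale) {
  check_weibull_args(t, shape, scale, allow_zero_t = FALSE)
  log(shape) - log(scale) + (shape - 1) * (log(t) - log(scale))
}

#' Median event time of a Weibull distribution
#'
#' A strictly monotone transform of the scale at fixed shape,
#' \eqn{\lambda (\log 2)^{1/k}}; useful for reporting predictions on the
#' time scale (ranking by median time is equivalent to ranking by
#' \eqn{\log\lambda}).
#'
#' @inheritParams weibull_log_survival
#' @export
predict_median_time <- function(shape, scale) {
  check_weibull_args(1, shape, scale, allow_zero_t = FALSE)
  scale * log(2)^(1 / shape)
}

check_weibull_args <- function(t, shape, scale, allow_zero_t = TRUE) {
  if (!is.numeric(t) || !is.numeric(shape) || !is.numeric(scale)) {
    stop("t, shape and scale must be numeric", call. = FALSE)
  }
  if (any(!is.finite(shape)) || any(shape <= 0)) {
    stop("shape must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop("scale must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be non-negative and finite", call. = FALSE)
  }
  if (!allow_zero_t && any(t == 0)) {
    stop("t must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Censored Weibull negative log-likelihood
#'
#' Right-censored negative log-likelihood for a shared-shape Weibull AFT
#' model with one scale per subject:
#' \deqn{-\sum_i [\,\delta_i \log f(t_i) + (1-\delta_i) \log S(t_i)\,]}
#' where \eqn{\delta_i} is the event indicator. This is the training loss
#' of both the linear and the neural-network scale models.
#'
#' Censored observations at `t = 0` contribute nothing (\eqn{\log S(0)=0});
#' events at `t = 0` are rejected.
#'
#' @param time Non-negative observed times.
#' @param event Event indicators in \{0, 1\} (1 = event observed).
#' @param shape Shared shape parameter \eqn{k > 0}.
#' @param log_scale Per-subject \eqn{\log\lambda_i}; length must match `time`.
#' @return A single finite number (the NLL; lower is a better fit).
#' @examples
#' # two events at t = 1, 2 under k = 1, lambda = 2: 2*log(2) + 1.5
#' censored_neg_log_likelihood(c(1, 2), c(1, 1), shape = 1,
#'                             log_scale = log(c(2, 2)))
#' @export
censored_neg_log_likelihood <- function(time, event, shape, log_scale) {
  if (length(time) == 0L) stop("empty cohort", call. = FALSE)
  if (length(time) != length(event) || length(time) != length(log_scale)) {
    stop("time, event and log_scale lengths must match", call. = FALSE)
  }
  if (any(!event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (any(time < 0) || any(!is.finite(time))) {
    stop("time must be non-negative and finite", call. = FALSE)
  }
  if (any(event == 1 & time == 0)) {
    stop("event at t = 0 is not allowed (density term degenerates)",
         call. = FALSE)
  }
  stop_if_not_scalar_number(shape, "shape")
  if (shape <= 0) stop("shape must be positive", call. = FALSE)
  ll <- weibull_loglik_terms(time, event, shape, log_scale)$loglik
  -sum(ll)
}

# Shared likelihood pieces. m = log t - log lambda; u = (t/lambda)^k.
# Returns per-subject log-likelihood plus the quantities the analytic
# gradients need. Censored t = 0 handled exactly (contribution 0).
weibull_loglik_terms <- function(time, event, shape, log_scale) {
  logt <- ifelse(time > 0, log(time), 0)     # placeholder where t = 0
  m <- logt - log_scale
  u <- ifelse(time > 0, exp(shape * m), 0)
  ll <- ifelse(
    event == 1,
    log(shape) + (shape - 1) * logt - shape * log_scale - u,
    -u
  )
  list(loglik = ll, m = ifelse(time > 0, m, 0), u = u)
}

# Gradient of the NLL w.r.t. per-subject log lambda and w.r.t. log k.
# d NLL / d log lambda_i = k (delta_i - u_i)
# d NLL / d log k        = k * sum_i [ u_i m_i - delta_i (1/k + m_i) ]
weibull_nll_grad <- function(time, event, shape, log_scale) {
  pieces <- weibull_loglik_terms(time, event, shape, log_scale)
  d_log_scale <- shape * (event - pieces$u)
  d_log_shape <- shape *
    sum(pieces$u * pieces$m - event * (1 / shape + pieces$m))
  list(d_log_scale = d_log_scale, d_log_shape = d_log_shape)
}
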