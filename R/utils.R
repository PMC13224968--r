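#' @keywords internal
"_PACKAGE"

# Numerically stable softplus and its derivative (the logistic function).
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

softplus_grad <- function(x) {
  stats::plogis(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library functions do not disturb user-level streams.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a root seed and a stage label, deterministically
# and within the 32-bit integer range.  Used so one pipeline seed drives
# every stage without stream collisions.  Polynomial string hash mod a
# prime below 2^31; all intermediates stay exactly representable.
string_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

derive_seed <- function(seed, label) {
  string_hash(paste0(label, ":", seed))
}

# Content hash of a serialized object, for config provenance stamps.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", string_hash(as.character(s)))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
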