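# Shared helpers: classed errors (mapped to distinct CLI exit codes) and
# deterministic seed derivation so one user seed drives every stochastic
# stage independently.

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nestcae_config_error")
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nestcae_data_error")
}

stop_io <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nestcae_io_error")
}

stop_contract <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nestcae_contract_error")
}

stop_usage <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nestcae_usage_error")
}

#' Derive a child seed from a master seed and a stage tag
#'
#' Every stochastic stage (corpus generation, splitting, weight
#' initialization, per-epoch shuffling, ...) draws its own seed
#' deterministically from the single user-facing seed, so runs are exactly
#' reproducible while stages stay statistically decoupled.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  val <- (abs(seed) * 48271 + h * 16807) %% (2^31 - 1)
  as.integer(val %% (2^31 - 2) + 1)
}

# clamp numeric array/matrix into [0, 1]
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_range <- function(x, name, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2]) {
    stop_config("'%s' must be a nonempty range c(min, max) with min <= max", name)
  }
  if (integer && any(x != round(x))) {
    stop_config("'%s' must contain integers", name)
  }
  invisible(x)
}

sample_range <- function(range, n = 1L, integer = FALSE) {
  if (integer) {
    vals <- seq.int(range[1], range[2])
    if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
  } else {
    runif(n, range[1], range[2])
  }
}
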