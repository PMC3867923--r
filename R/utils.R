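# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based fan-out so that independent pipeline stages (phantom
#' generation, fold dealing, swarm initialisation, ...) receive independent
#' but reproducible seeds from one master seed. Results stay within the
#' 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer counter (stage or sample index).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1,
            is.numeric(index), length(index) == 1, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master_seed) %% m) + 1
  # two rounds of a Lehmer-style mix keep consecutive indices uncorrelated
  s <- (s * 48271) %% m
  s <- (s + as.double(index) * 16807) %% m
  s <- (s * 69621) %% m
  as.integer(if (s == 0) 1 else s)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_param <- function(msg, field = NULL) {
  abort(msg, class = "iomil_parameter_error", field = field)
}

stop_state <- function(msg) abort(msg, class = "iomil_state_error")

stop_io <- function(msg, path = NULL) {
  abort(msg, class = "iomil_io_error", path = path)
}

assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_param(sprintf("`%s` must be a numeric matrix of 8-bit intensities", arg))
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop_param(sprintf("`%s` must contain values in [0, 255]", arg))
  }
  invisible(img)
}

# population variance (divide by n), used for across-direction spread
pop_var <- function(x) mean((x - mean(x))^2)
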