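#' @importFrom rlang %||%
#' @importFrom stats rnorm runif quantile setNames
#' @importFrom utils head tail write.csv read.csv
NULL

sigmoid_ <- function(x) 1 / (1 + exp(-x))

logit_ <- function(p) log(p / (1 - p))

# round a channel count up to a multiple of `divisor` (width scaling rule)
make_divisible <- function(x, divisor = 8L) {
  as.integer(ceiling(x / divisor) * divisor)
}

# depth scaling rule: at least one repeat
depth_gain <- function(n, gd) max(1L, as.integer(round(n * gd)))

abort_fishdet <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fishdet_error"))
}

validate_that <- function(ok, msg, class = "fishdet_validation_error") {
  if (!isTRUE(ok)) abort_fishdet(msg, class)
  invisible(TRUE)
}

# deterministic child seed derived from a master seed (kept below 2^31)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483629)
}
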