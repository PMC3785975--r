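#' Round half away from zero
#'
#' Printed percentages and currency amounts use conventional half-up
#' rounding (0.05 -> 0.1), not the IEEE round-half-even rule of [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.05, 1)   # 0.1
#' round_half_up(216.665, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(msg) stop(errorCondition(msg,
  class = c("alcsms_invalid_input", "error")))

abort_config <- function(msg) stop(errorCondition(msg,
  class = c("alcsms_config_error", "error")))

assert_scalar_choice <- function(x, choices, what) {
  if (length(x) != 1 || is.na(x) || !x %in% choices) {
    abort_input(sprintf("%s must be one of: %s (got %s)",
      what, paste(choices, collapse = ", "),
      if (length(x) == 1) paste0("'", x, "'") else sprintf("length-%d input", length(x))))
  }
  invisible(x)
}
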