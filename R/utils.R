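# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-point rounding with halves carried away from zero (so 1.75 -> 1.8 at
#' one decimal), matching how fold changes and concentrations are conventionally
#' reported. Base `round()` rounds halves to even, which is not what printed
#' tables use.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(1.75, 1)  # 1.8, where round(1.75, 1) gives 1.8 or 1.7
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a relative epsilon so values that are exactly representable
  # halves (e.g. 2.65 stored as 2.649999...) round the way they print
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# mid-point time (hours) of the frame pair (f, f+1); dt_min in minutes
pair_time_h <- function(frame_a, dt_min) (frame_a + 0.5) * dt_min / 60

`%||%` <- function(a, b) if (is.null(a)) b else a
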