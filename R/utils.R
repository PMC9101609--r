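#' Format a fraction as a one-decimal percentage
#'
#' Overlap percentages are reported to one decimal place. Two rounding
#' conventions are supported: `half_even` (IEEE banker's rounding, R's
#' [round()]) and `truncate` (drop digits beyond the first decimal).
#' Publications are not always consistent about which convention they use, so
#' the mode is an explicit argument everywhere a percentage is printed.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param round_mode `"half_even"` (default) or `"truncate"`.
#' @return Percentage `100 * numerator / denominator` rounded to one decimal.
#' @examples
#' percent_of(128, 1445, "truncate")  # 8.8
#' percent_of(13, 181, "half_even")   # 7.2
#' @export
percent_of <- function(numerator, denominator, round_mode = c("half_even", "truncate")) {
  round_mode <- match.arg(round_mode)
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) stop("denominator must be positive")
  pct <- 100 * numerator / denominator
  if (round_mode == "half_even") {
    round(pct, 1L)
  } else {
    # small epsilon guards against 10*pct landing a hair below an integer
    # representable value (e.g. 7.2 stored as 7.1999...)
    floor(pct * 10 + 1e-9) / 10
  }
}

# internal: stop with a message naming the offending argument
.check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

# internal: derive a deterministic sub-seed for one named generator stream.
# Fixed offsets mean adding a generator never shifts another stream's draws.
.stream_seed <- function(seed, stream) {
  offsets <- c(annotation = 11L, counts = 23L, proteome = 37L,
               flux = 53L, dose = 71L, pipeline = 97L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}
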