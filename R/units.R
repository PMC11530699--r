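#' Convert between millisecond periods and hertz rates
#'
#' All temporal quantities in this package are carried in milliseconds;
#' frequencies are carried in hertz. These two helpers are the only place
#' where the factor of 1000 between the two conventions appears.
#'
#' @param period_ms Period(s) in milliseconds.
#' @param rate_hz Rate(s) in hertz.
#' @return `period_to_rate()` returns hertz; `rate_to_period()` returns
#'   milliseconds.
#' @examples
#' period_to_rate(5)    # 200 Hz
#' rate_to_period(800)  # 1.25 ms
#' @export
period_to_rate <- function(period_ms) {
  stopifnot(all(period_ms > 0))
  1000 / period_ms
}

#' @rdname period_to_rate
#' @export
rate_to_period <- function(rate_hz) {
  stopifnot(all(rate_hz > 0))
  1000 / rate_hz
}

# TRUE if x is an integer multiple of step, up to floating-point slack.
is_grid_multiple <- function(x, step, tol = 1e-9) {
  r <- x / step
  abs(r - round(r)) < tol
}
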