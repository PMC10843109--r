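#' Wind speed unit conversions
#'
#' Convert between knots, metres per second, kilometres per hour and miles per
#' hour. The 34-knot gale-force threshold used to define cyclone exposure days
#' corresponds to 17.5 m/s, 63 km/h and 39 mph.
#'
#' @param v Numeric vector of wind speeds, must be non-negative.
#' @return Numeric vector of converted speeds.
#' @examples
#' knots_to_ms(34)   # 17.49 m/s
#' knots_to_kmh(34)  # 62.97 km/h
#' @export
knots_to_ms <- function(v) {
  check_nonneg(v)
  v * 0.514444
}

#' @rdname knots_to_ms
#' @export
ms_to_knots <- function(v) {
  check_nonneg(v)
  v / 0.514444
}

#' @rdname knots_to_ms
#' @export
knots_to_kmh <- function(v) {
  check_nonneg(v)
  v * 1.852
}

#' @rdname knots_to_ms
#' @export
knots_to_mph <- function(v) {
  check_nonneg(v)
  v * 1.15078
}

check_nonneg <- function(v) {
  if (!is.numeric(v)) stop("wind speed must be numeric", call. = FALSE)
  if (any(is.finite(v) & v < 0)) {
    stop("wind speed must be non-negative", call. = FALSE)
  }
  invisible(v)
}
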