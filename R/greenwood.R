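#' Greenwood cochlear frequency-position map
#'
#' The exponential frequency-position function
#' \eqn{F(x) = A (10^{a x} - k)} with position `x` in mm from the apex.
#' Defaults are the standard human constants (`A` = 165.4 Hz,
#' `a` = 0.06 / mm, `k` = 1, cochlear length 35 mm).
#'
#' @param A Scale parameter in Hz.
#' @param a Exponential slope in 1/mm.
#' @param k Integration constant (dimensionless).
#' @param length Cochlear length in mm.
#' @return An object of class `greenwood_map`.
#' @export
#' @examples
#' m <- greenwood_map()
#' greenwood_frequency(m, greenwood_position(m, 8000))  # 8000
greenwood_map <- function(A = 165.4, a = 0.06, k = 1, length = 35) {
  stopifnot(A > 0, a > 0, k >= 0, length > 0)
  structure(list(A = A, a = a, k = k, length = length), class = "greenwood_map")
}

#' @rdname greenwood_map
#' @param map A `greenwood_map`.
#' @param x Position(s) in mm from the apex.
#' @export
greenwood_frequency <- function(map, x) {
  map$A * (10^(map$a * x) - map$k)
}

#' @rdname greenwood_map
#' @param f Frequency (Hz).
#' @export
greenwood_position <- function(map, f) {
  log10(f / map$A + map$k) / map$a
}

#' Equivalent rectangular bandwidth of a cochlear span
#'
#' Frequency extent of a span of `span_mm` millimetres of basilar membrane
#' centred (in place) on the place of `f_c`:
#' `F(x + span/2) - F(x - span/2)` with `x = position(f_c)`. A 1.5-mm span at
#' an 8-kHz place gives approximately 1.69 kHz under the human map.
#'
#' @param f_c Centre frequency in Hz.
#' @param span_mm Cochlear span in mm.
#' @param map A `greenwood_map` (default: human constants).
#' @return Bandwidth in Hz.
#' @export
#' @examples
#' greenwood_erb(8000, 1.5)
greenwood_erb <- function(f_c, span_mm, map = greenwood_map()) {
  stopifnot(span_mm >= 0)
  x <- greenwood_position(map, f_c)
  if (!is.finite(x) || x - span_mm / 2 < 0 || x + span_mm / 2 > map$length) {
    abort("`f_c` (with the requested span) falls outside the cochlear map range.")
  }
  greenwood_frequency(map, x + span_mm / 2) - greenwood_frequency(map, x - span_mm / 2)
}
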