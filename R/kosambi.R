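#' Kosambi map function
#'
#' Converts a recombination fraction `r` into a map distance in centimorgans,
#' `d = 25 * ln((1 + 2r) / (1 - 2r))`, allowing for partial crossover
#' interference. `kosambi_inverse()` is the exact inverse,
#' `r = 0.5 * tanh(d / 50)`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in centimorgans, `>= 0`.
#' @return `kosambi_distance()` returns centimorgans; `kosambi_inverse()`
#'   returns recombination fractions in `[0, 0.5)`.
#' @examples
#' kosambi_distance(0.25)           # 25 * log(3) = 27.465 cM
#' kosambi_inverse(10)              # 0.0987
#' @export
kosambi_distance <- function(r) {
  if (!is.numeric(r) || any(is.na(r))) {
    stop("'r' must be numeric with no missing values")
  }
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_distance
#' @export
kosambi_inverse <- function(d) {
  if (!is.numeric(d) || any(is.na(d))) {
    stop("'d' must be numeric with no missing values")
  }
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * tanh(d / 50)
}
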