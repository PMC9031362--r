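#' Concentration series for a screening plate
#'
#' Builds the descending molar concentration series used by a screen stage.
#' Two named designs are provided: the 5-point primary-screen series
#' (5.14 uM, 1.09 uM, 156 nM, 30.8 nM, 6.2 nM; roughly 5-fold dilutions
#' spanning low-micromolar to nanomolar potency) and the 10-point
#' confirmation series, log-spaced from 20 uM down to 20 nM. `custom`
#' yields `n` log-spaced values from `top` to `bottom`.
#'
#' @param kind one of `"primary5"`, `"confirmation10"`, `"custom"`.
#' @param top,bottom highest/lowest concentration in mol/L (custom only).
#' @param n number of concentrations (custom only).
#' @return numeric vector of concentrations in mol/L, strictly decreasing,
#'   with attribute `label` naming the design.
#' @examples
#' concentration_series("primary5")
#' concentration_series("confirmation10")
#' concentration_series("custom", top = 1e-5, bottom = 1e-8, n = 4)
#' @export
concentration_series <- function(kind = c("primary5", "confirmation10", "custom"),
                                 top = NULL, bottom = NULL, n = NULL) {
  kind <- match.arg(kind)
  values <- switch(kind,
    primary5 = c(5.14e-6, 1.09e-6, 1.56e-7, 3.08e-8, 6.2e-9),
    confirmation10 = 10^seq(log10(2e-5), log10(2e-8), length.out = 10),
    custom = {
      if (is.null(top) || is.null(bottom) || is.null(n)) {
        abort_invalid("custom series requires top, bottom and n")
      }
      if (!is.numeric(top) || !is.numeric(bottom) || top <= 0 || bottom <= 0) {
        abort_invalid("concentration bounds must be positive")
      }
      if (top <= bottom) abort_invalid("top must exceed bottom")
      if (!is_count(n) || n < 2) abort_invalid("n must be an integer >= 2")
      10^seq(log10(top), log10(bottom), length.out = n)
    })
  structure(values, label = kind)
}

validate_series <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    abort_invalid("concentration series must have >= 2 values")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort_invalid("concentrations must be positive and finite")
  }
  if (any(diff(values) >= 0)) {
    abort_invalid("concentration series must be strictly decreasing")
  }
  invisible(values)
}
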