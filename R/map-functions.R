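#' Recombination map functions
#'
#' Convert genetic distance in centimorgan to a recombination fraction under
#' the Haldane (no crossover interference) or Kosambi (moderate positive
#' interference) map function, and back.
#'
#' Haldane: \eqn{r(d) = (1 - e^{-2d/100}) / 2}.
#' Kosambi: \eqn{r(d) = \tanh(2d/100) / 2}.
#'
#' @param d_cm Genetic distance(s) in centimorgan (non-negative).
#' @param map_function `"haldane"` or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' recomb_fraction(50, "haldane") # ~0.316
#' recomb_fraction(50, "kosambi") # ~0.381
#' @export
recomb_fraction <- function(d_cm, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  stopifnot(all(d_cm >= 0))
  m <- d_cm / 100
  switch(map_function,
    haldane = (1 - exp(-2 * m)) / 2,
    kosambi = tanh(2 * m) / 2
  )
}

#' @rdname recomb_fraction
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return For `map_distance()`, genetic distance(s) in centimorgan.
#' @export
map_distance <- function(r, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  stopifnot(all(r >= 0), all(r < 0.5))
  100 * switch(map_function,
    haldane = -log(1 - 2 * r) / 2,
    kosambi = atanh(2 * r) / 2
  )
}
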