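#' Map functions: recombination fraction to genetic distance
#'
#' Convert a per-meiosis recombination fraction `r` to a map distance in
#' centiMorgans and back.  The Kosambi function,
#' \deqn{d = 25 \,\ln\frac{1+2r}{1-2r},}
#' allows for positive crossover interference and is the function used
#' throughout this package for map construction and interval-mapping
#' position probabilities.  The Haldane function, \eqn{d = -50\,\ln(1-2r)},
#' assumes no interference and matches the Poisson crossover process used
#' by [simulate_ril_genomes()].
#'
#' @param r recombination fraction(s), in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return `kosambi()`/`haldane()` return distances in cM;
#'   `kosambi_inverse()`/`haldane_inverse()` return recombination fractions.
#'   Round trips are exact to floating-point precision.
#' @examples
#' kosambi(0.25)                  # 25 * log(3)
#' kosambi_inverse(kosambi(0.1))  # 0.1
#' @export
kosambi <- function(r) {
  check_rf(r)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inverse <- function(d) {
  check_cm(d)
  0.5 * tanh(d / 50)
}

#' @rdname kosambi
#' @export
haldane <- function(r) {
  check_rf(r)
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi
#' @export
haldane_inverse <- function(d) {
  check_cm(d)
  (1 - exp(-d / 50)) / 2
}

check_rf <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fractions must lie in [0, 0.5)", call. = FALSE)
  invisible(r)
}

check_cm <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("map distances must be finite and >= 0", call. = FALSE)
  invisible(d)
}

map_function <- function(name = c("kosambi", "haldane")) {
  name <- match.arg(name)
  if (name == "kosambi") list(to_cm = kosambi, to_r = kosambi_inverse)
  else list(to_cm = haldane, to_r = haldane_inverse)
}

#' Recombination fraction conversions for selfed RILs
#'
#' In a recombinant inbred population produced by repeated selfing, each
#' meiosis contributes crossovers, so the fraction `R` of lines in which two
#' loci carry different parental alleles exceeds the per-meiosis
#' recombination fraction `r`.  At fixation `R = 2r / (1 + 2r)`
#' (Haldane & Waddington), inverted by `r = R / (2 - 2R)`.
#'
#' @param r per-meiosis recombination fraction in `[0, 0.5)`.
#' @param R observed fraction of lines recombinant between two loci.
#' @return the converted fraction.
#' @export
ril_selfing_R <- function(r) {
  check_rf(r)
  2 * r / (1 + 2 * r)
}

#' @rdname ril_selfing_R
#' @export
ril_selfing_r <- function(R) {
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    stop("R must lie in [0, 1]", call. = FALSE)
  pmin(R / (2 - 2 * R), 0.5 - 1e-9)
}
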