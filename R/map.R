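#' Haldane map function
#'
#' Convert genetic distances in centimorgan to recombination fractions and
#' back under the Haldane (no-interference) map function, which matches the
#' memoryless Markov chain used to model haplotype inheritance along a
#' chromosome.
#'
#' @param d_cM numeric vector of interval lengths in centimorgan (>= 0).
#' @return `haldane_r()`: recombination fractions in `[0, 0.5)`.
#' @examples
#' haldane_r(100)          # one Morgan
#' haldane_d(haldane_r(5)) # round trip
#' @export
haldane_r <- function(d_cM) {
  stopifnot(is.numeric(d_cM), all(d_cM >= 0))
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' @rdname haldane_r
#' @param r numeric vector of recombination fractions in `[0, 0.5)`.
#' @return `haldane_d()`: distances in centimorgan.
#' @export
haldane_d <- function(r) {
  stopifnot(is.numeric(r), all(r >= 0), all(r < 0.5))
  -50 * log(1 - 2 * r)
}

#' Genetic map of one chromosome
#'
#' A genetic map holds the physical marker positions of one chromosome and
#' the genetic length (cM) of each of the `L - 1` marker intervals, for one
#' sex (or the sex-average). Recombination fractions are derived from the
#' interval lengths with the Haldane map function.
#'
#' @param chromosome chromosome label (single token).
#' @param positions integer-ish vector of marker bp positions, strictly
#'   increasing, length `L >= 2`.
#' @param d numeric vector of interval lengths in cM, length `L - 1`,
#'   all `>= 0`.
#' @param sex one of `"averaged"`, `"F"`, `"M"`.
#' @return An object of class `genetic_map`: a list with elements
#'   `chromosome`, `positions`, `d`, `sex`.
#' @seealso [map_length()], [haldane_r()], [write_genetic_map()]
#' @export
genetic_map <- function(chromosome, positions, d, sex = c("averaged", "F", "M")) {
  sex <- match.arg(sex)
  positions <- as.numeric(positions)
  if (length(positions) < 2L) {
    stop("a genetic map needs at least two markers")
  }
  if (any(diff(positions) <= 0)) {
    stop("marker positions must be strictly increasing")
  }
  if (length(d) != length(positions) - 1L) {
    stop("need one interval length per marker interval (length(positions) - 1)")
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("interval lengths must be finite and >= 0")
  }
  structure(
    list(chromosome = as.character(chromosome)[1L],
         positions = positions, d = as.numeric(d), sex = sex),
    class = "genetic_map"
  )
}

#' @rdname genetic_map
#' @param x a `genetic_map`.
#' @return `map_length()`: total length in cM (sum of interval lengths).
#' @export
map_length <- function(x) {
  stopifnot(inherits(x, "genetic_map"))
  sum(x$d)
}

#' @rdname genetic_map
#' @return `map_r()`: per-interval recombination fractions (Haldane).
#' @export
map_r <- function(x) {
  stopifnot(inherits(x, "genetic_map"))
  haldane_r(x$d)
}

#' Uniform genetic map
#'
#' Build a map in which a total length is divided equally over all marker
#' intervals. This is the uninformative starting point of the map iteration
#' (100 cM, i.e. one expected crossover per chromosome).
#'
#' @inheritParams genetic_map
#' @param total_length total chromosome length in cM.
#' @return A [genetic_map()].
#' @export
uniform_map <- function(chromosome, positions, total_length = 100, sex = "averaged") {
  L <- length(positions)
  genetic_map(chromosome, positions,
              rep(total_length / (L - 1L), L - 1L), sex = sex)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: chromosome %s, %d markers, %.2f cM (%s)\n",
              x$chromosome, length(x$positions), sum(x$d), x$sex))
  invisible(x)
}

#' Span of a chromosome map in Mb
#'
#' Physical span (last minus first marker position) in megabases; used as the
#' denominator when reporting recombination rates in cM/Mb.
#'
#' @param x a `genetic_map` or a marker-map data frame for one chromosome.
#' @return span in Mb.
#' @export
map_span_Mb <- function(x) {
  pos <- if (inherits(x, "genetic_map")) x$positions else x$pos
  (max(pos) - min(pos)) / 1e6
}
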