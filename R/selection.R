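#' Mean of the selected top fraction
#'
#' Mean of the `ceiling(n * proportion)` largest values (truncation
#' selection on the phenotype); ties are broken by value order, so equal
#' values at the truncation point are interchangeable.
#'
#' @param values numeric phenotype values (e.g. recombination rates in
#'   cM/Mb).
#' @param proportion selected proportion in (0, 1].
#' @return mean of the selected group.
#' @examples
#' selected_mean(c(1, 2, 3, 4), 0.5)  # 3.5
#' @export
selected_mean <- function(values, proportion) {
  stopifnot(length(values) > 0, proportion > 0, proportion <= 1)
  k <- ceiling(length(values) * proportion)
  mean(sort(values, decreasing = TRUE)[seq_len(k)])
}

#' Response to truncation selection (breeders' equation)
#'
#' `R = h^2 * S = h^2 * (mu_selected - mu)`: the response to one round of
#' selection equals the heritability times the selection differential.
#'
#' @param mu population mean (cM/Mb).
#' @param mu_selected mean of the selected individuals (cM/Mb).
#' @param h2 narrow-sense heritability in `[0, 1]`.
#' @return list with `response` (cM/Mb) and `relative` (response as a
#'   fraction of `mu`).
#' @examples
#' breeders_response(0.904, 1.22, 0.05)
#' @export
breeders_response <- function(mu, mu_selected, h2) {
  stopifnot(h2 >= 0, h2 <= 1, mu > 0)
  R <- h2 * (mu_selected - mu)
  list(response = R, relative = R / mu)
}

#' Gain from fixing a quantitative trait locus
#'
#' Expected increase of the population mean when the favourable allele of an
#' additive QTL is driven to fixation: `a * (1 - p)` where `a` is the
#' additive allele-substitution effect and `p` the current favourable-allele
#' frequency.
#'
#' @param a additive effect of the favourable allele (cM/Mb).
#' @param p favourable-allele frequency in `[0, 1]`.
#' @param mu optional population mean; when given, the relative gain is also
#'   returned.
#' @return list with `gain` (cM/Mb) and, if `mu` is given, `relative`.
#' @examples
#' qtl_fixation_gain(0.0271, 0.332, mu = 0.904)
#' @export
qtl_fixation_gain <- function(a, p, mu = NULL) {
  stopifnot(p >= 0, p <= 1)
  gain <- a * (1 - p)
  out <- list(gain = gain)
  if (!is.null(mu)) out$relative <- gain / mu
  out
}
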