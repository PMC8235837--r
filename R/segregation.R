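#' Segregation evidence at one locus
#'
#' Likelihood of a child's local data under each of the two parental
#' haplotypes the child may have inherited from one parent. The parent's
#' genotype states are marginalised into per-haplotype transmitted-allele
#' probabilities, the other parent's contribution enters through its
#' transmitted-allele distribution, and an `eps` transmission floor guards
#' against conflicting calls. Loci where the parent is (effectively)
#' homozygous or the child data are missing come out uninformative
#' (proportional to `[1, 1]`).
#'
#' @param child_lik likelihood 4-vector of the child's local data (own
#'   penetrance times posterior from its descendants) over ordered genotypes.
#' @param parent_dist normalised probability 4-vector of the parent's
#'   ordered genotype.
#' @param other_allele_dist probability 2-vector `(a, A)` of the allele
#'   transmitted by the other parent.
#' @param side `"pat"` when the parent under consideration is the sire (the
#'   child's paternal slot), `"mat"` for the dam.
#' @param eps transmission error floor.
#' @return normalised probability 2-vector over the parental haplotype.
#' @examples
#' # heterozygous parent, child carries 'a' on this side:
#' segregation_evidence(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0), "pat", 0.01)
#' @export
segregation_evidence <- function(child_lik, parent_dist, other_allele_dist,
                                 side = c("pat", "mat"), eps = 0.01) {
  side <- match.arg(side)
  stopifnot(length(child_lik) == 4, length(parent_dist) == 4,
            length(other_allele_dist) == 2, eps > 0, eps < 0.5)
  aA <- c(parent_dist[3] + parent_dist[4],   # P(transmit A | hap 0)
          parent_dist[2] + parent_dist[4])   # P(transmit A | hap 1)
  w <- other_allele_dist / sum(other_allele_dist)
  if (side == "pat") {
    qa <- w[1] * child_lik[1] + w[2] * child_lik[2]
    qA <- w[1] * child_lik[3] + w[2] * child_lik[4]
  } else {
    qa <- w[1] * child_lik[1] + w[2] * child_lik[3]
    qA <- w[1] * child_lik[2] + w[2] * child_lik[4]
  }
  fqa <- (1 - eps) * qa + eps * qA
  fqA <- (1 - eps) * qA + eps * qa
  e <- c((1 - aA[1]) * fqa + aA[1] * fqA,
         (1 - aA[2]) * fqa + aA[2] * fqA)
  if (sum(e) <= 0) return(c(0.5, 0.5))
  e / sum(e)
}

#' Forward-backward smoothing of the inheritance chain
#'
#' Exact smoothed marginals of the per-parent two-state Markov chain with
#' uniform initial distribution, symmetric transition matrix
#' `[[1 - r_j, r_j], [r_j, 1 - r_j]]` per interval (Haldane fractions from
#' the map), and the given per-locus evidence. Per-locus rescaling avoids
#' underflow; all reported quantities are invariant to evidence scaling.
#'
#' @param evidence 2 x L matrix of per-locus evidence (unnormalised).
#' @param map a [genetic_map()] with `L` markers (or a numeric vector of
#'   `L - 1` recombination fractions).
#' @return list with `gamma` (2 x L smoothed marginals), `exc` (expected
#'   crossovers per interval, see [expected_crossovers()]), and the scaled
#'   `alpha`/`beta` caches.
#' @export
forward_backward <- function(evidence, map) {
  r <- if (inherits(map, "genetic_map")) map_r(map) else as.numeric(map)
  stopifnot(is.matrix(evidence), nrow(evidence) == 2,
            length(r) == ncol(evidence) - 1L, all(r >= 0), all(r <= 0.5))
  .fb_twostate_cpp(evidence, r)
}

#' Expected crossover count per marker interval
#'
#' For interval `j` the pairwise posterior over neighbouring segregation
#' states is `xi_j(a, b) ~ alpha_j(a) T_ab(r_j) e_{j+1}(b) beta_{j+1}(b)`;
#' the expected crossover count is the normalised off-diagonal mass
#' `sum_{a != b} xi_j(a, b)`. With uninformative evidence this equals the
#' prior `r_j` exactly.
#'
#' @inheritParams forward_backward
#' @return numeric vector of length `L - 1`, each value in `[0, 1]`.
#' @export
expected_crossovers <- function(evidence, map) {
  forward_backward(evidence, map)$exc
}

#' Update a genetic map from expected crossover counts
#'
#' Sets each interval to 100 times the mean expected crossover count over
#' the contributing gametes (`mode = "interval"`, the default), or rescales
#' the whole map to the new total length while keeping the relative interval
#' spacing (`mode = "total"`). Recombination fractions follow via Haldane.
#'
#' @param expectations matrix of per-gamete expected crossover counts
#'   (gametes x intervals), `NA` rows allowed (dropped).
#' @param map the current [genetic_map()].
#' @param mode `"interval"` or `"total"`.
#' @return the updated [genetic_map()].
#' @export
update_map <- function(expectations, map, mode = c("interval", "total")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "genetic_map"))
  if (is.null(dim(expectations))) {
    expectations <- matrix(expectations, nrow = 1L)
  }
  expectations <- expectations[stats::complete.cases(expectations), ,
                               drop = FALSE]
  if (nrow(expectations) == 0L) {
    stop("no gametes available to update the map")
  }
  if (ncol(expectations) != length(map$d)) {
    stop("expectations have ", ncol(expectations),
         " intervals but the map has ", length(map$d))
  }
  mean_exc <- colMeans(expectations)
  d_new <- if (mode == "interval") {
    100 * mean_exc
  } else {
    total <- 100 * sum(mean_exc)
    if (sum(map$d) > 0) total * map$d / sum(map$d) else
      rep(total / length(map$d), length(map$d))
  }
  genetic_map(map$chromosome, map$positions, d_new, sex = map$sex)
}

#' Estimate recombination rates and sex-specific genetic maps
#'
#' The full estimation loop: starting from uniform 100 cM maps for both
#' sexes, alternate [run_peeling_cycles()] and [update_map()]
#' `n_map_iterations` times. The female map is re-estimated from the
#' maternal-side gametes and the male map from the paternal-side gametes of
#' the gamete set (by default the individuals passing
#' [filter_informative()]; if that set is empty, all individuals with both
#' parents known are used, with a warning). Multi-chromosome marker maps are
#' split and chromosomes estimated independently.
#'
#' @param pedigree a `pedigree`.
#' @param genotypes dosage matrix over all chromosomes, columns in
#'   `marker_map` order.
#' @param marker_map a `marker_map` (one or more chromosomes).
#' @param params a [peeling_params()].
#' @param n_map_iterations number of map refinement steps (default 4).
#' @param init_length starting chromosome length in cM (default 100, one
#'   expected crossover per chromosome).
#' @param map_update `"interval"` or `"total"`, see [update_map()].
#' @param gamete_filter `"informative"` (QC-filtered, default) or `"all"`
#'   (all individuals with both parents known).
#' @param warm_start reuse the peeling state across map iterations (faster;
#'   the result is still deterministic given inputs and parameters).
#' @return list of class `recomb_fit` with `map_female`, `map_male` (lists of
#'   per-chromosome [genetic_map()]s), `estimates` (data.frame with one row
#'   per gamete: `id`, `parent_id`, `side`, `sex_of_parent`,
#'   `expected_crossovers`, `rate_cM_per_Mb`), `exc_pat`, `exc_mat`
#'   (per-interval expectations per chromosome), `gametes_used`,
#'   `genome_Mb`, `fits` (final per-chromosome `peel_fit`s) and `params`.
#' @export
estimate_recombination <- function(pedigree, genotypes, marker_map,
                                   params = peeling_params(),
                                   n_map_iterations = 4L, init_length = 100,
                                   map_update = c("interval", "total"),
                                   gamete_filter = c("informative", "all"),
                                   warm_start = TRUE) {
  map_update <- match.arg(map_update)
  gamete_filter <- match.arg(gamete_filter)
  stopifnot(inherits(pedigree, "pedigree"), inherits(marker_map, "marker_map"),
            n_map_iterations >= 1)
  calls <- .align_genotypes(pedigree, genotypes)
  panel <- classify_panels(calls)
  genotyped <- names(panel)[panel != "ungenotyped"]

  gam <- if (gamete_filter == "informative") {
    filter_informative(pedigree, genotyped)
  } else {
    character(0)
  }
  if (!length(gam)) {
    gam <- pedigree$id[!is.na(pedigree$sire) & !is.na(pedigree$dam)]
    if (gamete_filter == "informative") {
      warning("no individuals pass the informative filter; ",
              "updating the map from all individuals with known parents")
    }
  }
  if (!length(gam)) stop("no gametes available for map estimation")

  chroms <- unique(marker_map$chrom)
  fits <- list(); maps_f <- list(); maps_m <- list()
  exc_pat <- list(); exc_mat <- list()
  for (ch in chroms) {
    sel <- which(marker_map$chrom == ch)
    mm <- marker_map[sel, , drop = FALSE]
    cc <- calls[, sel, drop = FALSE]
    map_f <- uniform_map(ch, mm$pos, init_length, sex = "F")
    map_m <- uniform_map(ch, mm$pos, init_length, sex = "M")
    st <- NULL
    fit <- NULL
    for (it in seq_len(n_map_iterations)) {
      fit <- .peel_engine(pedigree, cc, map_f, map_m, params,
                          state = if (warm_start) st else NULL)
      st <- fit$state
      map_f <- update_map(fit$exc_mat[gam, , drop = FALSE], map_f,
                          mode = map_update)
      map_m <- update_map(fit$exc_pat[gam, , drop = FALSE], map_m,
                          mode = map_update)
    }
    fit$state <- NULL
    fits[[ch]] <- fit
    maps_f[[ch]] <- map_f
    maps_m[[ch]] <- map_m
    exc_pat[[ch]] <- fit$exc_pat
    exc_mat[[ch]] <- fit$exc_mat
  }

  genome_Mb <- sum(vapply(chroms, function(ch) {
    map_span_Mb(marker_map[marker_map$chrom == ch, , drop = FALSE])
  }, numeric(1)))

  tot_pat <- Reduce(`+`, lapply(exc_pat, rowSums))
  tot_mat <- Reduce(`+`, lapply(exc_mat, rowSums))
  si <- stats::setNames(pedigree$sire, pedigree$id)
  di <- stats::setNames(pedigree$dam, pedigree$id)
  est <- rbind(
    data.frame(id = pedigree$id, parent_id = unname(si), side = "pat",
               expected_crossovers = unname(tot_pat[pedigree$id]),
               stringsAsFactors = FALSE),
    data.frame(id = pedigree$id, parent_id = unname(di), side = "mat",
               expected_crossovers = unname(tot_mat[pedigree$id]),
               stringsAsFactors = FALSE)
  )
  est <- est[!is.na(est$expected_crossovers) & !is.na(est$parent_id), ,
             drop = FALSE]
  est$rate_cM_per_Mb <- 100 * est$expected_crossovers / genome_Mb
  rownames(est) <- NULL

  structure(list(map_female = maps_f, map_male = maps_m, estimates = est,
                 exc_pat = exc_pat, exc_mat = exc_mat, gametes_used = gam,
                 genome_Mb = genome_Mb, fits = fits, params = params),
            class = "recomb_fit")
}

#' @export
print.recomb_fit <- function(x, ...) {
  lf <- sum(vapply(x$map_female, map_length, numeric(1)))
  lm <- sum(vapply(x$map_male, map_length, numeric(1)))
  cat(sprintf(
    "recomb_fit: %d chromosome(s), female map %.1f cM, male map %.1f cM, %d gametes in map update\n",
    length(x$map_female), lf, lm, length(x$gametes_used)))
  invisible(x)
}
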