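#' Select individuals with informative recombination estimates
#'
#' Keeps individuals whose parents and grandparents are present in the
#' pedigree and genotyped; under the strict reading (default) that means
#' both parents and all four grandparents. The relaxed mode requires both
#' parents genotyped and at least one genotyped grandparent on each side.
#' Founders are always excluded.
#'
#' @param pedigree a `pedigree`.
#' @param genotyped character vector of genotyped ids.
#' @param relaxed logical; relax the grandparent requirement (default FALSE).
#' @return character vector of retained ids.
#' @export
filter_informative <- function(pedigree, genotyped, relaxed = FALSE) {
  stopifnot(inherits(pedigree, "pedigree"))
  idx <- ped_indices(pedigree)
  si <- idx$sire; di <- idx$dam
  gt <- pedigree$id %in% genotyped
  gp_ok_side <- function(p) {
    # p: parent index vector (0 = unknown); TRUE when that side's
    # grandparents satisfy the requirement
    ok <- logical(length(p))
    known <- p > 0L
    gs <- ifelse(known, si[pmax(p, 1L)], 0L)
    gd <- ifelse(known, di[pmax(p, 1L)], 0L)
    g1 <- gs > 0L & gt[pmax(gs, 1L)]
    g2 <- gd > 0L & gt[pmax(gd, 1L)]
    if (relaxed) ok <- known & (g1 | g2) else ok <- known & g1 & g2
    ok
  }
  parents_gt <- si > 0L & gt[pmax(si, 1L)] & di > 0L & gt[pmax(di, 1L)]
  keep <- parents_gt & gp_ok_side(si) & gp_ok_side(di)
  pedigree$id[keep]
}

#' Remove individuals with extreme recombination-rate estimates
#'
#' Drops individuals whose average recombination rate exceeds the threshold
#' (strictly greater than; a rate exactly at the threshold is kept).
#'
#' @param rates named numeric vector of per-individual average rates in
#'   cM/Mb, or a data.frame with columns `id` and `rate_cM_per_Mb` (averaged
#'   per id).
#' @param threshold removal threshold in cM/Mb (default 5).
#' @return character vector of retained ids.
#' @export
filter_outliers <- function(rates, threshold = 5) {
  if (is.data.frame(rates)) {
    rates <- tapply(rates$rate_cM_per_Mb, rates$id, mean)
  }
  stopifnot(is.numeric(rates), !is.null(names(rates)))
  names(rates)[!(rates > threshold)]
}

#' Map gamete estimates to parental phenotype records
#'
#' Each retained offspring contributes one phenotype record to its dam (its
#' maternal gamete) and one to its sire (its paternal gamete); the
#' recombination rate of the gamete becomes a repeated observation of the
#' parent. Gamete records whose parent is unknown are omitted.
#'
#' @param estimates per-gamete estimates as produced by
#'   [estimate_recombination()] (columns `id`, `parent_id`, `side`,
#'   `rate_cM_per_Mb`), already filtered to the retained offspring.
#' @param pedigree a `pedigree` (provides the parents' sex and line).
#' @return data.frame of class `phenotype_table` with columns `parent_id`,
#'   `sex`, `line`, `offspring_id`, `rate`.
#' @export
gametes_to_parent_phenotypes <- function(estimates, pedigree) {
  stopifnot(inherits(pedigree, "pedigree"),
            all(c("id", "parent_id", "side", "rate_cM_per_Mb") %in%
                  names(estimates)))
  est <- estimates[!is.na(estimates$parent_id), , drop = FALSE]
  # the record's parent must be the sire (pat) or dam (mat) of the offspring
  si <- stats::setNames(pedigree$sire, pedigree$id)
  di <- stats::setNames(pedigree$dam, pedigree$id)
  expect <- ifelse(est$side == "pat", si[est$id], di[est$id])
  if (any(est$parent_id != expect, na.rm = TRUE)) {
    stop("estimate record whose parent is not the offspring's sire/dam")
  }
  sex <- stats::setNames(pedigree$sex, pedigree$id)
  line <- stats::setNames(pedigree$line, pedigree$id)
  out <- data.frame(parent_id = est$parent_id,
                    sex = ifelse(est$side == "pat", "M", "F"),
                    line = unname(line[est$parent_id]),
                    offspring_id = est$id,
                    rate = est$rate_cM_per_Mb,
                    stringsAsFactors = FALSE)
  sx <- unname(sex[est$parent_id])
  bad <- !is.na(sx) & sx != out$sex
  if (any(bad)) {
    stop("pedigree sex conflicts with parental role for ",
         out$parent_id[bad][1L])
  }
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}
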