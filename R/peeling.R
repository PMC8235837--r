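# Ordered-genotype state space. States are (paternal allele, maternal
# allele) with alleles a = 0, A = 1, in the fixed order
#   1: (a,a)  2: (a,A)  3: (A,a)  4: (A,A)
# so the dosage of a state is its count of A alleles.
.GENO_PAT <- c(0L, 0L, 1L, 1L)
.GENO_MAT <- c(0L, 1L, 0L, 1L)
.GENO_DOSE <- .GENO_PAT + .GENO_MAT

# Posterior match indicators: for a called offspring that received allele x
# through parental haplotype s, the parent ordered-genotype states whose
# haplotype-s allele equals x. Columns: missing, (s=0,x=0), (s=0,x=1),
# (s=1,x=0), (s=1,x=1).
.CONTRIB <- cbind(0, c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0), c(0, 1, 0, 1))

#' Peeling parameters
#'
#' Tunable parameters of the multilocus iterative peeling run.
#'
#' @param genotype_error symmetric genotyping error rate `eps` used in the
#'   penetrance and in the transmission floor of the segregation evidence
#'   and posterior (0 < eps < 0.5).
#' @param seg_call_threshold probability above which a segregation state is
#'   called (taken as certain); below it the state is set to missing.
#' @param geno_call_threshold probability above which an ordered genotype is
#'   called.
#' @param n_outer_cycles maximum number of outer peeling cycles (one
#'   downward anterior/segregation pass plus one upward posterior pass).
#' @param convergence_tol early stop when the largest absolute change in any
#'   genotype probability between cycles falls below this value.
#' @param founder_prior `"allele_freq"` (Hardy-Weinberg at the observed
#'   allele frequency; default) or `"uniform"` for founder genotype priors.
#' @return list of class `peeling_params`.
#' @export
peeling_params <- function(genotype_error = 0.01,
                           seg_call_threshold = 0.99,
                           geno_call_threshold = 0.90,
                           n_outer_cycles = 5L,
                           convergence_tol = 1e-4,
                           founder_prior = c("allele_freq", "uniform")) {
  stopifnot(genotype_error > 0, genotype_error < 0.5,
            seg_call_threshold > 0.5, seg_call_threshold <= 1,
            geno_call_threshold > 0.5, geno_call_threshold <= 1,
            n_outer_cycles >= 1, convergence_tol >= 0)
  structure(list(genotype_error = genotype_error,
                 seg_call_threshold = seg_call_threshold,
                 geno_call_threshold = geno_call_threshold,
                 n_outer_cycles = as.integer(n_outer_cycles),
                 convergence_tol = convergence_tol,
                 founder_prior = match.arg(founder_prior)),
            class = "peeling_params")
}

#' Penetrance of a dosage call
#'
#' Unnormalised probability of an observed dosage call given each of the four
#' ordered genotypes, under a symmetric error model: states whose dosage
#' matches the call share probability `1 - eps` equally, the remaining states
#' share `eps` equally; a missing call (9) is uninformative.
#'
#' @param call dosage code in `{0, 1, 2, 9}`.
#' @param eps genotyping error rate.
#' @return probability 4-vector over ordered genotypes.
#' @examples
#' penetrance(9, 0.01)  # all ones
#' penetrance(0, 0.01)  # c(0.99, 0.01/3, 0.01/3, 0.01/3)
#' @export
penetrance <- function(call, eps) {
  stopifnot(length(call) == 1L, eps > 0, eps < 0.5)
  if (!call %in% c(0, 1, 2, 9)) {
    stop("invalid dosage code (allowed: 0 1 2 9): ", call)
  }
  if (call == 9) return(rep(1, 4))
  hit <- .GENO_DOSE == call
  p <- numeric(4)
  p[hit] <- (1 - eps) / sum(hit)
  p[!hit] <- eps / sum(!hit)
  p
}

# 4 x 4 lookup, one column per code 0,1,2,9 (in that order)
.pen_lookup <- function(eps) {
  vapply(c(0, 1, 2, 9), penetrance, numeric(4), eps = eps)
}

#' Anterior genotype distribution of an offspring
#'
#' Probability of each ordered genotype of an offspring given its parents'
#' genotype distributions and its segregation distributions. The two parental
#' transmissions factorise: the paternal (maternal) allele is the father's
#' (mother's) haplotype-`s` allele, mixed over `s` by the segregation
#' probabilities.
#'
#' @param father_dist,mother_dist probability 4-vectors over the parents'
#'   ordered genotypes (normalised).
#' @param seg_pat,seg_mat probability 2-vectors over the inherited parental
#'   haplotype (paternal side, maternal side).
#' @return probability 4-vector over the offspring's ordered genotypes.
#' @examples
#' anterior(c(0, 0, 0, 1), c(1, 0, 0, 0), c(.5, .5), c(.5, .5)) # child (A,a)
#' @export
anterior <- function(father_dist, mother_dist, seg_pat, seg_mat) {
  stopifnot(length(father_dist) == 4, length(mother_dist) == 4,
            length(seg_pat) == 2, length(seg_mat) == 2)
  pA <- seg_pat[1] * (father_dist[3] + father_dist[4]) +
    seg_pat[2] * (father_dist[2] + father_dist[4])
  pM <- seg_mat[1] * (mother_dist[3] + mother_dist[4]) +
    seg_mat[2] * (mother_dist[2] + mother_dist[4])
  c((1 - pA) * (1 - pM), (1 - pA) * pM, pA * (1 - pM), pA * pM)
}

#' Call a probability distribution against a threshold
#'
#' Returns the 0-based index of the most probable state when its probability
#' reaches the threshold (called "taken as certain"), otherwise `NA`
#' (missing, i.e. all states equally likely downstream). The comparison is
#' `>=`, so a state exactly at the threshold is called.
#'
#' @param dist normalised probability vector.
#' @param tau calling threshold in (0.5, 1].
#' @return integer state index (0-based) or `NA_integer_`.
#' @examples
#' call_probabilities(c(0.995, 0.003, 0.001, 0.001), 0.99) # 0
#' call_probabilities(c(0.6, 0.4), 0.99)                   # NA
#' @export
call_probabilities <- function(dist, tau) {
  stopifnot(tau > 0.5, tau <= 1)
  k <- which.max(dist)
  if (dist[k] >= tau) k - 1L else NA_integer_
}

#' Posterior factor of a parent from called offspring
#'
#' For each parent ordered-genotype state `g`, the product over offspring
#' with a non-missing called genotype and a non-missing called segregation
#' on this parent's side of the probability of the called transmitted allele:
#' `1 - eps` when the parent's haplotype-`s` allele equals the allele the
#' offspring carries in the corresponding slot, `eps` otherwise. Offspring
#' with any missing call contribute a factor of one. The result is
#' renormalised; with no contributing offspring it is uniform.
#'
#' @param parent_side `"pat"` if the parent is the sire of the offspring
#'   (transmitted allele = paternal slot of the offspring genotype),
#'   `"mat"` if the dam.
#' @param geno_calls integer vector of called offspring ordered genotypes
#'   (0-based, `NA` = missing), one per offspring.
#' @param seg_calls integer vector of called segregation states on this side
#'   (0/1, `NA` = missing), aligned with `geno_calls`.
#' @param eps per-offspring error floor.
#' @return normalised probability 4-vector over the parent's genotypes.
#' @export
posterior_from_offspring <- function(parent_side = c("pat", "mat"),
                                     geno_calls, seg_calls, eps) {
  parent_side <- match.arg(parent_side)
  stopifnot(length(geno_calls) == length(seg_calls), eps > 0, eps < 0.5)
  slot <- if (parent_side == "pat") .GENO_PAT else .GENO_MAT
  p <- rep(1, 4)
  for (k in seq_along(geno_calls)) {
    if (is.na(geno_calls[k]) || is.na(seg_calls[k])) next
    x <- slot[geno_calls[k] + 1L]
    s <- seg_calls[k]
    match_g <- .CONTRIB[, 2L + 2L * s + x]
    p <- p * ifelse(match_g == 1, 1 - eps, eps)
  }
  p / sum(p)
}

#' Combine peeling factors for one individual
#'
#' Per-locus genotype distribution proportional to
#' `anterior * penetrance * posterior`, normalised column-wise. Loci where
#' the product vanishes (conflicting evidence) fall back to the penetrance
#' alone with a warning.
#'
#' @param anterior,penetrance,posterior 4 x L matrices (or 4-vectors for a
#'   single locus) of factor values.
#' @return normalised 4 x L matrix of genotype probabilities.
#' @export
peel_individual <- function(anterior, penetrance, posterior) {
  a <- if (is.matrix(anterior)) anterior else matrix(anterior, 4)
  pe <- if (is.matrix(penetrance)) penetrance else matrix(penetrance, 4)
  po <- if (is.matrix(posterior)) posterior else matrix(posterior, 4)
  g <- a * pe * po
  s <- colSums(g)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad)) {
    warning("conflicting evidence at ", length(bad),
            " locus/loci; falling back to penetrance only")
    g[, bad] <- pe[, bad]
    s[bad] <- colSums(pe[, bad, drop = FALSE])
  }
  g / rep(s, each = 4L)
}

# internal: normalise columns of a 4 x L factor product with penetrance
# fallback (returns a list to also flag fallback loci)
.norm_cols <- function(g, pen) {
  s <- colSums(g)
  bad <- s <= 0 | !is.finite(s)
  if (any(bad)) {
    g[, bad] <- pen[, bad]
    s[bad] <- colSums(pen[, bad, drop = FALSE])
  }
  g / rep(s, each = 4L)
}

#' Run multilocus iterative peeling on one chromosome
#'
#' Alternates downward passes (anterior update and segregation
#' forward-backward, individuals in generation order) and upward passes
#' (posterior factors rebuilt from the freshly called offspring states)
#' until `n_outer_cycles` is reached or the genotype probabilities stop
#' changing. Segregation and genotype probabilities are called against the
#' `seg_call_threshold` / `geno_call_threshold` after every cycle; values
#' below threshold are set to missing, meaning either parental haplotype or
#' any genotype is treated as equally likely when used as offspring evidence.
#'
#' @param pedigree a `pedigree` (see [read_pedigree()]).
#' @param genotypes integer dosage matrix (individuals x loci, codes
#'   0/1/2/9) with rownames covering all pedigree ids, as returned by
#'   [read_genotypes()].
#' @param map_female,map_male [genetic_map()]s used for the maternal-side
#'   and paternal-side segregation chains. A single `map` argument may be
#'   given instead to use one map for both sides.
#' @param params a [peeling_params()] list.
#' @param map optional sex-averaged map used for both sides.
#' @param keep_genotype_probs keep the full per-individual 4 x L genotype
#'   probability arrays in the result (memory-heavy for large data).
#' @param state internal: warm-start state from a previous call.
#' @return list of class `peel_fit` with elements `dosage` (expected dosage
#'   matrix), `geno_call`, `seg_call_pat`, `seg_call_mat` (called states,
#'   `NA` = missing), `exc_pat`, `exc_mat` (per-gamete expected crossover
#'   counts per interval; `NA` rows for unknown-parent sides), `seg_pat`,
#'   `seg_mat` (smoothed segregation probability arrays), `n_cycles`,
#'   `delta`, `converged`, and optionally `geno_prob`.
#' @export
run_peeling_cycles <- function(pedigree, genotypes, map_female = NULL,
                               map_male = NULL, params = peeling_params(),
                               map = NULL, keep_genotype_probs = FALSE,
                               state = NULL) {
  stopifnot(inherits(pedigree, "pedigree"), inherits(params, "peeling_params"))
  if (!is.null(map)) {
    map_female <- map_male <- map
  }
  stopifnot(inherits(map_female, "genetic_map"), inherits(map_male, "genetic_map"))
  calls <- .align_genotypes(pedigree, genotypes)
  eng <- .peel_engine(pedigree, calls, map_female, map_male, params,
                      keep_genotype_probs = keep_genotype_probs,
                      state = state)
  eng
}

# align genotype matrix rows to pedigree ids, filling missing rows with 9
.align_genotypes <- function(pedigree, genotypes) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  L <- ncol(genotypes)
  out <- matrix(9L, nrow(pedigree), L,
                dimnames = list(pedigree$id, colnames(genotypes)))
  keep <- intersect(pedigree$id, rownames(genotypes))
  out[keep, ] <- genotypes[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  if (!all(out %in% c(0L, 1L, 2L, 9L))) {
    stop("genotype matrix contains codes outside {0, 1, 2, 9}")
  }
  out
}

# founder genotype prior (4 x L) from observed allele frequencies
.founder_prior <- function(calls, type) {
  L <- ncol(calls)
  if (type == "uniform") {
    return(matrix(0.25, 4, L))
  }
  obs <- calls != 9L
  n <- colSums(obs)
  d <- colSums(calls * obs)
  f <- ifelse(n > 0, d / (2 * n), 0.5)
  f <- pmin(pmax(f, 0.01), 0.99)  # keep the prior proper
  rbind((1 - f)^2, (1 - f) * f, f * (1 - f), f^2)
}

# The engine. One chromosome; individuals in pedigree (generation) order.
.peel_engine <- function(ped, calls, map_f, map_m, params,
                         keep_genotype_probs = FALSE, state = NULL) {
  n <- nrow(ped)
  L <- ncol(calls)
  eps <- params$genotype_error
  tau_g <- params$geno_call_threshold
  tau_s <- params$seg_call_threshold
  idx <- ped_indices(ped)
  sire <- idx$sire
  dam <- idx$dam
  PEN <- .pen_lookup(eps)
  codecol <- matrix(match(calls, c(0L, 1L, 2L, 9L)), n, L)
  prior4 <- .founder_prior(calls, params$founder_prior)
  r_f <- haldane_r(map_f$d)
  r_m <- haldane_r(map_m$d)
  logit <- log((1 - eps) / eps)
  drop_ratio <- eps / (1 - eps)
  unif2 <- matrix(0.5, 2, L)

  if (is.null(state)) {
    anterior <- lapply(seq_len(n), function(i) {
      if (sire[i] == 0L && dam[i] == 0L) prior4 else matrix(0.25, 4, L)
    })
    postm <- vector("list", n)                 # match-count matrices (NULL = none)
    segp <- rep(list(unif2), n)
    segm <- rep(list(unif2), n)
    gcall <- matrix(NA_integer_, n, L)
    scall_p <- matrix(NA_integer_, n, L)
    scall_m <- matrix(NA_integer_, n, L)
    gprob <- vector("list", n)
  } else {
    anterior <- state$anterior; postm <- state$postm
    segp <- state$segp; segm <- state$segm
    gcall <- state$gcall; scall_p <- state$scall_p; scall_m <- state$scall_m
    gprob <- state$gprob
  }

  pen_of <- function(i) PEN[, codecol[i, ], drop = FALSE]

  # posterior weight matrix from match counts, column-normalised by max
  post_weight <- function(i) {
    m <- postm[[i]]
    if (is.null(m)) return(NULL)
    cm <- pmax(m[1, ], m[2, ], m[3, ], m[4, ])
    exp(logit * (m - rep(cm, each = 4L)))
  }

  # contribution (match-indicator) matrix of offspring i to parent on side
  contrib_of <- function(i, side) {
    g <- gcall[i, ]
    s <- if (side == "pat") scall_p[i, ] else scall_m[i, ]
    slot <- if (side == "pat") .GENO_PAT else .GENO_MAT
    code <- ifelse(is.na(g) | is.na(s), 0L, 1L + 2L * s + slot[g + 1L])
    .CONTRIB[, code + 1L, drop = FALSE]
  }

  # genotype distribution of parent p excluding offspring i's contribution
  parent_dist <- function(p, contrib) {
    pe <- pen_of(p)
    w <- post_weight(p)
    g <- anterior[[p]] * pe
    if (!is.null(w)) {
      if (!is.null(contrib)) {
        w <- w * (1 + contrib * (drop_ratio - 1))
      }
      g <- g * w
    }
    .norm_cols(g, pe)
  }

  # P(transmit allele A | haplotype s) rows s = 1, 2; from a 4 x L dist
  hap_alleleA <- function(P) {
    rbind(P[3, ] + P[4, ], P[2, ] + P[4, ])
  }

  n_cycles <- 0L
  delta <- Inf
  converged <- FALSE
  exc_p <- matrix(NA_real_, n, max(L - 1L, 0L))
  exc_m <- matrix(NA_real_, n, max(L - 1L, 0L))

  for (cycle in seq_len(params$n_outer_cycles)) {
    n_cycles <- n_cycles + 1L

    ## downward pass: anterior + segregation, generation order
    for (i in seq_len(n)) {
      si <- sire[i]; di <- dam[i]
      if (si == 0L && di == 0L) next
      Fd <- if (si > 0L) parent_dist(si, contrib_of(i, "pat")) else prior4
      Md <- if (di > 0L) parent_dist(di, contrib_of(i, "mat")) else prior4
      aF <- hap_alleleA(Fd)
      aM <- hap_alleleA(Md)
      pe <- pen_of(i)
      w <- post_weight(i)
      Lc <- if (is.null(w)) pe else pe * w
      # paternal-side evidence (other-side mixing via cached maternal seg)
      wAm <- colSums(segm[[i]] * aM)
      qa <- (1 - wAm) * Lc[1, ] + wAm * Lc[2, ]
      qA <- (1 - wAm) * Lc[3, ] + wAm * Lc[4, ]
      fqa <- (1 - eps) * qa + eps * qA       # transmission floor
      fqA <- (1 - eps) * qA + eps * qa
      ep <- rbind((1 - aF[1, ]) * fqa + aF[1, ] * fqA,
                  (1 - aF[2, ]) * fqa + aF[2, ] * fqA)
      # maternal-side evidence
      wAp <- colSums(segp[[i]] * aF)
      qa2 <- (1 - wAp) * Lc[1, ] + wAp * Lc[3, ]
      qA2 <- (1 - wAp) * Lc[2, ] + wAp * Lc[4, ]
      fqa2 <- (1 - eps) * qa2 + eps * qA2
      fqA2 <- (1 - eps) * qA2 + eps * qa2
      em <- rbind((1 - aM[1, ]) * fqa2 + aM[1, ] * fqA2,
                  (1 - aM[2, ]) * fqa2 + aM[2, ] * fqA2)
      fbp <- .fb_twostate_cpp(ep, r_m)
      fbm <- .fb_twostate_cpp(em, r_f)
      segp[[i]] <- fbp$gamma
      segm[[i]] <- fbm$gamma
      if (L > 1L) {
        exc_p[i, ] <- fbp$exc
        exc_m[i, ] <- fbm$exc
      }
      pA <- colSums(fbp$gamma * aF)
      pM <- colSums(fbm$gamma * aM)
      anterior[[i]] <- rbind((1 - pA) * (1 - pM), (1 - pA) * pM,
                             pA * (1 - pM), pA * pM)
    }

    ## genotype distributions + calling
    dmax <- 0
    for (i in seq_len(n)) {
      pe <- pen_of(i)
      w <- post_weight(i)
      g <- anterior[[i]] * pe
      if (!is.null(w)) g <- g * w
      g <- .norm_cols(g, pe)
      if (!is.null(gprob[[i]])) {
        dmax <- max(dmax, max(abs(g - gprob[[i]])))
      } else {
        dmax <- Inf
      }
      gprob[[i]] <- g
      mx <- pmax(g[1, ], g[2, ], g[3, ], g[4, ])
      am <- max.col(t(g), ties.method = "first")
      gcall[i, ] <- ifelse(mx >= tau_g, am - 1L, NA_integer_)
      sp <- segp[[i]]
      scall_p[i, ] <- ifelse(sp[1, ] >= tau_s, 0L,
                             ifelse(sp[2, ] >= tau_s, 1L, NA_integer_))
      sm <- segm[[i]]
      scall_m[i, ] <- ifelse(sm[1, ] >= tau_s, 0L,
                             ifelse(sm[2, ] >= tau_s, 1L, NA_integer_))
    }
    # founders and unknown sides have no segregation
    scall_p[sire == 0L, ] <- NA_integer_
    scall_m[dam == 0L, ] <- NA_integer_

    ## upward pass: rebuild posterior match counts from the fresh calls
    postm <- vector("list", n)
    for (i in seq_len(n)) {
      si <- sire[i]; di <- dam[i]
      if (si > 0L) {
        cc <- contrib_of(i, "pat")
        postm[[si]] <- if (is.null(postm[[si]])) cc else postm[[si]] + cc
      }
      if (di > 0L) {
        cc <- contrib_of(i, "mat")
        postm[[di]] <- if (is.null(postm[[di]])) cc else postm[[di]] + cc
      }
    }

    delta <- dmax
    if (is.finite(delta) && delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && params$convergence_tol > 0 &&
      params$n_outer_cycles > 1L) {
    # informational only; results are still returned
    message(sprintf(
      "peeling did not reach convergence_tol after %d cycles (delta = %.2g)",
      n_cycles, delta))
  }

  dosage <- matrix(0, n, L, dimnames = list(ped$id, colnames(calls)))
  for (i in seq_len(n)) dosage[i, ] <- colSums(gprob[[i]] * .GENO_DOSE)
  dimnames(gcall) <- dimnames(calls)
  rownames(exc_p) <- rownames(exc_m) <- ped$id
  rownames(scall_p) <- rownames(scall_m) <- ped$id

  out <- list(dosage = dosage, geno_call = gcall,
              seg_call_pat = scall_p, seg_call_mat = scall_m,
              exc_pat = exc_p, exc_mat = exc_m,
              seg_pat = stats::setNames(segp, ped$id),
              seg_mat = stats::setNames(segm, ped$id),
              n_cycles = n_cycles, delta = delta, converged = converged,
              state = list(anterior = anterior, postm = postm, segp = segp,
                           segm = segm, gcall = gcall, scall_p = scall_p,
                           scall_m = scall_m, gprob = gprob))
  if (keep_genotype_probs) out$geno_prob <- stats::setNames(gprob, ped$id)
  class(out) <- "peel_fit"
  out
}

#' @export
print.peel_fit <- function(x, ...) {
  cat(sprintf("peel_fit: %d individuals x %d loci, %d cycle(s), delta %.3g%s\n",
              nrow(x$dosage), ncol(x$dosage), x$n_cycles, x$delta,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}
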