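# Independent brute-force oracles. These enumerate the exact model directly
# and share no code with the package implementation.

# All 2^L state paths of a two-state chain as a matrix (paths x L).
.all_paths <- function(L) {
  as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE]
}

# Exact smoothed marginals and per-interval switch expectations of the
# two-state chain by full path enumeration.
enum_fb <- function(evidence, r) {
  L <- ncol(evidence)
  paths <- .all_paths(L)
  w <- rep(0.5, nrow(paths))
  for (j in seq_len(L)) {
    w <- w * evidence[paths[, j] + 1L, j]
  }
  if (L > 1L) {
    for (j in seq_len(L - 1L)) {
      same <- paths[, j] == paths[, j + 1L]
      w <- w * ifelse(same, 1 - r[j], r[j])
    }
  }
  w <- w / sum(w)
  gamma <- rbind(colSums(w * (paths == 0L)), colSums(w * (paths == 1L)))
  exc <- if (L > 1L) {
    vapply(seq_len(L - 1L), function(j) {
      sum(w * (paths[, j] != paths[, j + 1L]))
    }, numeric(1))
  } else numeric(0)
  list(gamma = gamma, exc = exc)
}

# symmetric-error penetrance used by the oracles (model definition,
# written out independently): consistent states share 1-eps, others eps
.oracle_pen <- function(call, eps) {
  dose <- c(0, 1, 1, 2)
  if (call == 9) return(rep(1, 4))
  hit <- dose == call
  hit * (1 - eps) / sum(hit) + (!hit) * eps / sum(!hit)
}

.hap0 <- c(0L, 0L, 1L, 1L)  # first-slot allele of the 4 ordered states
.hap1 <- c(0L, 1L, 0L, 1L)

# Exact genotype marginals for a founder trio (sire, dam, child) by
# enumeration over both of the child's segregation paths and the parents'
# per-locus genotypes.
# calls: 3 x L matrix (rows sire, dam, child); r_pat/r_mat: L-1 fractions;
# prior: per-founder-locus 4-vector prior (4 x L matrix).
enum_trio <- function(calls, r_pat, r_mat, eps, prior) {
  L <- ncol(calls)
  paths <- .all_paths(L)
  np <- nrow(paths)
  path_w <- function(pp, r) {
    w <- rep(0.5, np)
    if (L > 1L) {
      for (j in seq_len(L - 1L)) {
        w <- w * ifelse(pp[, j] == pp[, j + 1L], 1 - r[j], r[j])
      }
    }
    w
  }
  wp <- path_w(paths, r_pat)
  wm <- path_w(paths, r_mat)
  # per locus and per (s_pat, s_mat) in {0,1}^2: partition function and
  # per-individual marginal numerators
  Z <- array(0, c(2, 2, L))
  margF <- array(0, c(2, 2, L, 4))
  margM <- array(0, c(2, 2, L, 4))
  margC <- array(0, c(2, 2, L, 4))
  for (j in seq_len(L)) {
    pF <- .oracle_pen(calls[1L, j], eps) * prior[, j]
    pM <- .oracle_pen(calls[2L, j], eps) * prior[, j]
    pCpen <- .oracle_pen(calls[3L, j], eps)
    for (sp in 0:1) {
      for (sm in 0:1) {
        hapF <- if (sp == 0) .hap0 else .hap1
        hapM <- if (sm == 0) .hap0 else .hap1
        for (gF in 1:4) {
          for (gM in 1:4) {
            x <- hapF[gF]; y <- hapM[gM]
            gC <- 1L + 2L * x + y          # state index of (x, y)
            t <- pF[gF] * pM[gM] * pCpen[gC]
            Z[sp + 1, sm + 1, j] <- Z[sp + 1, sm + 1, j] + t
            margF[sp + 1, sm + 1, j, gF] <- margF[sp + 1, sm + 1, j, gF] + t
            margM[sp + 1, sm + 1, j, gM] <- margM[sp + 1, sm + 1, j, gM] + t
            margC[sp + 1, sm + 1, j, gC] <- margC[sp + 1, sm + 1, j, gC] + t
          }
        }
      }
    }
  }
  outF <- matrix(0, 4, L); outM <- matrix(0, 4, L); outC <- matrix(0, 4, L)
  total <- 0
  for (a in seq_len(np)) {
    for (b in seq_len(np)) {
      zz <- vapply(seq_len(L), function(j) {
        Z[paths[a, j] + 1L, paths[b, j] + 1L, j]
      }, numeric(1))
      W <- wp[a] * wm[b] * prod(zz)
      if (W == 0) next
      total <- total + W
      for (j in seq_len(L)) {
        sp <- paths[a, j] + 1L; sm <- paths[b, j] + 1L
        outF[, j] <- outF[, j] + W / zz[j] * margF[sp, sm, j, ]
        outM[, j] <- outM[, j] + W / zz[j] * margM[sp, sm, j, ]
        outC[, j] <- outC[, j] + W / zz[j] * margC[sp, sm, j, ]
      }
    }
  }
  list(sire = outF / total, dam = outM / total, child = outC / total)
}

# Exact genotype marginals for the 4-individual chain A x B -> C,
# C x (unknown) -> E, enumerating C's two segregation paths and E's
# paternal path; the unknown dam of E is marginalised per locus through the
# transmitted-allele distribution of the founder prior.
# calls: 4 x L (rows A, B, C, E).
enum_chain <- function(calls, r_pat, r_mat, eps, prior) {
  L <- ncol(calls)
  paths <- .all_paths(L)
  np <- nrow(paths)
  pw <- function(r) {
    w <- rep(0.5, np)
    if (L > 1L) {
      for (j in seq_len(L - 1L)) {
        w <- w * ifelse(paths[, j] == paths[, j + 1L], 1 - r[j], r[j])
      }
    }
    w
  }
  wCp <- pw(r_pat); wCm <- pw(r_mat); wEp <- pw(r_pat)
  # transmitted-allele distribution of an unknown founder
  pA_un <- colSums(prior * (.hap0 + .hap1) / 2)
  out <- lapply(1:4, function(i) matrix(0, 4, L))
  total <- 0
  penA <- vapply(seq_len(L), function(j) .oracle_pen(calls[1, j], eps) * prior[, j], numeric(4))
  penB <- vapply(seq_len(L), function(j) .oracle_pen(calls[2, j], eps) * prior[, j], numeric(4))
  penC <- vapply(seq_len(L), function(j) .oracle_pen(calls[3, j], eps), numeric(4))
  penE <- vapply(seq_len(L), function(j) .oracle_pen(calls[4, j], eps), numeric(4))
  for (a in seq_len(np)) {        # C pat path (from A)
    for (b in seq_len(np)) {      # C mat path (from B)
      for (e in seq_len(np)) {    # E pat path (from C)
        w0 <- wCp[a] * wCm[b] * wEp[e]
        zz <- numeric(L)
        mj <- vector("list", L)
        for (j in seq_len(L)) {
          m <- matrix(0, 4, 4)    # accumulators: rows individual, cols state
          z <- 0
          for (gA in 1:4) {
            for (gB in 1:4) {
              x <- if (paths[a, j] == 0) .hap0[gA] else .hap1[gA]
              y <- if (paths[b, j] == 0) .hap0[gB] else .hap1[gB]
              gC <- 1L + 2L * x + y
              xe <- if (paths[e, j] == 0) .hap0[gC] else .hap1[gC]
              for (ye in 0:1) {
                gE <- 1L + 2L * xe + ye
                py <- if (ye == 1) pA_un[j] else 1 - pA_un[j]
                t <- penA[gA, j] * penB[gB, j] * penC[gC, j] *
                  penE[gE, j] * py
                z <- z + t
                m[1, gA] <- m[1, gA] + t
                m[2, gB] <- m[2, gB] + t
                m[3, gC] <- m[3, gC] + t
                m[4, gE] <- m[4, gE] + t
              }
            }
          }
          zz[j] <- z
          mj[[j]] <- m
        }
        W <- w0 * prod(zz)
        if (W == 0) next
        total <- total + W
        for (j in seq_len(L)) {
          for (i in 1:4) {
            out[[i]][, j] <- out[[i]][, j] + W / zz[j] * mj[[j]][i, ]
          }
        }
      }
    }
  }
  names(out) <- c("A", "B", "C", "E")
  lapply(out, function(m) m / total)
}
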