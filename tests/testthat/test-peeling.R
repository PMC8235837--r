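test_that("penetrance follows the symmetric error model", {
  eps <- 0.01
  expect_equal(penetrance(9, eps), rep(1, 4))
  expect_equal(penetrance(0, eps), c(1 - eps, eps / 3, eps / 3, eps / 3))
  expect_equal(penetrance(2, eps), c(eps / 3, eps / 3, eps / 3, 1 - eps))
  # enumeration of the stated rule for the heterozygous call: the two
  # consistent ordered states share 1 - eps, the two others share eps
  p1 <- penetrance(1, eps)
  dose <- c(0, 1, 1, 2)
  expect_equal(p1[dose == 1], rep((1 - eps) / 2, 2))
  expect_equal(p1[dose != 1], rep(eps / 2, 2))
  expect_equal(sum(p1), 1)
  expect_error(penetrance(3, eps), "invalid dosage")
})

test_that("anterior distribution combines parents and segregation", {
  # forced transmission: (A,A) father x (a,a) mother -> child (A,a)
  expect_equal(anterior(c(0, 0, 0, 1), c(1, 0, 0, 0), c(.5, .5), c(.5, .5)),
               c(0, 0, 1, 0))
  # symmetry: uniform everything -> uniform child
  expect_equal(anterior(rep(.25, 4), rep(.25, 4), c(.5, .5), c(.5, .5)),
               rep(.25, 4))
  # hand enumeration of the two haplotype choices of a het father
  expect_equal(anterior(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0.7, 0.3), c(.5, .5)),
               c(0.7, 0, 0.3, 0))
})

test_that("probability calling respects the threshold boundary", {
  expect_equal(call_probabilities(c(0.995, 0.003, 0.001, 0.001), 0.99), 0L)
  expect_true(is.na(call_probabilities(c(0.6, 0.4), 0.99)))
  # calls at exactly the threshold (>= rule)
  expect_equal(call_probabilities(c(0.90, 0.10), 0.90), 0L)
  # idempotence: calling a called (certain) state returns the same state
  for (k in 1:4) {
    d <- rep(0, 4); d[k] <- 1
    expect_equal(call_probabilities(d, 0.99), k - 1L)
  }
})

test_that("posterior from called offspring matches a brute-force product", {
  eps <- 0.01
  # no offspring -> uniform
  expect_equal(posterior_from_offspring("pat", integer(0), integer(0), eps),
               rep(0.25, 4))
  # one offspring carrying A in the paternal slot via haplotype 0:
  # parent states with first-slot allele A get 1 - eps, others eps
  p <- posterior_from_offspring("pat", geno_calls = 3L, seg_calls = 0L,
                                eps = eps)
  w <- c(eps, eps, 1 - eps, 1 - eps)
  expect_equal(p, w / sum(w))
  # three offspring with mixed/missing calls vs independent product oracle
  geno <- c(3L, 0L, NA)
  seg <- c(0L, 1L, 1L)
  got <- posterior_from_offspring("pat", geno, seg, eps)
  hap <- list(c(0, 0, 1, 1), c(0, 1, 0, 1))
  pat_slot <- c(0, 0, 1, 1)
  oracle <- rep(1, 4)
  for (k in 1:3) {
    if (is.na(geno[k]) || is.na(seg[k])) next
    x <- pat_slot[geno[k] + 1]
    oracle <- oracle * ifelse(hap[[seg[k] + 1]] == x, 1 - eps, eps)
  }
  expect_equal(got, oracle / sum(oracle), tolerance = 1e-12)
})

test_that("peel_individual multiplies factors with closed-form results", {
  eps <- 0.01
  # founder with call 0 and no other information
  g <- peel_individual(rep(0.25, 4), penetrance(0, eps), rep(1, 4))
  expect_equal(g[1, 1], (1 - eps) / (1 - eps + eps), tolerance = 1e-12)
  # ungenotyped offspring of two (A,A) parents is (A,A) with certainty
  ant <- anterior(c(0, 0, 0, 1), c(0, 0, 0, 1), c(.5, .5), c(.5, .5))
  g2 <- peel_individual(ant, penetrance(9, eps), rep(1, 4))
  expect_equal(g2[, 1], c(0, 0, 0, 1))
  # conflicting evidence falls back to the penetrance with a warning
  expect_warning(
    g3 <- peel_individual(c(1, 0, 0, 0), c(0, 1, 0, 0), rep(1, 4)),
    "conflicting")
  expect_equal(g3[, 1], c(0, 1, 0, 0))
})

test_that("trio genotype marginals match exhaustive enumeration", {
  # regime in which the factorised updates are exact to float accuracy:
  # tiny error rate and tight linkage
  eps <- 1e-6
  L <- 6L
  map <- genetic_map("1", 1e6 * seq_len(L), rep(0.02, L - 1L))
  ped <- trio_pedigree()
  # informative fixture: het sire, mixed dam, child consistent with one
  # crossover-free transmission
  calls <- geno_matrix(F1 = c(1L, 1L, 1L, 1L, 1L, 1L),
                       M1 = c(0L, 0L, 2L, 2L, 0L, 1L),
                       C1 = c(0L, 0L, 1L, 1L, 0L, 1L))
  params <- peeling_params(genotype_error = eps, founder_prior = "uniform",
                           n_outer_cycles = 10L)
  fit <- suppressMessages(run_peeling_cycles(ped, calls, map = map,
                                             params = params,
                                             keep_genotype_probs = TRUE))
  oracle <- enum_trio(calls, map_r(map), map_r(map), eps,
                      prior = matrix(0.25, 4, L))
  expect_lt(max(abs(fit$geno_prob[["C1"]] - oracle$child)), 1e-6)
  expect_lt(max(abs(fit$geno_prob[["F1"]] - oracle$sire)), 1e-6)
  expect_lt(max(abs(fit$geno_prob[["M1"]] - oracle$dam)), 1e-6)
})

test_that("peeling is a fixed point on fully missing data", {
  ped <- trio_pedigree()
  L <- 5L
  calls <- geno_matrix(F1 = rep(9L, L), M1 = rep(9L, L), C1 = rep(9L, L))
  map <- genetic_map("1", 1e6 * seq_len(L), rep(5, L - 1L))
  params <- peeling_params(founder_prior = "uniform", n_outer_cycles = 4L)
  fit <- suppressMessages(run_peeling_cycles(ped, calls, map = map,
                                             params = params,
                                             keep_genotype_probs = TRUE))
  for (id in ped$id) {
    expect_equal(fit$geno_prob[[id]], matrix(0.25, 4, L))
  }
  expect_true(all(is.na(fit$geno_call)))
})

test_that("error-free complete trio recovers Mendelian phase", {
  # sire (a,A)-het everywhere, dam aa: child's het loci must be phased
  # paternal-A, and imputed dosages equal the observed dosages
  L <- 8L
  ped <- trio_pedigree()
  calls <- geno_matrix(F1 = rep(1L, L), M1 = rep(0L, L),
                       C1 = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  map <- genetic_map("1", 1e6 * seq_len(L), rep(1, L - 1L))
  params <- peeling_params(genotype_error = 1e-6, n_outer_cycles = 6L)
  fit <- suppressMessages(run_peeling_cycles(ped, calls, map = map,
                                             params = params))
  expect_equal(unname(fit$geno_call["C1", 1:4]), rep(2L, 4L)) # (A,a)
  expect_equal(unname(fit$geno_call["C1", 5:8]), rep(0L, 4L)) # (a,a)
  expect_lt(max(abs(fit$dosage["C1", ] - calls["C1", ])), 1e-4)
})

test_that("distributions stay normalised and non-negative through cycles", {
  set.seed(5)
  cfg <- sim_config(n_founders = 20, n_generations = 3, dams_per_gen = 5,
                    sires_per_gen = 2, offspring_per_dam = 4, n_loci = 30,
                    total_length_male = 60, seed = 9)
  ds <- simulate_dataset(cfg)
  map <- uniform_map("1", ds$marker_map$pos, 100)
  fit <- suppressMessages(run_peeling_cycles(
    ds$pedigree, ds$genotypes, map = map,
    params = peeling_params(n_outer_cycles = 3L),
    keep_genotype_probs = TRUE))
  for (id in sample(ds$pedigree$id, 20)) {
    g <- fit$geno_prob[[id]]
    expect_true(all(g >= 0))
    expect_lt(max(abs(colSums(g) - 1)), 1e-8)
    sp <- fit$seg_pat[[id]]
    expect_lt(max(abs(colSums(sp) - 1)), 1e-8)
  }
})

test_that("with near-zero error and complete genotyping, dosages are exact", {
  set.seed(13)
  cfg <- sim_config(n_founders = 20, n_generations = 3, dams_per_gen = 5,
                    sires_per_gen = 2, offspring_per_dam = 4, n_loci = 40,
                    total_length_male = 60,
                    panel_fractions = c(high = 1, low = 0, ungenotyped = 0),
                    genotype_error = 0, seed = 21)
  ds <- simulate_dataset(cfg)
  truth <- ds$truth$hap_pat + ds$truth$hap_mat
  map <- uniform_map("1", ds$marker_map$pos, 100)
  fit <- suppressMessages(run_peeling_cycles(
    ds$pedigree, ds$genotypes, map = map,
    params = peeling_params(genotype_error = 1e-9, n_outer_cycles = 3L)))
  # in the eps -> 0 limit the imputed dosages converge to the truth; the
  # residual is proportional to eps (checked at eps = 1e-9)
  expect_lt(max(abs(fit$dosage - truth)), 1e-3)
  # wherever the ordered genotype is called, its dosage is the true dosage
  called <- !is.na(fit$geno_call)
  dose_of_state <- c(0L, 1L, 1L, 2L)
  expect_true(all(dose_of_state[fit$geno_call[called] + 1L] == truth[called]))
})
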