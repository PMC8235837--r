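test_that("Haldane map function round-trips and bounds hold", {
  d <- c(0, 0.1, 1, 10, 100, 300)
  r <- haldane_r(d)
  expect_true(all(r >= 0 & r < 0.5))
  expect_equal(haldane_d(r), d, tolerance = 1e-10)
  expect_equal(haldane_r(100), 0.5 * (1 - exp(-2)))
})

test_that("segregation evidence marginalises parent and other-parent", {
  eps <- 0.01
  # heterozygous parent, child certainly carries 'a' on the paternal side
  e <- segregation_evidence(c(1, 1, 0, 0), c(0, 1, 0, 0), c(0.5, 0.5),
                            side = "pat", eps = eps)
  expect_equal(e, c(1 - eps, eps))
  # homozygous parent is uninformative
  e2 <- segregation_evidence(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0.5, 0.5),
                             side = "pat", eps = eps)
  expect_equal(e2, c(0.5, 0.5))
  # uncertain child genotype: hand marginalisation
  e3 <- segregation_evidence(c(0.7, 0.7, 0.3, 0.3), c(0, 1, 0, 0),
                             c(0.5, 0.5), side = "pat", eps = eps)
  expected <- c(0.7 * (1 - eps) + 0.3 * eps, 0.3 * (1 - eps) + 0.7 * eps)
  expect_equal(e3, expected / sum(expected))
})

test_that("forward-backward matches path enumeration", {
  # trivial prior recovery
  L <- 6L
  ev <- matrix(1, 2, L)
  map <- genetic_map("1", 1e6 * seq_len(L), rep(3, L - 1L))
  fb <- forward_backward(ev, map)
  expect_equal(fb$gamma, matrix(0.5, 2, L))
  # certain evidence pins both loci
  fb2 <- forward_backward(matrix(c(1, 0, 1, 0), 2), c(0.2))
  expect_equal(fb2$gamma, matrix(c(1, 0, 1, 0), 2))
  # random evidence vs brute force over all 2^L paths
  set.seed(101)
  for (rep in 1:3) {
    L <- 10L
    ev <- matrix(stats::runif(2 * L), 2, L)
    r <- stats::runif(L - 1L, 0.001, 0.2)
    fb3 <- forward_backward(ev, r)
    oracle <- enum_fb(ev, r)
    expect_lt(max(abs(fb3$gamma - oracle$gamma)), 1e-10)
    expect_lt(max(abs(fb3$exc - oracle$exc)), 1e-10)
  }
  # and at the acceptance scale of 12 loci
  L <- 12L
  ev <- matrix(stats::runif(2 * L), 2, L)
  r <- stats::runif(L - 1L, 0.001, 0.3)
  fb4 <- forward_backward(ev, r)
  oracle <- enum_fb(ev, r)
  expect_lt(max(abs(fb4$gamma - oracle$gamma)), 1e-10)
  expect_lt(max(abs(fb4$exc - oracle$exc)), 1e-10)
})

test_that("expected crossovers recover the prior and forced switches", {
  # uninformative evidence: interval expectation equals r_j exactly
  L <- 9L
  r <- seq(0.01, 0.08, length.out = L - 1L)
  exc <- expected_crossovers(matrix(1, 2, L), r)
  expect_equal(exc, r, tolerance = 1e-12)
  # forced switch
  exc2 <- expected_crossovers(matrix(c(1, 0, 0, 1), 2), 0.01)
  expect_gt(exc2, 0.999)
  # L = 8 random fixture vs enumeration
  set.seed(77)
  ev <- matrix(stats::runif(16), 2, 8)
  r8 <- stats::runif(7, 0.01, 0.2)
  expect_lt(max(abs(expected_crossovers(ev, r8) - enum_fb(ev, r8)$exc)),
            1e-10)
})

test_that("map update averages gamete expectations", {
  map <- genetic_map("1", c(1e6, 2e6, 3e6), c(1, 1))
  # single shared expectation
  m1 <- update_map(matrix(0.005, 4, 2), map)
  expect_equal(m1$d, c(0.5, 0.5))
  # mean of two gametes
  m2 <- update_map(rbind(c(0.01, 0.02), c(0.03, 0.02)), map)
  expect_equal(m2$d, c(2, 2))
  # scale consistency: doubling expectations doubles every interval
  e <- matrix(stats::runif(10, 0, 0.05), 5, 2)
  expect_equal(update_map(2 * e, map)$d, 2 * update_map(e, map)$d)
  # total-only mode keeps relative spacing
  map_uneven <- genetic_map("1", c(1e6, 2e6, 3e6), c(3, 1))
  m3 <- update_map(rbind(c(0.01, 0.01)), map_uneven, mode = "total")
  expect_equal(m3$d / sum(m3$d), c(0.75, 0.25))
  expect_equal(sum(m3$d), 2)
  expect_error(update_map(matrix(NA_real_, 1, 2), map), "no gametes")
})

test_that("all-missing genotypes leave the 100 cM prior as a fixed point", {
  ped <- fixture_pedigree(30L, n_gen = 3L)
  L <- 200L
  mm <- tiny_marker_map(L, spacing = 5e5)
  calls <- matrix(9L, nrow(ped), L, dimnames = list(ped$id, mm$marker))
  map0 <- uniform_map("1", mm$pos, 100)
  fit <- suppressMessages(run_peeling_cycles(
    ped, calls, map = map0,
    params = peeling_params(n_outer_cycles = 2L, founder_prior = "uniform")))
  r0 <- map_r(map0)
  # every interval expectation equals the prior r_j exactly
  exc <- fit$exc_pat[!is.na(fit$exc_pat[, 1L]), , drop = FALSE]
  expect_gt(nrow(exc), 0L)
  expect_lt(max(abs(t(exc) - r0)), 1e-12)
  # the update reproduces the prior in recombination-frequency units
  # exactly; in cM it is a fixed point up to the Haldane second-order term
  # sum(d_j^2)/100 (= 0.5 cM at this marker density)
  upd <- update_map(exc, map0)
  expect_lt(max(abs(upd$d - 100 * r0)), 1e-12)
  drift <- sum(map0$d^2) / 100
  expect_lt(abs(map_length(upd) - (100 - drift)), 0.01)
})

test_that("estimation recovers a flat map and stays near truth", {
  cfg <- sim_config(n_founders = 80, n_generations = 4, dams_per_gen = 16,
                    sires_per_gen = 4, offspring_per_dam = 6, n_loci = 150,
                    total_length_male = 100, female_ratio = 1,
                    end_elevation = 1,   # flat landscape
                    panel_fractions = c(high = 0.8, low = 0.2,
                                        ungenotyped = 0),
                    seed = 31)
  ds <- simulate_dataset(cfg)
  fit <- suppressMessages(estimate_recombination(
    ds$pedigree, ds$genotypes, ds$marker_map, n_map_iterations = 4))
  est_len <- map_length(fit$map_male[[1L]])
  expect_lt(abs(est_len - 100) / 100, 0.15)
  est_len_f <- map_length(fit$map_female[[1L]])
  expect_lt(abs(est_len_f - 100) / 100, 0.15)
})

test_that("peeled genotype marginals match enumeration on a 4-member chain", {
  # A x B -> C, C x unknown -> E; near-deterministic regime (tiny error,
  # tight linkage) where the called factorised updates are exact
  eps <- 1e-6
  L <- 4L
  d <- rep(0.02, L - 1L)
  map <- genetic_map("1", 1e6 * seq_len(L), d)
  ped <- chain_pedigree()
  calls <- geno_matrix(A = c(2L, 2L, 0L, 0L),
                       B = c(0L, 0L, 0L, 0L),
                       C = c(1L, 1L, 0L, 0L),
                       E = c(1L, 1L, 0L, 0L))
  params <- peeling_params(genotype_error = eps, founder_prior = "uniform",
                           n_outer_cycles = 8L)
  fit <- suppressMessages(run_peeling_cycles(ped, calls, map = map,
                                             params = params,
                                             keep_genotype_probs = TRUE))
  oracle <- enum_chain(calls, map_r(map), map_r(map), eps,
                       prior = matrix(0.25, 4, L))
  for (id in c("A", "B", "C", "E")) {
    expect_lt(max(abs(fit$geno_prob[[id]] - oracle[[id]])), 1e-6)
  }
})
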