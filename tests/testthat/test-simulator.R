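test_that("designed landscape has flat middle, quadratic ends, exact total", {
  L <- 200L
  pos <- 1e5 * seq_len(L)
  m <- build_landscape(120, pos, end_elevation = 3)
  expect_equal(sum(m$d), 120, tolerance = 1e-12)
  # degenerate elevation 1 gives a flat map
  flat <- build_landscape(100, pos, end_elevation = 1)
  expect_equal(flat$d, rep(100 / (L - 1L), L - 1L), tolerance = 1e-12)
  # constant middle
  mid <- m$d[(0.35 * L):(0.65 * L)]
  expect_lt(diff(range(mid)), 1e-12)
  # continuity at the junction: the interval just outside the middle is
  # within one quadratic step of the middle rate
  c_mid <- mid[1L]
  junction <- m$d[floor(0.30 * L) - 1L]
  expect_lt(abs(junction - c_mid) / c_mid, 0.01)
  # ends elevated to ~3x the middle rate and monotone towards the ends
  expect_equal(m$d[1L] / c_mid, 3, tolerance = 0.01)
  left <- m$d[1:(0.25 * L)]
  expect_true(all(diff(left) <= 1e-12))
})

test_that("founder haplotypes show tunable allele association", {
  set.seed(15)
  # ld_decay = 0: independent loci; realised freq within a binomial CI
  f0 <- simulate_founders(400L, 50L, c(0.3, 0.7), ld_decay = 0)
  freq_hat <- colMeans(rbind(f0$hap1, f0$hap2))
  se <- sqrt(f0$freq * (1 - f0$freq) / 800)
  expect_gt(mean(abs(freq_hat - f0$freq) < 3 * se), 0.95)
  # ld_decay = 1: every haplotype constant along the chromosome
  f1 <- simulate_founders(50L, 30L, c(0.3, 0.7), ld_decay = 1)
  expect_true(all(apply(f1$hap1, 1, function(h) length(unique(h)) == 1L)))
  # ld_decay = 0.9: adjacent r2 exceeds 50-locus-apart r2
  f9 <- simulate_founders(500L, 60L, c(0.3, 0.7), ld_decay = 0.9)
  haps <- rbind(f9$hap1, f9$hap2)
  r2 <- function(j, k) suppressWarnings(stats::cor(haps[, j], haps[, k]))^2
  adj <- mean(vapply(1:59, function(j) r2(j, j + 1), numeric(1)), na.rm = TRUE)
  far <- mean(vapply(1:10, function(j) r2(j, j + 50), numeric(1)), na.rm = TRUE)
  expect_gt(adj, far)
})

test_that("gamete dropping matches the map moments", {
  set.seed(22)
  L <- 60L
  pos <- 1e6 * seq_len(L)
  # r = 0 everywhere: gametes are untouched parental haplotypes
  ped1 <- as_pedigree(data.frame(id = c("S", "D", "K"),
                                 sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
                                 sex = c("M", "F", "M")))
  fh <- simulate_founders(2L, L, c(0.2, 0.8), 0.5)
  zero <- genetic_map("1", pos, rep(0, L - 1L))
  g0 <- drop_gametes(ped1, fh, zero, zero)
  expect_true(all(g0$hap_pat["K", ] == fh$hap1[1, ]) ||
                all(g0$hap_pat["K", ] == fh$hap2[1, ]))
  expect_equal(g0$counts$n_crossovers, c(0L, 0L))

  # moment check over many meioses: mean crossovers ~ sum(r_j)
  big <- as_pedigree(data.frame(
    id = c("S", "D", sprintf("K%04d", 1:4000)),
    sire = c(NA, NA, rep("S", 4000)),
    dam = c(NA, NA, rep("D", 4000)),
    sex = c("M", "F", rep("F", 4000))))
  fh2 <- simulate_founders(2L, L, c(0.2, 0.8), 0.5)
  map_m <- build_landscape(80, pos)
  map_f <- genetic_map("1", pos, map_m$d * 1.3, sex = "F")
  gg <- drop_gametes(big, fh2, map_f, map_m)
  mu_m <- sum(map_r(map_m)); mu_f <- sum(map_r(map_f))
  got_m <- mean(gg$counts$n_crossovers[gg$counts$side == "pat"])
  got_f <- mean(gg$counts$n_crossovers[gg$counts$side == "mat"])
  expect_lt(abs(got_m - mu_m), 3 * sqrt(mu_m / 4000))
  expect_lt(abs(got_f - mu_f), 3 * sqrt(mu_f / 4000))
  # female/male ratio near 1.3 (in recombination-fraction units)
  expect_lt(abs(got_f / got_m - mu_f / mu_m), 0.1)

  # per-interval crossover frequencies match r_j (chi-square at alpha=.01)
  ev <- gg$events[gg$events$side == "pat", ]
  obs <- tabulate(ev$interval, nbins = L - 1L)
  expe <- 4000 * map_r(map_m)
  chi2 <- sum((obs - expe)^2 / (expe * (1 - map_r(map_m))))
  expect_lt(chi2, stats::qchisq(0.99, df = L - 1L))
})

test_that("genotyping observation model is faithful", {
  set.seed(33)
  n <- 600L; L <- 500L
  true_geno <- matrix(sample(0:2, n * L, replace = TRUE), n, L,
                      dimnames = list(sprintf("i%03d", 1:n), NULL))
  # error 0, all high: calls equal the truth
  g_hi <- apply_genotyping(true_geno, c(high = 1, low = 0, ungenotyped = 0),
                           genotype_error = 0)
  expect_identical(unname(g_hi[, ]), unname(true_geno))
  # mixed panels: ungenotyped rows all 9, low rows observe the fixed subset
  g_mix <- apply_genotyping(true_geno, c(high = .39, low = .51,
                                         ungenotyped = .10),
                            low_panel_fraction_of_loci = 0.25,
                            genotype_error = 0)
  pan <- attr(g_mix, "panel")
  expect_true(all(g_mix[pan == "ungenotyped", ] == 9L))
  low_loci <- attr(g_mix, "low_loci")
  expect_equal(length(low_loci), round(0.25 * L))
  lows <- which(pan == "low")
  expect_true(all(g_mix[lows, low_loci] != 9L))
  expect_true(all(g_mix[lows, -low_loci] == 9L))
  # flip count is binomial-consistent at error 0.01 over ~1e5 calls
  g_err <- apply_genotyping(true_geno, c(high = 1, low = 0, ungenotyped = 0),
                            genotype_error = 0.01)
  flips <- sum(g_err != true_geno)
  n_calls <- n * L
  expect_lt(abs(flips - 0.01 * n_calls), 3 * sqrt(n_calls * 0.01 * 0.99))
})

test_that("simulation is deterministic and Mendelian-consistent", {
  cfg <- sim_config(n_founders = 30, n_generations = 3, dams_per_gen = 6,
                    sires_per_gen = 2, offspring_per_dam = 4, n_loci = 50,
                    total_length_male = 70, seed = 99,
                    genotype_error = 0.01)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genotypes[, ], b$genotypes[, ])
  expect_identical(a$truth$counts, b$truth$counts)
  expect_identical(a$marker_map$pos, b$marker_map$pos)
  # Mendelian consistency of true genotypes in every trio
  idx <- ped_indices(a$pedigree)
  hp <- a$truth$hap_pat; hm <- a$truth$hap_mat
  for (i in which(idx$sire > 0L)) {
    s <- idx$sire[i]
    expect_true(all(hp[i, ] == hp[s, ] | hp[i, ] == hm[s, ]))
  }
  # truth crossover intervals lie in valid range
  expect_true(all(a$truth$events$interval >= 1 &
                    a$truth$events$interval <= 49))
})
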