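#' Simulation configuration
#'
#' Settings of the validation simulator. The defaults emulate the design of
#' the validation study: one chromosome with 1522 SNPs, a multi-generation
#' pedigree of a few thousand pigs with polygynous matings (each sire serves
#' many dams, each dam raises one litter), mixed-density genotyping with
#' 39% high-density / 51% low-density / 10% ungenotyped individuals, a
#' recombination landscape that is constant over the middle 30-70% of the
#' marker map with second-degree-polynomial high-rate ends, and a female map
#' 1.3 times longer than the male map.
#'
#' @param n_founders founder generation size.
#' @param n_generations total generations including founders.
#' @param dams_per_gen,sires_per_gen breeding females/males drawn per
#'   generation from the previous one.
#' @param offspring_per_dam litter size (one litter per dam).
#' @param n_loci markers on the chromosome.
#' @param chrom_length_bp physical chromosome length; marker positions are
#'   drawn uniformly and sorted.
#' @param total_length_male male genetic map length in cM.
#' @param female_ratio female/male map length ratio.
#' @param mid_lo,mid_hi relative map range of the constant middle.
#' @param end_elevation terminal-interval rate as a multiple of the middle
#'   rate.
#' @param allele_freq_range founder allele-frequency range (uniform draw per
#'   locus).
#' @param ld_decay probability that a founder haplotype copies its previous
#'   locus's allele rather than drawing from the locus frequency (adjacent-
#'   locus association).
#' @param panel_fractions proportions of high / low / ungenotyped
#'   individuals (must sum to 1).
#' @param low_panel_fraction_of_loci fraction of loci on the low-density
#'   panel (evenly spaced subset).
#' @param genotype_error probability that an observed call is flipped to a
#'   random wrong dosage.
#' @param seed integer seed; the whole simulation is deterministic given the
#'   configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 600L, n_generations = 5L,
                       dams_per_gen = 90L, sires_per_gen = 9L,
                       offspring_per_dam = 7L,
                       n_loci = 1522L, chrom_length_bp = 1e8,
                       total_length_male = 90, female_ratio = 1.3,
                       mid_lo = 0.30, mid_hi = 0.70, end_elevation = 3,
                       allele_freq_range = c(0.1, 0.9), ld_decay = 0.7,
                       panel_fractions = c(high = 0.39, low = 0.51,
                                           ungenotyped = 0.10),
                       low_panel_fraction_of_loci = 0.25,
                       genotype_error = 0, seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 2, n_loci >= 3,
            dams_per_gen >= 1, sires_per_gen >= 1, offspring_per_dam >= 1,
            total_length_male > 0, female_ratio > 0,
            0 < mid_lo, mid_lo < mid_hi, mid_hi < 1, end_elevation > 0,
            length(allele_freq_range) == 2,
            allele_freq_range[1] > 0, allele_freq_range[2] < 1,
            ld_decay >= 0, ld_decay <= 1,
            length(panel_fractions) == 3,
            abs(sum(panel_fractions) - 1) < 1e-9,
            low_panel_fraction_of_loci > 0, low_panel_fraction_of_loci <= 1,
            genotype_error >= 0, genotype_error < 1)
  cfg <- as.list(environment())
  cfg$n_founders <- as.integer(n_founders)
  cfg$n_generations <- as.integer(n_generations)
  cfg$n_loci <- as.integer(n_loci)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Build a designed recombination landscape
#'
#' Per-interval cM values with a constant rate `c` on intervals in the
#' relative range `[mid_lo, mid_hi)` of the map and, on each end segment, a
#' second-degree polynomial in relative position that equals `c` at the
#' inner junction (continuity) and rises monotonically to
#' `end_elevation * c` at the terminal interval:
#' `d(t) = c * (1 + (end_elevation - 1) * t^2)` with `t` in `[0, 1]` from
#' junction to chromosome end. The whole profile is rescaled so its sum is
#' exactly `total_length`.
#'
#' @param total_length chromosome length in cM.
#' @param positions marker bp positions (defines `L` and the map).
#' @param mid_lo,mid_hi,end_elevation landscape shape, see [sim_config()].
#' @param sex sex label of the returned map.
#' @param chromosome chromosome label of the returned map.
#' @return a [genetic_map()].
#' @export
build_landscape <- function(total_length, positions, mid_lo = 0.30,
                            mid_hi = 0.70, end_elevation = 3,
                            sex = "averaged", chromosome = "1") {
  L <- length(positions)
  stopifnot(L >= 3)
  n_int <- L - 1L
  lo <- mid_lo * L
  hi <- mid_hi * L
  # interval j sits between markers j and j+1; use its midpoint index
  mid <- seq_len(n_int) + 0.5
  d <- numeric(n_int)
  left <- mid < lo
  right <- mid >= hi
  # t = 0 at the junction, exactly 1 at the terminal interval midpoint
  t_left <- (lo - mid[left]) / (lo - 1.5)
  t_right <- (mid[right] - hi) / (n_int + 0.5 - hi)
  d[!left & !right] <- 1
  d[left] <- 1 + (end_elevation - 1) * t_left^2
  d[right] <- 1 + (end_elevation - 1) * t_right^2
  d <- d * total_length / sum(d)
  genetic_map(chromosome, positions, d, sex = sex)
}

#' Simulate founder haplotypes
#'
#' Draws per-locus allele frequencies uniformly in `allele_freq_range`, then
#' builds each founder haplotype left to right: the first locus is a
#' Bernoulli draw at the locus frequency and every later locus copies the
#' haplotype's previous allele with probability `ld_decay`, otherwise draws
#' fresh. This induces blockwise allele association that decays with marker
#' distance, standing in for population linkage disequilibrium.
#'
#' @param n_founders number of founders (two haplotypes each).
#' @param n_loci number of loci.
#' @param allele_freq_range,ld_decay see [sim_config()].
#' @return list with `hap1`, `hap2` (0/1 matrices, founders x loci) and
#'   `freq` (drawn allele frequencies).
#' @export
simulate_founders <- function(n_founders, n_loci,
                              allele_freq_range = c(0.1, 0.9),
                              ld_decay = 0.7) {
  freq <- stats::runif(n_loci, allele_freq_range[1], allele_freq_range[2])
  draw <- function() {
    h <- matrix(0L, n_founders, n_loci)
    h[, 1L] <- stats::rbinom(n_founders, 1L, freq[1L])
    if (n_loci > 1L) {
      for (j in 2L:n_loci) {
        copy <- stats::runif(n_founders) < ld_decay
        fresh <- stats::rbinom(n_founders, 1L, freq[j])
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      }
    }
    h
  }
  list(hap1 = draw(), hap2 = draw(), freq = freq)
}

# meiosis: recombine a parent's two haplotypes into one gamete.
# Returns the gamete and the crossover interval indices.
.meiosis <- function(h1, h2, r) {
  L <- length(h1)
  switches <- stats::runif(L - 1L) < r
  path <- cumsum(c(stats::rbinom(1L, 1L, 0.5), switches)) %% 2L
  list(gamete = ifelse(path == 0L, h1, h2),
       crossovers = which(switches))
}

#' Drop gametes through a pedigree
#'
#' Simulates every meiosis in the pedigree: the transmitted haplotype starts
#' on a random parental haplotype and switches in interval `j` with
#' probability `r_j` (independent across intervals, matching the Haldane/
#' no-interference model of the estimator). Paternal gametes use the male
#' map, maternal gametes the female map. Crossover locations are recorded as
#' truth.
#'
#' @param pedigree a `pedigree`; founders must be covered by `founder_haps`.
#' @param founder_haps founder haplotypes from [simulate_founders()], rows
#'   aligned with `founders(pedigree)`.
#' @param map_female,map_male [genetic_map()]s with `L - 1` intervals.
#' @return list with `hap_pat`, `hap_mat` (0/1 matrices over all pedigree
#'   members), `counts` (data.frame `id`, `parent_id`, `side`,
#'   `n_crossovers`) and `events` (data.frame `id`, `side`, `interval`).
#' @export
drop_gametes <- function(pedigree, founder_haps, map_female, map_male) {
  stopifnot(inherits(pedigree, "pedigree"))
  fid <- founders(pedigree)
  stopifnot(nrow(founder_haps$hap1) == length(fid))
  L <- ncol(founder_haps$hap1)
  r_f <- map_r(map_female)
  r_m <- map_r(map_male)
  stopifnot(length(r_f) == L - 1L, length(r_m) == L - 1L)
  n <- nrow(pedigree)
  hp <- matrix(0L, n, L, dimnames = list(pedigree$id, NULL))
  hm <- matrix(0L, n, L, dimnames = list(pedigree$id, NULL))
  hp[fid, ] <- founder_haps$hap1
  hm[fid, ] <- founder_haps$hap2
  idx <- ped_indices(pedigree)
  counts <- list(); events <- list()
  for (i in seq_len(n)) {
    si <- idx$sire[i]; di <- idx$dam[i]
    if (si == 0L && di == 0L) next
    if (si > 0L) {
      g <- .meiosis(hp[si, ], hm[si, ], r_m)
      hp[i, ] <- g$gamete
      counts[[length(counts) + 1L]] <- data.frame(
        id = pedigree$id[i], parent_id = pedigree$id[si], side = "pat",
        n_crossovers = length(g$crossovers), stringsAsFactors = FALSE)
      if (length(g$crossovers)) {
        events[[length(events) + 1L]] <- data.frame(
          id = pedigree$id[i], side = "pat", interval = g$crossovers,
          stringsAsFactors = FALSE)
      }
    } else {
      hp[i, ] <- stats::rbinom(L, 1L, 0.5)  # unknown sire: random alleles
    }
    if (di > 0L) {
      g <- .meiosis(hp[di, ], hm[di, ], r_f)
      hm[i, ] <- g$gamete
      counts[[length(counts) + 1L]] <- data.frame(
        id = pedigree$id[i], parent_id = pedigree$id[di], side = "mat",
        n_crossovers = length(g$crossovers), stringsAsFactors = FALSE)
      if (length(g$crossovers)) {
        events[[length(events) + 1L]] <- data.frame(
          id = pedigree$id[i], side = "mat", interval = g$crossovers,
          stringsAsFactors = FALSE)
      }
    } else {
      hm[i, ] <- stats::rbinom(L, 1L, 0.5)
    }
  }
  list(hap_pat = hp, hap_mat = hm,
       counts = do.call(rbind, counts),
       events = if (length(events)) do.call(rbind, events) else
         data.frame(id = character(0), side = character(0),
                    interval = integer(0)))
}

#' Apply mixed-density genotyping to true genotypes
#'
#' Assigns each individual a panel (high / low / ungenotyped) at the
#' configured fractions, observes all loci on the high-density panel and a
#' fixed evenly-spaced subset on the low-density panel, sets ungenotyped
#' individuals fully missing, and flips each observed call to a random wrong
#' dosage with probability `genotype_error`.
#'
#' @param true_geno true dosage matrix (individuals x loci, values 0/1/2).
#' @param panel_fractions,low_panel_fraction_of_loci,genotype_error see
#'   [sim_config()].
#' @return dosage matrix with codes `{0,1,2,9}` and attributes `panel` and
#'   `low_loci` (the low-panel locus indices).
#' @export
apply_genotyping <- function(true_geno,
                             panel_fractions = c(high = 0.39, low = 0.51,
                                                 ungenotyped = 0.10),
                             low_panel_fraction_of_loci = 0.25,
                             genotype_error = 0) {
  n <- nrow(true_geno); L <- ncol(true_geno)
  panel <- sample(c("high", "low", "ungenotyped"), n, replace = TRUE,
                  prob = panel_fractions)
  n_low <- max(2L, round(low_panel_fraction_of_loci * L))
  low_loci <- unique(round(seq(1L, L, length.out = n_low)))
  calls <- true_geno
  storage.mode(calls) <- "integer"
  calls[panel == "ungenotyped", ] <- 9L
  if (any(panel == "low")) {
    calls[panel == "low", setdiff(seq_len(L), low_loci)] <- 9L
  }
  if (genotype_error > 0) {
    obs <- which(calls != 9L)
    flip <- obs[stats::runif(length(obs)) < genotype_error]
    if (length(flip)) {
      wrong <- vapply(calls[flip], function(v) {
        sample(setdiff(0:2, v), 1L)
      }, integer(1))
      calls[flip] <- wrong
    }
  }
  attr(calls, "panel") <- stats::setNames(panel, rownames(true_geno))
  attr(calls, "low_loci") <- low_loci
  calls
}

# discrete-generation pedigree with polygynous matings
.sim_pedigree <- function(cfg) {
  make_ids <- function(g, k) sprintf("G%d_%04d", g, seq_len(k))
  balanced_sex <- function(k) sample(rep(c("M", "F"), length.out = k))
  id <- make_ids(1L, cfg$n_founders)
  sex <- balanced_sex(cfg$n_founders)
  rows <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                     sex = sex, line = "1", stringsAsFactors = FALSE)
  prev <- rows
  for (g in seq_len(cfg$n_generations - 1L) + 1L) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) < cfg$sires_per_gen ||
        length(females) < cfg$dams_per_gen) {
      stop("not enough candidate parents in generation ", g - 1L)
    }
    sires <- sample(males, cfg$sires_per_gen)
    dams <- sample(females, cfg$dams_per_gen)
    mate_sire <- sample(sires, cfg$dams_per_gen, replace = TRUE)
    k <- cfg$dams_per_gen * cfg$offspring_per_dam
    off <- data.frame(
      id = make_ids(g, k),
      sire = rep(mate_sire, each = cfg$offspring_per_dam),
      dam = rep(dams, each = cfg$offspring_per_dam),
      sex = balanced_sex(k), line = "1", stringsAsFactors = FALSE)
    rows <- rbind(rows, off)
    prev <- off
  }
  as_pedigree(rows)
}

#' Run the full validation simulation
#'
#' Generates a pedigree, founder haplotypes, sex-specific recombination
#' landscapes, every meiosis (with recorded truth) and mixed-density
#' genotype observations, reproducing the design of the validation study at
#' the configured scale. Fully deterministic given the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list of class `recomb_sim` with `pedigree`, `genotypes` (dosage
#'   matrix with `panel` attribute), `marker_map`, `map_female`, `map_male`
#'   (true maps), `truth` (list: `counts`, `events`, `hap_pat`, `hap_mat`),
#'   `founder_freq` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- .sim_pedigree(config)
  pos <- sort(sample.int(config$chrom_length_bp, config$n_loci))
  mm <- as_marker_map(data.frame(
    marker = sprintf("M%05d", seq_len(config$n_loci)),
    chrom = "1", pos = pos))
  map_m <- build_landscape(config$total_length_male, pos,
                           config$mid_lo, config$mid_hi,
                           config$end_elevation, sex = "M")
  map_f <- genetic_map("1", pos, map_m$d * config$female_ratio, sex = "F")
  fh <- simulate_founders(length(founders(ped)), config$n_loci,
                          config$allele_freq_range, config$ld_decay)
  drop <- drop_gametes(ped, fh, map_f, map_m)
  true_geno <- drop$hap_pat + drop$hap_mat
  dimnames(true_geno) <- list(ped$id, mm$marker)
  calls <- apply_genotyping(true_geno, config$panel_fractions,
                            config$low_panel_fraction_of_loci,
                            config$genotype_error)
  structure(list(pedigree = ped, genotypes = calls, marker_map = mm,
                 map_female = map_f, map_male = map_m,
                 truth = list(counts = drop$counts, events = drop$events,
                              hap_pat = drop$hap_pat, hap_mat = drop$hap_mat),
                 founder_freq = fh$freq, config = config),
            class = "recomb_sim")
}

#' @export
print.recomb_sim <- function(x, ...) {
  cat(sprintf(
    "recomb_sim: %d individuals, %d loci, male map %.1f cM, female map %.1f cM (seed %d)\n",
    nrow(x$pedigree), ncol(x$genotypes), map_length(x$map_male),
    map_length(x$map_female), x$config$seed))
  invisible(x)
}
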