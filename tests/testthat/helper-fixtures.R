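# Fixture builders (everything generated in code; no data files).

# genotype matrix with rownames from a list of integer vectors
geno_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  storage.mode(m) <- "integer"
  m
}

trio_pedigree <- function() {
  as_pedigree(data.frame(id = c("F1", "M1", "C1"),
                         sire = c(NA, NA, "F1"),
                         dam = c(NA, NA, "M1"),
                         sex = c("M", "F", "M")))
}

# sire-dam pair, their child, and a grandchild by an unknown mate
chain_pedigree <- function() {
  as_pedigree(data.frame(id = c("A", "B", "C", "E"),
                         sire = c(NA, NA, "A", "C"),
                         dam = c(NA, NA, "B", NA),
                         sex = c("M", "F", "M", "F")))
}

# a deterministic 5-generation pedigree of `n` individuals used for the
# brute-scan filter tests; sexes alternate, parents drawn from the previous
# generation round-robin
fixture_pedigree <- function(n = 200L, n_gen = 5L, seed = 42L) {
  set.seed(seed)
  per_gen <- ceiling(n / n_gen)
  rows <- NULL
  prev <- NULL
  total <- 0L
  for (g in seq_len(n_gen)) {
    k <- min(per_gen, n - total)
    ids <- sprintf("P%d_%03d", g, seq_len(k))
    sex <- rep(c("M", "F"), length.out = k)
    if (is.null(prev)) {
      rows <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                         sex = sex, line = "1")
    } else {
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      rows <- rbind(rows, data.frame(
        id = ids,
        sire = males[(seq_len(k) - 1L) %% length(males) + 1L],
        dam = females[(seq_len(k) - 1L) %% length(females) + 1L],
        sex = sex, line = "1"))
    }
    prev <- rows[rows$id %in% ids, ]
    total <- total + k
  }
  as_pedigree(rows)
}

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

tiny_marker_map <- function(L, chrom = "1", spacing = 1e6) {
  as_marker_map(data.frame(marker = sprintf("m%03d", seq_len(L)),
                           chrom = chrom, pos = spacing * seq_len(L)))
}
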