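#' Read a pedigree file
#'
#' Reads a whitespace-delimited pedigree with one line per individual:
#' `id sire dam [sex] [line]`. The token `"0"` denotes an unknown parent,
#' sex tokens are `F`, `M` or `0` (unknown). Parents that are referenced but
#' never listed are added implicitly as founders with unknown parents and
#' unknown sex. The pedigree is validated to be acyclic (no individual is its
#' own ancestor) and to have unique ids.
#'
#' @param path path to the pedigree file.
#' @return A `pedigree`: a data.frame with columns `id`, `sire`, `dam` (both
#'   `NA` when unknown), `sex` (`"F"`, `"M"` or `NA`) and `line`, ordered so
#'   that every parent precedes its offspring (generation order), with an
#'   attribute `order` giving that topological order over row indices.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf < 3L | nf > 5L)
  if (length(bad)) {
    stop(sprintf("pedigree line %d: expected 3-5 fields, got %d",
                 bad[1L], nf[bad[1L]]))
  }
  get <- function(k) vapply(toks, function(t) if (length(t) >= k) t[k] else "0",
                            character(1))
  id <- get(1); sire <- get(2); dam <- get(3); sex <- get(4); line <- get(5)
  if (anyDuplicated(id)) {
    stop("duplicate individual id in pedigree: ", id[duplicated(id)][1L])
  }
  bad_sex <- !(sex %in% c("F", "M", "0"))
  if (any(bad_sex)) {
    stop("invalid sex token (expected F, M or 0): ", sex[bad_sex][1L])
  }
  sex <- ifelse(sex == "0", NA_character_, sex)
  line <- ifelse(line == "0", "1", line)
  sire[sire == "0"] <- NA_character_
  dam[dam == "0"] <- NA_character_
  # implicit founders for referenced-but-unlisted parents
  parents <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(parents)) {
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
    sex <- c(rep(NA_character_, length(parents)), sex)
    line <- c(rep("1", length(parents)), line)
  }
  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex, line = line,
                    stringsAsFactors = FALSE)
  as_pedigree(ped)
}

#' Construct a pedigree from a data frame
#'
#' Validates acyclicity and parent references, sorts rows into generation
#' order (parents before offspring) and attaches the topological order.
#'
#' @param df data.frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`, `line`; `NA` marks unknown parents/sex.
#' @return A `pedigree` (see [read_pedigree()]).
#' @export
as_pedigree <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "sire", "dam") %in% names(df)))
  if (is.null(df$sex)) df$sex <- NA_character_
  if (is.null(df$line)) df$line <- "1"
  if (anyDuplicated(df$id)) {
    stop("duplicate individual id in pedigree: ", df$id[duplicated(df$id)][1L])
  }
  n <- nrow(df)
  si <- match(df$sire, df$id)
  di <- match(df$dam, df$id)
  miss_ref <- (!is.na(df$sire) & is.na(si)) | (!is.na(df$dam) & is.na(di))
  if (any(miss_ref)) {
    stop("parent of ", df$id[miss_ref][1L], " is not in the pedigree")
  }
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  ord <- .topo_order(si, di, df$id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "order") <- seq_len(n)
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn topological sort; errors naming an individual on a cycle.
.topo_order <- function(si, di, ids) {
  n <- length(ids)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        if (p == i) stop("pedigree cycle detected at individual ", ids[i])
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stuck <- setdiff(seq_len(n), ord)
    stop("pedigree cycle detected at individual ", ids[stuck[1L]])
  }
  ord
}

#' Parent row indices of a pedigree
#'
#' @param ped a `pedigree`.
#' @return list with integer vectors `sire` and `dam` (0 = unknown), aligned
#'   to pedigree rows.
#' @keywords internal
ped_indices <- function(ped) {
  si <- match(ped$sire, ped$id); si[is.na(si)] <- 0L
  di <- match(ped$dam, ped$id); di[is.na(di)] <- 0L
  list(sire = si, dam = di)
}

#' Founders of a pedigree
#'
#' @param ped a `pedigree`.
#' @return character vector of ids with both parents unknown.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[is.na(ped$sire) & is.na(ped$dam)]
}

#' Read a marker map file
#'
#' Whitespace-delimited file with one row per marker: `marker chromosome bp`.
#' Positions must be strictly increasing within each chromosome.
#'
#' @param path path to the map file.
#' @return data.frame of class `marker_map` with columns `marker`, `chrom`,
#'   `pos`, in file order.
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("marker map file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("marker", "chrom", "pos"))
  as_marker_map(df)
}

#' @rdname read_marker_map
#' @param df data.frame with columns `marker`, `chrom`, `pos`.
#' @export
as_marker_map <- function(df) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(df)))
  df$marker <- as.character(df$marker)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions not strictly increasing on chromosome ", ch)
    }
  }
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Read a genotype matrix file
#'
#' Whitespace-delimited file with one row per individual: an id followed by
#' `L` dosage codes in `{0, 1, 2, 9}` (9 = missing), one per marker of the
#' map, in map order. Individuals that are in the pedigree but absent from
#' the file are added with all calls missing and panel `"ungenotyped"`.
#'
#' Each individual is assigned a panel label from its missingness pattern:
#' `"ungenotyped"` when every call is 9, `"high"` when at least 90% of loci
#' are observed, `"low"` otherwise.
#'
#' @param path path to the genotype file.
#' @param map a `marker_map` defining the `L` loci and their order.
#' @param pedigree optional `pedigree`; if given, the returned matrix has one
#'   row per pedigree member (in pedigree order).
#' @return integer matrix (individuals x loci) with rownames = ids and
#'   attribute `panel` (named character vector).
#' @export
read_genotypes <- function(path, map, pedigree = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  stopifnot(inherits(map, "marker_map"))
  L <- nrow(map)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- which(keep)
  nf <- lengths(toks)
  bad <- which(nf != L + 1L)
  if (length(bad)) {
    stop(sprintf("genotype file line %d: expected %d codes for %s, got %d",
                 lineno[bad[1L]], L, toks[[bad[1L]]][1L], nf[bad[1L]] - 1L))
  }
  ids <- vapply(toks, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate individual in genotype file: ", ids[duplicated(ids)][1L])
  }
  calls <- matrix(NA_integer_, length(ids), L, dimnames = list(ids, map$marker))
  for (k in seq_along(toks)) {
    v <- suppressWarnings(as.integer(toks[[k]][-1L]))
    ok <- !is.na(v) & v %in% c(0L, 1L, 2L, 9L)
    if (!all(ok)) {
      stop(sprintf("genotype file line %d: invalid code '%s' (allowed: 0 1 2 9)",
                   lineno[k], toks[[k]][-1L][!ok][1L]))
    }
    calls[k, ] <- v
  }
  if (!is.null(pedigree)) {
    stopifnot(inherits(pedigree, "pedigree"))
    extra <- setdiff(ids, pedigree$id)
    if (length(extra)) {
      stop("genotyped individual not in pedigree: ", extra[1L])
    }
    full <- matrix(9L, nrow(pedigree), L,
                   dimnames = list(pedigree$id, map$marker))
    full[ids, ] <- calls
    calls <- full
  }
  attr(calls, "panel") <- classify_panels(calls)
  calls
}

#' Classify genotyping panels from missingness
#'
#' @param calls integer matrix of dosage codes with 9 = missing.
#' @param high_frac minimum observed fraction of loci to count as
#'   high-density.
#' @return named character vector over rows: `"high"`, `"low"` or
#'   `"ungenotyped"`.
#' @export
classify_panels <- function(calls, high_frac = 0.9) {
  obs <- rowMeans(calls != 9L)
  p <- ifelse(obs == 0, "ungenotyped", ifelse(obs >= high_frac, "high", "low"))
  stats::setNames(p, rownames(calls))
}

#' Write / read a genotype matrix
#'
#' Writes the dosage dialect read by [read_genotypes()].
#'
#' @param calls integer matrix of dosage codes.
#' @param path output path.
#' @export
write_genotypes <- function(calls, path) {
  df <- data.frame(id = rownames(calls), calls, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a pedigree file
#'
#' @param ped a `pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    id = ped$id,
    sire = ifelse(is.na(ped$sire), "0", ped$sire),
    dam = ifelse(is.na(ped$dam), "0", ped$dam),
    sex = ifelse(is.na(ped$sex), "0", ped$sex),
    line = ped$line
  )
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a marker map file
#'
#' @param map a `marker_map`.
#' @param path output path.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map[, c("marker", "chrom", "pos")], path, quote = FALSE,
                     sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an estimated genetic map as TSV
#'
#' One data row per marker interval with half-open bp coordinates
#' `[interval_start_bp, interval_end_bp)` plus a totals row per chromosome
#' (`type = "total"`), with columns `chromosome`, `interval_start_bp`,
#' `interval_end_bp`, `cM`, `cM_per_Mb`, `sex`, `type`.
#'
#' @param map a [genetic_map()] or list of them (one per chromosome).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  maps <- if (inherits(map, "genetic_map")) list(map) else map
  rows <- lapply(maps, function(m) {
    stopifnot(inherits(m, "genetic_map"))
    L <- length(m$positions)
    start <- m$positions[-L]; end <- m$positions[-1L]
    data <- data.frame(
      chromosome = m$chromosome,
      interval_start_bp = start, interval_end_bp = end,
      cM = m$d, cM_per_Mb = m$d / ((end - start) / 1e6),
      sex = m$sex, type = "interval"
    )
    total <- data.frame(
      chromosome = m$chromosome,
      interval_start_bp = m$positions[1L], interval_end_bp = m$positions[L],
      cM = sum(m$d),
      cM_per_Mb = sum(m$d) / ((m$positions[L] - m$positions[1L]) / 1e6),
      sex = m$sex, type = "total"
    )
    rbind(data, total)
  })
  out <- do.call(rbind, rows)
  utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a genetic map TSV written by [write_genetic_map()]
#'
#' @param path path to the TSV.
#' @return a list of [genetic_map()] objects, one per chromosome.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character",
                                         sex = "character"))
  need <- c("chromosome", "interval_start_bp", "interval_end_bp", "cM",
            "sex", "type")
  if (!all(need %in% names(df))) {
    stop("malformed genetic map file (missing columns): ", path)
  }
  df <- df[df$type == "interval", , drop = FALSE]
  lapply(split(df, df$chromosome), function(d) {
    genetic_map(d$chromosome[1L],
                c(d$interval_start_bp, d$interval_end_bp[nrow(d)]),
                d$cM, sex = d$sex[1L])
  })
}

#' Write per-gamete recombination estimates as TSV
#'
#' @param estimates data.frame with at least `id`, `parent_id`, `side`,
#'   `expected_crossovers`, `rate_cM_per_Mb`.
#' @param path output path.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.table(estimates, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Import PLINK text files
#'
#' Import shim for PLINK `.ped`/`.map` pairs; the data are normalised to the
#' package's primary dosage dialect. Per marker, the dosage counts the
#' lexicographically larger of the two observed alleles; `0 0` becomes
#' missing (9). Multi-allelic markers are rejected.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return list with `pedigree`, `genotypes` (dosage matrix with panel
#'   attribute) and `map` (`marker_map`).
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PLINK .ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("PLINK .map file not found: ", map_path)
  m <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) < 4L) stop("PLINK .map needs 4 columns (chrom id cM bp)")
  map <- as_marker_map(data.frame(marker = as.character(m[[2]]),
                                  chrom = as.character(m[[1]]),
                                  pos = as.numeric(m[[4]])))
  L <- nrow(map)
  p <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(p) != 6L + 2L * L) {
    stop(sprintf("PLINK .ped has %d columns, expected %d for %d markers",
                 ncol(p), 6L + 2L * L, L))
  }
  sex <- c("1" = "M", "2" = "F")[p[[5]]]
  ped <- as_pedigree(data.frame(
    id = p[[2]],
    sire = ifelse(p[[3]] == "0", NA, p[[3]]),
    dam = ifelse(p[[4]] == "0", NA, p[[4]]),
    sex = ifelse(is.na(sex), NA_character_, sex),
    line = p[[1]]
  ))
  a1 <- as.matrix(p[, 6L + 2L * seq_len(L) - 1L])
  a2 <- as.matrix(p[, 6L + 2L * seq_len(L)])
  calls <- matrix(9L, nrow(p), L, dimnames = list(p[[2]], map$marker))
  for (j in seq_len(L)) {
    obs <- a1[, j] != "0" & a2[, j] != "0"
    alleles <- sort(unique(c(a1[obs, j], a2[obs, j])))
    if (length(alleles) > 2L) {
      stop("multi-allelic marker not supported: ", map$marker[j])
    }
    if (!length(alleles)) next
    counted <- alleles[length(alleles)]
    calls[obs, j] <- (a1[obs, j] == counted) + (a2[obs, j] == counted)
  }
  calls <- calls[ped$id[ped$id %in% rownames(calls)], , drop = FALSE]
  attr(calls, "panel") <- classify_panels(calls)
  list(pedigree = ped, genotypes = calls, map = map)
}
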