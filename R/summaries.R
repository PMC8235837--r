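#' Windowed recombination landscape
#'
#' Apportions the cM of each marker interval to fixed-width physical windows
#' pro rata by bp overlap (windows are half-open `[start, end)`), and
#' reports the window rate in cM/Mb. Total cM is conserved exactly.
#'
#' @param map a [genetic_map()].
#' @param width window width in bp (default 1 Mb).
#' @return data.frame of class `landscape` with columns `chromosome`,
#'   `start_bp`, `end_bp`, `cM`, `rate` (cM/Mb).
#' @export
windowed_landscape <- function(map, width = 1e6) {
  stopifnot(inherits(map, "genetic_map"), width > 0)
  pos <- map$positions
  L <- length(pos)
  first_w <- floor(pos[1L] / width)
  last_w <- floor((pos[L] - 1) / width)
  starts <- (first_w:last_w) * width
  cM <- numeric(length(starts))
  istart <- pos[-L]; iend <- pos[-1L]
  for (j in seq_len(L - 1L)) {
    span <- iend[j] - istart[j]
    w1 <- floor(istart[j] / width); w2 <- floor((iend[j] - 1) / width)
    for (w in w1:w2) {
      lo <- max(istart[j], w * width)
      hi <- min(iend[j], (w + 1) * width)
      k <- w - first_w + 1L
      cM[k] <- cM[k] + map$d[j] * (hi - lo) / span
    }
  }
  data.frame(chromosome = map$chromosome, start_bp = starts,
             end_bp = starts + width, cM = cM, rate = cM / (width / 1e6))
}

#' Correlations between recombination landscapes
#'
#' Pearson correlations over shared windows (or marker intervals) for every
#' pair of (line, sex) groups, with the between-line-within-sex and
#' between-sex-within-line means summarised separately. Pairs with fewer
#' than three shared complete windows are reported as `NA`.
#'
#' @param rates numeric matrix, one column per group, one row per shared
#'   window or marker interval.
#' @param line,sex character vectors labelling the columns of `rates`.
#' @return list with `correlations` (full matrix),
#'   `between_line` (named vector of mean between-line correlation per sex)
#'   and `between_sex` (named vector of between-sex correlation per line).
#' @export
landscape_correlations <- function(rates, line, sex) {
  stopifnot(is.matrix(rates), ncol(rates) == length(line),
            length(line) == length(sex))
  k <- ncol(rates)
  cm <- matrix(NA_real_, k, k)
  grp <- paste(line, sex, sep = ":")
  dimnames(cm) <- list(grp, grp)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- stats::complete.cases(rates[, c(i, j)])
      if (sum(ok) >= 3L &&
          stats::sd(rates[ok, i]) > 0 && stats::sd(rates[ok, j]) > 0) {
        cm[i, j] <- if (i == j) 1 else stats::cor(rates[ok, i], rates[ok, j])
      }
    }
  }
  between_line <- vapply(unique(sex), function(s) {
    cols <- which(sex == s)
    if (length(cols) < 2L) return(NA_real_)
    pairs <- utils::combn(cols, 2L)
    mean(cm[t(pairs)], na.rm = TRUE)
  }, numeric(1))
  between_sex <- vapply(unique(line), function(l) {
    cols <- which(line == l)
    if (length(cols) != 2L) return(NA_real_)
    cm[cols[1L], cols[2L]]
  }, numeric(1))
  list(correlations = cm,
       between_line = stats::setNames(between_line, unique(sex)),
       between_sex = stats::setNames(between_sex, unique(line)))
}

#' Linear model for genetic map length
#'
#' Ordinary least-squares fit of per-chromosome crossover counts with fixed
#' effects for line and chromosome (one sex at a time). The per-line total
#' map length is the sum over chromosomes of the fitted cell means, with a
#' normal-theory 95% confidence interval from the OLS covariance.
#'
#' @param counts numeric vector of crossover counts, one per observed
#'   (gamete, chromosome) record.
#' @param line,chromosome factors (or vectors) aligned with `counts`.
#' @return list with `model` (the `lm` fit) and `lengths` (data.frame with
#'   `line`, `morgans`, `lower`, `upper`; lengths in Morgan = expected
#'   crossovers summed over chromosomes).
#' @export
map_length_model <- function(counts, line, chromosome) {
  df <- data.frame(counts = counts, line = factor(line),
                   chromosome = factor(chromosome))
  form <- if (nlevels(df$line) > 1L && nlevels(df$chromosome) > 1L) {
    counts ~ line + chromosome
  } else if (nlevels(df$line) > 1L) {
    counts ~ line
  } else if (nlevels(df$chromosome) > 1L) {
    counts ~ chromosome
  } else {
    counts ~ 1
  }
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient map length model; confounded terms: ",
         paste(bad, collapse = ", "))
  }
  lines <- levels(df$line)
  chroms <- levels(df$chromosome)
  V <- stats::vcov(fit)
  res <- lapply(lines, function(l) {
    grid <- data.frame(line = factor(l, levels = lines),
                       chromosome = factor(chroms, levels = chroms))
    X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
    xc <- colSums(X)  # sum of cell means over chromosomes
    est <- sum(xc * stats::coef(fit))
    se <- sqrt(drop(t(xc) %*% V %*% xc))
    data.frame(line = l, morgans = est,
               lower = est - 1.96 * se, upper = est + 1.96 * se)
  })
  list(model = fit, lengths = do.call(rbind, res))
}

#' Smooth a per-marker rate series
#'
#' Averages values in marker windows: block means over non-overlapping
#' windows (default; a trailing partial block is averaged over its own
#' length) or centred rolling means.
#'
#' @param values numeric series (one value per marker or interval).
#' @param window window size in markers (default 50).
#' @param mode `"non_overlapping"` or `"rolling"`.
#' @return numeric vector: one value per block (`non_overlapping`) or per
#'   input position (`rolling`; positions whose window falls off the series
#'   are averaged over the available part).
#' @export
smooth_landscape <- function(values, window = 50L,
                             mode = c("non_overlapping", "rolling")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), window >= 1, length(values) >= window)
  n <- length(values)
  if (mode == "non_overlapping") {
    blocks <- ceiling(seq_len(n) / window)
    as.numeric(tapply(values, blocks, mean))
  } else {
    half_lo <- floor((window - 1) / 2)
    half_hi <- window - 1 - half_lo
    vapply(seq_len(n), function(i) {
      mean(values[max(1L, i - half_lo):min(n, i + half_hi)])
    }, numeric(1))
  }
}

#' Accuracy of recombination estimates against simulation truth
#'
#' Given the recorded truth of a simulation and the per-gamete estimates,
#' computes (1) the Pearson correlation between true and estimated
#' crossover counts per gamete, by parent group (dams = maternal gametes,
#' sires = paternal gametes), and (2) the correlation between the true and
#' estimated per-interval landscape, raw and smoothed in non-overlapping
#' 50-SNP windows. Zero-variance inputs yield `NA`.
#'
#' @param truth simulation truth as produced by [simulate_dataset()] (list
#'   with `counts`: data.frame `id`, `side`, `n_crossovers`; and `events`:
#'   data.frame `id`, `side`, `interval`).
#' @param estimates per-gamete estimates (`id`, `side`,
#'   `expected_crossovers`) as from [estimate_recombination()].
#' @param exc_by_interval matrix of per-gamete per-interval expected
#'   crossovers used for the landscape comparison (rows named by id); give
#'   the row-bound `exc_pat`/`exc_mat` of the fit.
#' @param ids optional ids to restrict the per-gamete comparison to (e.g.
#'   the QC-retained set); defaults to all ids present in both inputs.
#' @param window smoothing window in SNPs (default 50).
#' @param aggregate `"gamete"` correlates true and estimated counts across
#'   individual gametes; `"parent"` first averages each parent's gametes
#'   (the repeated-observation phenotype attached to dams and sires, whose
#'   accuracy differs because a sire's many offspring share the sire's
#'   phase errors while a dam's few do not).
#' @return list with `per_individual` (named vector: `dams`, `sires`),
#'   `landscape` (named vector: `raw`, `smoothed`), `n_groups` (gametes or
#'   parents entering each correlation) and the underlying series.
#' @export
accuracy_metrics <- function(truth, estimates, exc_by_interval = NULL,
                             ids = NULL, window = 50L,
                             aggregate = c("gamete", "parent")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("id", "side", "n_crossovers") %in% names(truth$counts)),
            all(c("id", "side", "expected_crossovers") %in% names(estimates)))
  tc <- truth$counts
  est <- estimates[, c("id", "side", "expected_crossovers")]
  m <- merge(tc, est, by = c("id", "side"))
  if (!is.null(ids)) m <- m[m$id %in% ids, , drop = FALSE]
  safe_cor <- function(x, y) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  group_cor <- function(side) {
    ms <- m[m$side == side, , drop = FALSE]
    if (aggregate == "parent") {
      t_bar <- tapply(ms$n_crossovers, ms$parent_id, mean)
      e_bar <- tapply(ms$expected_crossovers, ms$parent_id, mean)
      c(safe_cor(as.numeric(t_bar), as.numeric(e_bar)), length(t_bar))
    } else {
      c(safe_cor(ms$n_crossovers, ms$expected_crossovers), nrow(ms))
    }
  }
  gd <- group_cor("mat"); gs <- group_cor("pat")
  per_ind <- c(dams = gd[1L], sires = gs[1L])
  n_groups <- c(dams = gd[2L], sires = gs[2L])
  landscape <- c(raw = NA_real_, smoothed = NA_real_)
  true_by_int <- est_by_int <- NULL
  if (!is.null(exc_by_interval)) {
    keep_ids <- unique(m$id)
    ev <- truth$events[truth$events$id %in% keep_ids, , drop = FALSE]
    n_int <- ncol(exc_by_interval)
    true_by_int <- tabulate(ev$interval, nbins = n_int)
    rows <- rownames(exc_by_interval) %in% keep_ids
    est_by_int <- colSums(exc_by_interval[rows, , drop = FALSE], na.rm = TRUE)
    landscape["raw"] <- safe_cor(true_by_int, est_by_int)
    if (n_int >= window) {
      landscape["smoothed"] <- safe_cor(
        smooth_landscape(true_by_int, window),
        smooth_landscape(est_by_int, window))
    }
  }
  list(per_individual = per_ind, landscape = landscape, n_groups = n_groups,
       true_by_interval = true_by_int, est_by_interval = est_by_int)
}
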