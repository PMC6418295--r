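#' Filter a RIL SNP call table
#'
#' Applies the population SNP filters: locus quality must strictly exceed
#' `min_qual`; loci falling in any 10 bp window containing `max_per_10bp` or
#' more loci are dropped (SNP-dense windows are untrustworthy); calls not
#' matching a parental allele are recoded to missing and loci that are
#' heterozygous in every genotyped line are dropped; loci genotyped in fewer
#' than `min_lines` lines are dropped.
#'
#' @param table SNP table: columns `chrom`, `pos` (strictly increasing per
#'   chromosome), optional `qual`, optional `allele_a`/`allele_b` (parental
#'   nucleotides; when present, calls are raw nucleotides and are recoded),
#'   then one column per line with calls in A/B/H/- (or nucleotides).
#' @param min_qual minimum locus quality (strict `>`; default 30).
#' @param max_per_10bp loci per 10 bp window triggering removal (default 3).
#' @param min_lines minimum genotyped lines per locus (default 20).
#' @return filtered table with calls recoded to A/B/H/-.
#' @export
filter_snps <- function(table, min_qual = 30, max_per_10bp = 3, min_lines = 20) {
  meta_cols <- intersect(c("chrom", "pos", "qual", "allele_a", "allele_b"),
                         names(table))
  line_cols <- setdiff(names(table), meta_cols)
  out <- table
  if ("allele_a" %in% meta_cols) {
    for (lc in line_cols) {
      x <- out[[lc]]
      recoded <- dplyr::case_when(
        x == out$allele_a ~ "A",
        x == out$allele_b ~ "B",
        x %in% c("H", "h") ~ "H",
        TRUE ~ "-")
      out[[lc]] <- recoded
    }
  }
  if ("qual" %in% names(out)) out <- filter(out, .data$qual > min_qual)
  # density rule: any 10 bp window (span <= 9 bp) holding >= max_per_10bp loci
  keep <- rep(TRUE, nrow(out))
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    pos <- out$pos[idx]
    n <- length(pos)
    if (n >= max_per_10bp) {
      for (s in seq_len(n - max_per_10bp + 1)) {
        e <- s + max_per_10bp - 1
        if (pos[e] - pos[s] <= 9) keep[idx[s:e]] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  calls <- as.matrix(out[, line_cols, drop = FALSE])
  genotyped <- rowSums(calls != "-" & !is.na(calls))
  informative <- rowSums(matrix(calls %in% c("A", "B"), nrow(calls)))
  out <- out[genotyped >= min_lines & informative > 0, , drop = FALSE]
  out
}

#' Sliding-window genotype calls along one chromosome for one line
#'
#' Windows of `window` consecutive SNP calls advance by `step`; a window is
#' called A or B when at least a `majority`/`window` share of its
#' non-missing calls agree (11 of 15 by default), H otherwise, and missing
#' when fewer than `min_informative` calls are non-missing. A chromosome
#' with fewer loci than `window` is called as a single whole-chromosome
#' window.
#'
#' @param calls character vector of calls (A/B/H/-) ordered by position.
#' @param positions bp positions of the calls.
#' @param window window size in SNPs (default 15).
#' @param step step size in SNPs (default 1).
#' @param majority agreeing calls required in a full window (default 11;
#'   applied proportionally to the non-missing count).
#' @param min_informative minimum non-missing calls per window (default 5).
#' @return tibble: `win`, `pos_start`, `pos_end`, `pos_mid`, `call`.
#' @export
sliding_window_genotypes <- function(calls, positions, window = 15, step = 1,
                                     majority = 11, min_informative = 5) {
  n <- length(calls)
  if (n < window) {
    nA <- sum(calls == "A"); nB <- sum(calls == "B")
    inf <- nA + nB
    call <- window_call(nA, nB, inf, majority / window, min_informative)
    return(tibble(win = 1L, pos_start = positions[1], pos_end = positions[n],
                  pos_mid = (positions[1] + positions[n]) / 2, call = call))
  }
  starts <- seq(1, n - window + 1, by = step)
  isA <- cumsum(c(0, calls == "A"))
  isB <- cumsum(c(0, calls == "B"))
  nA <- isA[starts + window] - isA[starts]
  nB <- isB[starts + window] - isB[starts]
  inf <- nA + nB
  thr <- ceiling(majority / window * inf)
  call <- rep("H", length(starts))
  call[nA >= thr & nA > nB] <- "A"
  call[nB >= thr & nB > nA] <- "B"
  call[inf < min_informative] <- "-"
  tibble(win = seq_along(starts),
         pos_start = positions[starts],
         pos_end = positions[starts + window - 1],
         pos_mid = (positions[starts] + positions[starts + window - 1]) / 2,
         call = call)
}

window_call <- function(nA, nB, inf, frac, min_informative) {
  if (inf < min_informative) return("-")
  thr <- ceiling(frac * inf)
  if (nA >= thr && nA > nB) "A" else if (nB >= thr && nB > nA) "B" else "H"
}

#' Detect recombination breakpoints from window genotype calls
#'
#' A breakpoint is emitted between the last window of one homozygous state
#' and the first window of the other; the uncertainty interval spans the
#' transition region including any intervening H or missing windows, and
#' the point estimate is the interval midpoint. Isolated H runs without a
#' state change emit nothing.
#'
#' @param window_calls tibble from [sliding_window_genotypes()].
#' @return tibble: `from`, `to` (states), `interval_start`, `interval_end`,
#'   `pos` (midpoint).
#' @export
detect_breakpoints <- function(window_calls) {
  hom <- filter(window_calls, .data$call %in% c("A", "B"))
  empty <- tibble(from = character(), to = character(),
                  interval_start = numeric(), interval_end = numeric(),
                  pos = numeric())
  if (nrow(hom) < 2) return(empty)
  change <- which(hom$call[-1] != hom$call[-nrow(hom)])
  if (length(change) == 0) return(empty)
  tibble(from = hom$call[change], to = hom$call[change + 1],
         interval_start = hom$pos_mid[change],
         interval_end = hom$pos_mid[change + 1],
         pos = (hom$pos_mid[change] + hom$pos_mid[change + 1]) / 2)
}

#' Build a bin map from per-line breakpoints
#'
#' The chromosome is partitioned on a fixed grid anchored at position 1;
#' each line's breakpoints are snapped to the nearest grid boundary, giving
#' piecewise-constant line genotypes per grid cell; adjacent cells whose
#' genotype columns are identical across all lines are merged into bins.
#' With no breakpoints a chromosome is a single bin; with breakpoints in
#' every cell the bins equal the grid.
#'
#' @param breakpoints tibble: `line`, `chrom`, `pos` (point estimates in bp).
#' @param line_states tibble: `line`, `chrom`, `state` — each line's
#'   genotype at the chromosome start (A/B).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param interval grid interval in bp (default 50 Kb).
#' @return list: `bins` (tibble `chrom`, `start`, `end`, `bin`), `genotypes`
#'   (matrix bins x lines), class `bin_map`.
#' @export
build_binmap <- function(breakpoints, line_states, chrom_lengths,
                         interval = 5e4) {
  lines <- sort(unique(line_states$line))
  bin_rows <- list(); geno_rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    bnd <- seq(interval, len - 1, by = interval)
    cell_start <- c(1, bnd + 1)
    cell_end <- c(bnd, len)
    n_cell <- length(cell_start)
    G <- matrix("-", n_cell, length(lines), dimnames = list(NULL, lines))
    for (li in seq_along(lines)) {
      st <- line_states$state[line_states$line == lines[li] &
                                line_states$chrom == ch]
      if (length(st) == 0 || !st[1] %in% c("A", "B")) next
      st <- st[1]
      if (length(bnd) == 0) { G[, li] <- st; next }
      bp <- sort(breakpoints$pos[breakpoints$line == lines[li] &
                                   breakpoints$chrom == ch])
      # half-up snapping (round() would banker-round exact cell midpoints)
      bp_snap <- unique(pmin(pmax(floor(bp / interval + 0.5) * interval,
                                  interval), max(bnd)))
      # state per cell: flips accumulate at snapped boundaries
      flips <- findInterval(cell_start - 1, bp_snap)
      states <- rep(st, n_cell)
      flip_idx <- flips %% 2 == 1
      states[flip_idx] <- if (st == "A") "B" else "A"
      G[, li] <- states
    }
    key <- apply(G, 1, paste, collapse = "")
    grp <- cumsum(c(TRUE, key[-1] != key[-n_cell]))
    first_i <- which(!duplicated(grp))
    last_i <- c(first_i[-1] - 1L, n_cell)
    bin_rows[[ch]] <- tibble(chrom = ch,
                             start = cell_start[first_i],
                             end = cell_end[last_i])
    geno_rows[[ch]] <- G[first_i, , drop = FALSE]
  }
  bins <- bind_rows(bin_rows)
  bins$bin <- seq_len(nrow(bins))
  res <- list(bins = bins, genotypes = do.call(rbind, geno_rows),
              lines = lines, interval = interval)
  class(res) <- "bin_map"
  res
}

#' @export
print.bin_map <- function(x, ...) {
  cat(sprintf("<bin_map> %d bins x %d lines over %d chromosome(s)\n",
              nrow(x$bins), length(x$lines), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Map-distance functions
#'
#' Kosambi and Haldane map functions converting a recombination fraction to
#' centiMorgans: `kosambi(r) = 25 ln((1+2r)/(1-2r))`,
#' `haldane(r) = -50 ln(1-2r)`. Both tend to `100 r` as `r -> 0`.
#'
#' @param r recombination fraction in [0, 0.5).
#' @return distance in cM.
#' @export
kosambi_cM <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' @rdname kosambi_cM
#' @export
haldane_cM <- function(r) -50 * log(1 - 2 * r)

#' Genetic distances along a bin map
#'
#' Recombination fractions between adjacent bins are estimated from
#' genotype discordance across lines (H and missing calls excluded). For a
#' selfed-RIL population the observed discordance R is map-expanded; with
#' `correct_ril = TRUE` (default) it is converted back to the meiotic
#' recombination fraction `r = R / (2 (1 - R))` before applying the map
#' function, which is how standard RIL map software treats selfed lines.
#' Fractions at or above 0.5 are capped at 0.4999 with a warning.
#'
#' @param binmap a `bin_map` from [build_binmap()].
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param correct_ril apply the selfed-RIL correction (default TRUE).
#' @return `binmap` with `bins` gaining `r_adj` (to previous bin), `cM`
#'   (cumulative genetic position per chromosome).
#' @export
genetic_distances <- function(binmap, mapping_function = c("kosambi", "haldane"),
                              correct_ril = TRUE) {
  mapping_function <- match.arg(mapping_function)
  mf <- if (mapping_function == "kosambi") kosambi_cM else haldane_cM
  bins <- binmap$bins
  G <- binmap$genotypes
  r_adj <- rep(NA_real_, nrow(bins))
  cM <- rep(0, nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    pos <- 0
    for (k in seq_along(idx)[-1]) {
      g1 <- G[idx[k - 1], ]; g2 <- G[idx[k], ]
      ok <- g1 %in% c("A", "B") & g2 %in% c("A", "B")
      R <- if (any(ok)) mean(g1[ok] != g2[ok]) else 0
      if (R >= 0.5) {
        warn(sprintf("recombination fraction %.3f capped at 0.4999 (bins %d-%d)",
                     R, idx[k - 1], idx[k]))
        R <- 0.4999
      }
      r <- if (correct_ril) R / (2 * (1 - R)) else R
      r <- min(r, 0.4999)
      r_adj[idx[k]] <- r
      pos <- pos + mf(r)
      cM[idx[k]] <- pos
    }
  }
  binmap$bins$r_adj <- r_adj
  binmap$bins$cM <- cM
  binmap$mapping_function <- mapping_function
  binmap
}

inv_map <- function(d_cM, mapping_function) {
  if (mapping_function == "kosambi") {
    x <- exp(d_cM / 25)
    (x - 1) / (2 * (x + 1))
  } else {
    (1 - exp(-d_cM / 50)) / 2
  }
}

#' Single-QTL LOD scan over a bin map
#'
#' Haley-Knott style interval mapping: at each grid position (0.5 cM step by
#' default) the expected genotype given the flanking bin genotypes is
#' regressed on the phenotype and `LOD = (n/2) log10(RSS0 / RSS1)`.
#' Composite mode residualizes the phenotype on forward-selected marker
#' cofactors outside a `window_cM` exclusion window around the scan
#' position before computing the LOD.
#'
#' @param binmap a `bin_map` with genetic positions (see
#'   [genetic_distances()]).
#' @param phenotype tibble (`line`, `phenotype`) or named numeric vector;
#'   lines with missing phenotype are excluded.
#' @param step_cM scan step (default 0.5 cM).
#' @param window_cM cofactor exclusion window for composite mode (default
#'   10 cM).
#' @param mode `"interval_mapping"` (default) or `"composite"`.
#' @param n_cofactors cofactors for composite mode (default 3).
#' @return a `qtl_scan` object: tibble `result` (`chrom`, `pos_cM`, `lod`)
#'   plus metadata; see [tidy.qtl_scan()], [call_qtl()],
#'   [permutation_threshold()].
#' @export
lod_scan <- function(binmap, phenotype, step_cM = 0.5, window_cM = 10,
                     mode = c("interval_mapping", "composite"),
                     n_cofactors = 3) {
  mode <- match.arg(mode)
  assert_that(!is.null(binmap$bins$cM),
              "run genetic_distances() on the bin map first")
  ph <- as_phenotype(phenotype, binmap$lines)
  use <- !is.na(ph)
  y <- ph[use]
  n <- sum(use)
  X <- genotype_design(binmap)[use, , drop = FALSE]
  grid <- scan_grid(binmap, step_cM)
  E <- expected_genotype_matrix(binmap, grid, X)
  lod <- lod_from_design(E, y)
  if (mode == "composite" && n_cofactors > 0) {
    lod <- composite_lod(binmap, grid, E, X, y, window_cM, n_cofactors)
  }
  res <- list(result = tibble(chrom = grid$chrom, pos_cM = grid$pos_cM,
                              lod = lod),
              n = n, mode = mode, step_cM = step_cM, window_cM = window_cM,
              threshold = NA_real_, binmap = binmap)
  class(res) <- "qtl_scan"
  res
}

as_phenotype <- function(phenotype, lines) {
  if (is.data.frame(phenotype)) {
    ph <- phenotype$phenotype[match(lines, phenotype$line)]
  } else if (!is.null(names(phenotype))) {
    ph <- phenotype[lines]
  } else {
    ph <- phenotype
  }
  as.numeric(ph)
}

# bins x lines numeric coding A=+1, B=-1, H/-=NA, transposed to lines x bins
genotype_design <- function(binmap) {
  G <- binmap$genotypes
  X <- matrix(NA_real_, ncol(G), nrow(G))
  X[t(G) == "A"] <- 1
  X[t(G) == "B"] <- -1
  X
}

scan_grid <- function(binmap, step_cM) {
  rows <- list()
  for (ch in unique(binmap$bins$chrom)) {
    cm <- binmap$bins$cM[binmap$bins$chrom == ch]
    pos <- seq(0, max(cm), by = step_cM)
    if (max(cm) > max(pos)) pos <- c(pos, max(cm))
    rows[[ch]] <- tibble(chrom = ch, pos_cM = pos)
  }
  bind_rows(rows)
}

# expected genotype at each grid position from flanking bin genotypes
expected_genotype_matrix <- function(binmap, grid, X) {
  mfname <- binmap$mapping_function %||% "kosambi"
  n <- nrow(X)
  E <- matrix(0, n, nrow(grid))
  for (ch in unique(grid$chrom)) {
    bi <- which(binmap$bins$chrom == ch)
    cm <- binmap$bins$cM[bi]
    gi <- which(grid$chrom == ch)
    for (g in gi) {
      p <- grid$pos_cM[g]
      l_rel <- findInterval(p, cm)
      r_rel <- l_rel + 1
      has_l <- l_rel >= 1
      has_r <- r_rel <= length(bi)
      xl <- if (has_l) X[, bi[l_rel]] else rep(NA_real_, n)
      xr <- if (has_r) X[, bi[r_rel]] else rep(NA_real_, n)
      dl <- if (has_l) p - cm[l_rel] else NA_real_
      dr <- if (has_r) cm[r_rel] - p else NA_real_
      E[, g] <- expected_genotype(xl, xr, dl, dr, mfname)
    }
  }
  E
}

# conditional expectation of +-1 genotype between two flanking markers
expected_genotype <- function(xl, xr, dl, dr, mfname) {
  n <- length(xl)
  rl <- if (!is.na(dl)) inv_map(dl, mfname) else NA_real_
  rr <- if (!is.na(dr)) inv_map(dr, mfname) else NA_real_
  e <- numeric(n)
  both <- !is.na(xl) & !is.na(xr) & !is.na(rl) & !is.na(rr)
  onlyl <- !is.na(xl) & !both & !is.na(rl)
  onlyr <- !is.na(xr) & !both & !is.na(rr)
  if (any(both)) {
    # P(flanks | g) products for g = +1 / -1, haploid-equivalent transmission
    pl_match <- (1 - rl); pl_mis <- rl
    pr_match <- (1 - rr); pr_mis <- rr
    pA <- ifelse(xl[both] == 1, pl_match, pl_mis) *
      ifelse(xr[both] == 1, pr_match, pr_mis)
    pB <- ifelse(xl[both] == -1, pl_match, pl_mis) *
      ifelse(xr[both] == -1, pr_match, pr_mis)
    e[both] <- (pA - pB) / (pA + pB)
  }
  e[onlyl] <- xl[onlyl] * (1 - 2 * rl)
  e[onlyr] <- xr[onlyr] * (1 - 2 * rr)
  e
}

# vectorized single-predictor LOD over all columns of E
lod_from_design <- function(E, y) {
  n <- length(y)
  yc <- y - mean(y)
  Ec <- sweep(E, 2, colMeans(E))
  sy <- sqrt(sum(yc^2))
  se <- sqrt(colSums(Ec^2))
  r <- as.numeric(crossprod(Ec, yc)) / (se * sy)
  r[!is.finite(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  (n / 2) * log10(1 / (1 - r2))
}

composite_lod <- function(binmap, grid, E, X, y, window_cM, n_cofactors) {
  # forward-select cofactor bins by marginal correlation
  Xb <- X; Xb[is.na(Xb)] <- 0
  cors <- abs(cor(Xb, y))
  sel <- integer(0)
  resid <- y
  for (k in seq_len(min(n_cofactors, ncol(Xb)))) {
    cc <- abs(cor(Xb, resid)); cc[sel] <- 0
    pick <- which.max(cc)
    if (cc[pick] < 0.1) break
    sel <- c(sel, pick)
    fit <- stats::lm.fit(cbind(1, Xb[, sel, drop = FALSE]), y)
    resid <- fit$residuals
  }
  if (length(sel) == 0) return(lod_from_design(E, y))
  bin_chrom <- binmap$bins$chrom
  bin_cm <- binmap$bins$cM
  vapply(seq_len(nrow(grid)), function(g) {
    keep <- sel[!(bin_chrom[sel] == grid$chrom[g] &
                    abs(bin_cm[sel] - grid$pos_cM[g]) < window_cM)]
    yr <- if (length(keep)) {
      stats::lm.fit(cbind(1, Xb[, keep, drop = FALSE]), y)$residuals
    } else y
    lod_from_design(E[, g, drop = FALSE], yr)
  }, numeric(1))
}

#' Permutation threshold for a genome-wide LOD scan
#'
#' Permutes phenotype labels `n_perm` times, records the genome-wide
#' maximum LOD of each permuted scan, and returns the empirical
#' `(1 - alpha)` quantile as the significance threshold. Deterministic
#' given `seed`.
#'
#' @inheritParams lod_scan
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return threshold (numeric scalar), with the null max-LOD distribution as
#'   attribute `"null_max_lod"`.
#' @export
permutation_threshold <- function(binmap, phenotype, n_perm = 1000,
                                  alpha = 0.05, step_cM = 0.5, seed = NULL) {
  assert_that(n_perm >= 100, "`n_perm` must be >= 100")
  ph <- as_phenotype(phenotype, binmap$lines)
  use <- !is.na(ph)
  y <- ph[use]
  X <- genotype_design(binmap)[use, , drop = FALSE]
  grid <- scan_grid(binmap, step_cM)
  E <- expected_genotype_matrix(binmap, grid, X)
  n <- length(y)
  Ec <- sweep(E, 2, colMeans(E))
  se <- sqrt(colSums(Ec^2))
  maxlod <- with_seed_or_not(seed, {
    P <- replicate(n_perm, sample(y))
    Pc <- sweep(P, 2, colMeans(P))
    sp <- sqrt(colSums(Pc^2))
    R <- crossprod(Ec, Pc) / outer(se, sp)
    R[!is.finite(R)] <- 0
    r2max <- apply(pmin(R^2, 1 - 1e-12), 2, max)
    (n / 2) * log10(1 / (1 - r2max))
  })
  k <- max(1L, ceiling((1 - alpha) * n_perm))
  thr <- sort(maxlod)[k]
  attr(thr, "null_max_lod") <- maxlod
  thr
}

#' Call QTL intervals from a thresholded scan
#'
#' Maximal contiguous runs of LOD above the threshold are reported with
#' their peak and a 1.5-LOD support interval (positions where LOD stays
#' within 1.5 of the peak, extended outward from the peak within the
#' chromosome).
#'
#' @param scan a `qtl_scan`.
#' @param threshold LOD threshold; defaults to the scan's stored threshold.
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return tibble: `chrom`, `peak_cM`, `peak_lod`, `start_cM`, `end_cM`.
#' @export
call_qtl <- function(scan, threshold = scan$threshold, drop = 1.5) {
  assert_that(is_scalar_number(as.numeric(threshold)),
              "a LOD threshold is required (run permutation_threshold())")
  res <- scan$result
  out <- list()
  for (ch in unique(res$chrom)) {
    r <- filter(res, .data$chrom == ch)
    above <- r$lod > as.numeric(threshold)
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    for (i in which(rl$values)) {
      idx <- starts[i]:ends[i]
      peak <- idx[which.max(r$lod[idx])]
      lo <- peak
      while (lo > 1 && r$lod[lo - 1] >= r$lod[peak] - drop) lo <- lo - 1
      hi <- peak
      while (hi < nrow(r) && r$lod[hi + 1] >= r$lod[peak] - drop) hi <- hi + 1
      out[[length(out) + 1]] <- tibble(
        chrom = ch, peak_cM = r$pos_cM[peak], peak_lod = r$lod[peak],
        start_cM = r$pos_cM[lo], end_cM = r$pos_cM[hi])
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), peak_cM = numeric(),
                  peak_lod = numeric(), start_cM = numeric(),
                  end_cM = numeric()))
  }
  bind_rows(out)
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("<qtl_scan> %d positions, %d lines, mode=%s, max LOD=%.2f%s\n",
              nrow(x$result), x$n, x$mode, max(x$result$lod),
              if (!is.na(x$threshold))
                sprintf(", threshold=%.2f", as.numeric(x$threshold)) else ""))
  invisible(x)
}

#' Tidy a QTL scan
#'
#' @param x a `qtl_scan`.
#' @param ... unused.
#' @return tibble with `chrom`, `pos_cM`, `lod` (one row per grid position).
#' @export
tidy.qtl_scan <- function(x, ...) x$result

#' One-row summary of a QTL scan
#'
#' @param x a `qtl_scan`.
#' @param ... unused.
#' @return tibble with `n`, `n_positions`, `max_lod`, `peak_chrom`,
#'   `peak_cM`, `threshold`, `mode`.
#' @export
glance.qtl_scan <- function(x, ...) {
  i <- which.max(x$result$lod)
  tibble(n = x$n, n_positions = nrow(x$result), max_lod = x$result$lod[i],
         peak_chrom = x$result$chrom[i], peak_cM = x$result$pos_cM[i],
         threshold = as.numeric(x$threshold), mode = x$mode)
}
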