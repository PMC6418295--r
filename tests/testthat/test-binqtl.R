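geno_table <- function(pos, quals, calls_by_line, chrom = "chr1",
                       allele_a = NULL, allele_b = NULL) {
  t <- tibble::tibble(chrom = chrom, pos = pos, qual = quals)
  if (!is.null(allele_a)) { t$allele_a <- allele_a; t$allele_b <- allele_b }
  dplyr::bind_cols(t, tibble::as_tibble(calls_by_line))
}

test_that("SNP filters: quality, density window, line count, recoding", {
  calls <- list(L1 = rep("A", 6), L2 = rep("B", 6), L3 = rep("A", 6))
  tab <- geno_table(c(100L, 105L, 109L, 500L, 600L, 700L),
                    c(50, 50, 50, 30, 31, 50), calls)
  f <- filter_snps(tab, min_lines = 2)
  # 100/105/109 fall in one 10 bp window (3 loci); qual 30 is dropped (strict >)
  expect_equal(f$pos, c(600L, 700L))

  # fewer than min_lines genotyped drops the locus
  calls2 <- list(L1 = c("A", "A"), L2 = c("-", "B"), L3 = c("-", "A"))
  tab2 <- geno_table(c(100L, 200L), c(50, 50), calls2)
  f2 <- filter_snps(tab2, min_lines = 2)
  expect_equal(f2$pos, 200L)

  # nucleotide calls recoded against parental alleles; non-parental -> missing
  calls3 <- list(L1 = c("G", "T"), L2 = c("T", "C"), L3 = c("C", "T"))
  tab3 <- geno_table(c(100L, 200L), c(50, 50), calls3,
                     allele_a = c("G", "T"), allele_b = c("T", "A"))
  f3 <- filter_snps(tab3, min_lines = 2)
  expect_equal(f3$L1, c("A", "A"))
  expect_equal(f3$L2, c("B", "-"))
  expect_equal(f3$L3, c("-", "A"))

  # all-heterozygous loci are dropped
  calls4 <- list(L1 = c("H", "A"), L2 = c("H", "B"), L3 = c("H", "A"))
  tab4 <- geno_table(c(100L, 200L), c(50, 50), calls4)
  expect_equal(filter_snps(tab4, min_lines = 2)$pos, 200L)
})

test_that("sliding windows call by proportional majority", {
  pos <- seq(1000, by = 1000, length.out = 15)
  expect_equal(sliding_window_genotypes(rep("A", 15), pos)$call, "A")
  expect_equal(sliding_window_genotypes(c(rep("A", 11), rep("B", 4)), pos)$call, "A")
  expect_equal(sliding_window_genotypes(c(rep("A", 8), rep("B", 7)), pos)$call, "H")
  # fewer than 5 informative calls -> missing
  expect_equal(sliding_window_genotypes(c(rep("A", 4), rep("-", 11)), pos)$call, "-")
  # chromosome shorter than the window: single whole-chromosome window
  short <- sliding_window_genotypes(rep("A", 7), pos[1:7])
  expect_equal(nrow(short), 1)
  expect_equal(short$call, "A")
  # step advances one SNP at a time
  wc <- sliding_window_genotypes(c(rep("A", 20), rep("B", 20)),
                                 seq(1000, by = 1000, length.out = 40))
  expect_equal(nrow(wc), 26)
})

test_that("breakpoints appear only at homozygous state changes", {
  pos <- seq(1000, by = 1000, length.out = 30)
  wc <- sliding_window_genotypes(c(rep("A", 15), rep("B", 15)), pos)
  bp <- detect_breakpoints(wc)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$from, "A"); expect_equal(bp$to, "B")
  mid <- (pos[15] + pos[16]) / 2
  expect_gte(mid, bp$interval_start)
  expect_lte(mid, bp$interval_end)

  expect_equal(nrow(detect_breakpoints(
    sliding_window_genotypes(rep("A", 30), pos))), 0)
  # isolated H run without a state change
  wc_h <- sliding_window_genotypes(c(rep("A", 12), rep("H", 6), rep("A", 12)),
                                   seq(1000, by = 1000, length.out = 30))
  expect_equal(nrow(detect_breakpoints(wc_h)), 0)
})

test_that("binmap: merging, single-breakpoint boundary, saturation", {
  lines <- c("L1", "L2")
  states <- tibble::tibble(line = lines, chrom = "chr1", state = c("A", "B"))
  none <- tibble::tibble(line = character(), chrom = character(), pos = numeric())
  bm0 <- build_binmap(none, states, c(chr1 = 2e6))
  expect_equal(nrow(bm0$bins), 1)
  expect_equal(unname(bm0$genotypes[1, ]), c("A", "B"))

  one <- tibble::tibble(line = "L1", chrom = "chr1", pos = 1.23e6)
  bm1 <- build_binmap(one, states, c(chr1 = 2e6))
  expect_equal(nrow(bm1$bins), 2)
  boundary <- bm1$bins$end[1]
  expect_gte(boundary, 1.20e6); expect_lte(boundary, 1.25e6)
  expect_equal(unname(bm1$genotypes[, "L1"]), c("A", "B"))
  expect_equal(unname(bm1$genotypes[, "L2"]), c("B", "B"))

  # breakpoints in every 50 Kb cell -> no merging
  sat <- tibble::tibble(line = "L1", chrom = "chr1",
                        pos = seq(25e3, 975e3, by = 50e3))
  bms <- build_binmap(sat, states[1, ], c(chr1 = 1e6))
  expect_equal(nrow(bms$bins), 20)
})

test_that("map functions match closed forms and agree as r -> 0", {
  expect_equal(kosambi_cM(0.1), 25 * log(1.2 / 0.8))
  expect_equal(round(kosambi_cM(0.1), 2), 10.14)
  expect_equal(haldane_cM(0.1), -50 * log(0.8))
  expect_equal(round(haldane_cM(0.1), 2), 11.16)
  r0 <- 1e-4
  expect_equal(kosambi_cM(r0), 100 * r0, tolerance = 1e-3)
  expect_equal(haldane_cM(r0), 100 * r0, tolerance = 1e-3)
})

test_that("genetic distances from discordance, with and without RIL correction", {
  G <- rbind(rep("A", 10), c(rep("A", 8), "B", "B"))
  bm <- list(bins = tibble::tibble(chrom = "chr1", start = c(1, 51e3),
                                   end = c(5e4, 1e5), bin = 1:2),
             genotypes = G, lines = paste0("L", 1:10), interval = 5e4)
  class(bm) <- "bin_map"
  # identical columns -> 0 cM
  bm_id <- bm; bm_id$genotypes <- rbind(rep("A", 10), rep("A", 10))
  expect_equal(genetic_distances(bm_id)$bins$cM, c(0, 0))
  # R = 0.2 -> r = 0.125 under the selfed-RIL correction
  d <- genetic_distances(bm)
  expect_equal(d$bins$r_adj[2], 0.125)
  expect_equal(d$bins$cM[2], kosambi_cM(0.125))
  d2 <- genetic_distances(bm, correct_ril = FALSE)
  expect_equal(d2$bins$cM[2], kosambi_cM(0.2))
  d3 <- genetic_distances(bm, mapping_function = "haldane")
  expect_equal(d3$bins$cM[2], haldane_cM(0.125))
  # discordance of 1 would cap
  bm_cap <- bm
  bm_cap$genotypes <- rbind(rep("A", 10), rep("B", 10))
  expect_warning(genetic_distances(bm_cap), "capped")
})

mk_scan_binmap <- function(x, n_bins = 5, spacing_cM = 10) {
  # bins along one chromosome; the phenotype-linked genotype sits at bin 3
  n <- length(x)
  G <- matrix("A", n_bins, n)
  G[3, ] <- ifelse(x > 0, "A", "B")
  # neighbours correlated with bin 3 to mimic linkage
  G[2, ] <- G[3, ]; G[4, ] <- G[3, ]
  bm <- list(bins = tibble::tibble(chrom = "chr1",
                                   start = seq(1, by = 5e4, length.out = n_bins),
                                   end = seq(5e4, by = 5e4, length.out = n_bins),
                                   bin = seq_len(n_bins),
                                   cM = seq(0, by = spacing_cM, length.out = n_bins)),
             genotypes = G, lines = paste0("L", seq_len(n)), interval = 5e4,
             mapping_function = "kosambi")
  class(bm) <- "bin_map"
  bm
}

test_that("LOD matches the closed form and is affine invariant", {
  x <- c(1, 1, -1, -1)
  bm <- mk_scan_binmap(x)
  y <- x + c(1, -1, 1, -1)        # R^2 = 0.5 at the causal bin
  ph <- tibble::tibble(line = bm$lines, phenotype = y)
  scan <- lod_scan(bm, ph)
  at_bin <- scan$result$lod[scan$result$pos_cM == 20]
  expect_equal(at_bin, (4 / 2) * log10(2))
  # affine transformation leaves the LOD curve unchanged
  ph2 <- dplyr::mutate(ph, phenotype = 3 * phenotype + 7)
  expect_equal(lod_scan(bm, ph2)$result$lod, scan$result$lod)
  # constant phenotype gives an all-zero curve
  ph3 <- dplyr::mutate(ph, phenotype = 2)
  expect_true(all(lod_scan(bm, ph3)$result$lod == 0))
  # R^2 = 0.5 with n = 100: LOD = 50 log10(2)
  set.seed(90)
  x100 <- rep(c(1, -1), 50)
  e <- rep(c(1, -1), each = 50)    # orthogonal to x100, equal variance
  bm100 <- mk_scan_binmap(x100)
  y100 <- x100 + e
  sc100 <- lod_scan(bm100, tibble::tibble(line = bm100$lines, phenotype = y100))
  expect_equal(sc100$result$lod[sc100$result$pos_cM == 20], 50 * log10(2))
})

test_that("permutation threshold is deterministic with boundary quantiles", {
  set.seed(91)
  x <- sample(c(1, -1), 60, replace = TRUE)
  bm <- mk_scan_binmap(x)
  ph <- tibble::tibble(line = bm$lines, phenotype = rnorm(60))
  t1 <- permutation_threshold(bm, ph, n_perm = 100, seed = 5)
  t2 <- permutation_threshold(bm, ph, n_perm = 100, seed = 5)
  expect_equal(as.numeric(t1), as.numeric(t2))
  null_dist <- attr(t1, "null_max_lod")
  tmin <- permutation_threshold(bm, ph, n_perm = 100, alpha = 1, seed = 5)
  expect_equal(as.numeric(tmin), min(null_dist))
  expect_error(permutation_threshold(bm, ph, n_perm = 10, seed = 1), "100")
})

test_that("call_qtl reports super-threshold regions with support intervals", {
  x <- rep(c(1, -1), 30)
  bm <- mk_scan_binmap(x)
  set.seed(92)
  y <- x + rnorm(60, sd = 0.8)
  scan <- lod_scan(bm, tibble::tibble(line = bm$lines, phenotype = y))
  expect_equal(nrow(call_qtl(scan, threshold = 1e6)), 0)
  qtl <- call_qtl(scan, threshold = 2)
  expect_gte(nrow(qtl), 1)
  expect_true(any(qtl$start_cM <= 20 & qtl$end_cM >= 20))
  g <- glance(scan)
  expect_s3_class(tidy(scan), "tbl_df")
  expect_true(is.na(g$threshold))
})

test_that("bin genotype columns give non-decreasing genetic positions", {
  sim <- simulate_ril_population(40, c(chr1 = 80, chr2 = 40), 400, seed = 93)
  bp <- ril_breakpoints(sim$geno)
  bm <- genetic_distances(build_binmap(bp$breakpoints, bp$line_states,
                                       c(chr1 = 8e6, chr2 = 4e6)))
  for (ch in c("chr1", "chr2")) {
    cm <- bm$bins$cM[bm$bins$chrom == ch]
    expect_true(all(diff(cm) >= 0))
  }
})

test_that("autoplot returns a ggplot for a scan", {
  x <- rep(c(1, -1), 20)
  bm <- mk_scan_binmap(x)
  scan <- lod_scan(bm, tibble::tibble(line = bm$lines, phenotype = x))
  expect_s3_class(autoplot(scan), "ggplot")
  expect_s3_class(plot_track(gc_track(strrep("ACGT", 250), 100)), "ggplot")
})
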