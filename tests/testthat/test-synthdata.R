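test_that("reference generation is deterministic and respects its contract", {
  a <- generate_reference(2, c(6e4, 8e4), gc = 0.35, te_library_size = 4,
                          n_genes = 10, seed = 1)
  b <- generate_reference(2, c(6e4, 8e4), gc = 0.35, te_library_size = 4,
                          n_genes = 10, seed = 1)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$te_annotation, b$te_annotation)
  expect_identical(a$genes, b$genes)

  expect_equal(length(a$genome), 2L)
  expect_equal(unname(Biostrings::width(a$genome)), c(6e4, 8e4))
  expect_true(all(Biostrings::width(a$te_library) >= 500 &
                    Biostrings::width(a$te_library) <= 10000))
  # gene intervals non-overlapping per chromosome
  g <- dplyr::arrange(a$genes, chrom, start)
  for (ch in unique(g$chrom)) {
    sub <- g[g$chrom == ch, ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }

  expect_error(generate_reference(1, 1e5, gc = 1.2), "gc")
  expect_error(generate_reference(1, 0), "positive")
})

test_that("empirical GC tracks the requested fraction", {
  r <- generate_reference(1, 1e7, gc = 0.35, te_library_size = 0,
                          n_te_copies = 0, n_genes = 0, seed = 7)
  f <- Biostrings::letterFrequency(r$genome[[1]], c("G", "C"))
  expect_equal(sum(f) / 1e7, 0.35, tolerance = 0.01 / 0.35)
})

test_that("sv_plan rejects overlapping events naming the pair", {
  expect_error(
    sv_plan(tibble::tibble(kind = c("inversion", "te_insertion"),
                           chrom = "chr1", pos = c(1000, 1500),
                           length = c(2000, 500), te_fraction = c(NA, 1))),
    "events 1 and 2 overlap on chr1")
  ok <- sv_plan(tibble::tibble(kind = c("inversion", "te_insertion"),
                               chrom = "chr1", pos = c(1000, 5000),
                               length = c(2000, 500), te_fraction = c(NA, 1)))
  expect_s3_class(ok, "sv_plan")
})

test_that("derive_variant_genome: identity, conservation, inversion sequence", {
  ref <- tiny_reference(4e4, seed = 2)
  # empty plan, no SNPs -> identical genome
  vg0 <- derive_variant_genome(ref, sv_plan(tibble::tibble()), snp_rate = 0,
                               seed = 1)
  expect_identical(as.character(vg0$genome), as.character(ref$genome))

  plan <- sv_plan(tibble::tibble(
    kind = c("novel_insertion", "inversion"),
    chrom = "chr1", pos = c(10000, 20000), length = c(2000, 8000)))
  vg <- derive_variant_genome(ref, plan, snp_rate = 0, seed = 3)
  # length conservation: insertions add, inversions preserve
  expect_equal(sum(Biostrings::width(vg$genome)),
               sum(Biostrings::width(ref$genome)) + 2000)
  # inverted query segment is the reverse complement of the reference segment
  ev <- vg$truth$events[vg$truth$events$kind == "inversion", ]
  qseg <- Biostrings::subseq(vg$genome[[ev$qry_chrom]], ev$qry_start, ev$qry_end)
  rseg <- Biostrings::subseq(ref$genome[["chr1"]], 20000, 27999)
  expect_identical(as.character(qseg),
                   as.character(Biostrings::reverseComplement(rseg)))
})

test_that("liftover round-trips planted breakpoints and translocations swap tails", {
  ref <- tiny_reference(5e4, n_chrom = 2, seed = 4)
  plan <- sv_plan(tibble::tibble(
    kind = "inter_translocation", chrom = "chr1", pos = 30000,
    chrom2 = "chr2", pos2 = 20000))
  vg <- derive_variant_genome(ref, plan, snp_rate = 0, seed = 5)
  expect_equal(unname(Biostrings::width(vg$genome)), c(60000, 40000))
  # sequence identity of the swapped tails
  expect_identical(as.character(Biostrings::subseq(vg$genome[["chr1"]], 30001, 60000)),
                   as.character(Biostrings::subseq(ref$genome[["chr2"]], 20001, 50000)))
  # liftover: a position in the moved tail maps into the other query chromosome
  lp <- lift_position(vg$truth$liftover, "chr2", 25000)
  expect_equal(lp$qry_chrom, "chr1")
  expect_equal(lp$qry_pos, 30000 + (25000 - 20000))
  lp2 <- lift_position(vg$truth$liftover, "chr1", 100)
  expect_equal(lp2$qry_chrom, "chr1")
  expect_equal(lp2$qry_pos, 100)
})

test_that("background SNPs avoid planted breakpoints and are reproducible", {
  ref <- tiny_reference(5e4, seed = 6)
  plan <- sv_plan(tibble::tibble(kind = "novel_insertion", chrom = "chr1",
                                 pos = 25000, length = 1500))
  vg1 <- derive_variant_genome(ref, plan, snp_rate = 0.01, seed = 9)
  vg2 <- derive_variant_genome(ref, plan, snp_rate = 0.01, seed = 9)
  expect_identical(as.character(vg1$genome), as.character(vg2$genome))
  expect_gt(vg1$truth$n_snps, 0)
  ev <- vg1$truth$events
  bnd <- c(ev$qry_start, ev$qry_end)
  dmin <- min(outer(vg1$truth$snp_positions$pos, bnd,
                    function(a, b) abs(a - b)))
  expect_gt(dmin, 200)
})

test_that("RIL simulation: determinism, non-recombinant 0 cM, heritability", {
  s1 <- simulate_ril_population(10, c(chr1 = 50), 100, seed = 11)
  s2 <- simulate_ril_population(10, c(chr1 = 50), 100, seed = 11)
  expect_identical(s1$geno, s2$geno)

  s0 <- simulate_ril_population(20, c(chr1 = 0), 50, seed = 12)
  expect_equal(nrow(s0$truth$crossovers), 0)
  expect_true(all(apply(s0$truth$geno_true, 1,
                        function(g) length(unique(g)) == 1)))

  expect_error(simulate_ril_population(
    10, c(chr1 = 100), 50, qtl = tibble::tibble(chrom = "chr1", pos = 1e6, effect = 1),
    h2 = 1.5, seed = 1), "h2")

  # moment check: realized var(genetic)/var(total) near h2 across replicates
  ratios <- vapply(1:100, function(s) {
    sim <- simulate_ril_population(
      96, c(chr1 = 100), 20,
      qtl = tibble::tibble(chrom = "chr1", pos = 5e6, effect = 1),
      h2 = 0.3, seed = s)
    var(sim$truth$genetic_values) /
      var(sim$pheno$phenotype)
  }, numeric(1))
  expect_equal(mean(ratios), 0.3, tolerance = 0.1 / 0.3)
})

test_that("RIL crossover counts follow the doubled-meiosis rate", {
  sim <- simulate_ril_population(300, c(chr1 = 100), 10, seed = 13)
  # Poisson mean 2 per line at 100 cM
  expect_equal(nrow(sim$truth$crossovers) / 300, 2, tolerance = 0.15)
})

test_that("optical molecule simulation honours its error model", {
  set.seed(20)
  labs <- sort(sample(1e6, 1000))
  src <- tibble::tibble(id = "m", length = 1e6, n_labels = 1000,
                        labels = list(labs), channel = 1L)
  # clean molecules carry an exact window of the source labels
  clean <- simulate_optical_molecules(src, 5, seed = 21)
  for (i in 1:5) {
    inside <- labs[labs >= clean$source_start[i] & labs <= clean$source_end[i]]
    expect_identical(clean$labels[[i]], as.numeric(inside - clean$source_start[i] + 1))
  }
  # drop-out rate is honoured in aggregate
  noisy <- simulate_optical_molecules(src, 60, label_fn_rate = 0.1, seed = 22)
  expect_gt(sum(noisy$n_true), 10000)
  expect_equal(sum(noisy$n_dropped) / sum(noisy$n_true), 0.1,
               tolerance = 0.02 / 0.1)
  # n = 0 is an empty set, not an error
  expect_equal(nrow(simulate_optical_molecules(src, 0)), 0)
  # fixed intensity of 0.5 passes the downstream QC intensity rule
  fixed <- simulate_optical_molecules(src, 8, intensity_dist = function(n) rep(0.5, n),
                                      length_dist = function(n) rep(2e5, n),
                                      seed = 23)
  qc <- qc_filter_molecules(fixed)
  expect_false(any(grepl("intensity", qc$removed$reason)))
  # determinism
  m1 <- simulate_optical_molecules(src, 7, sizing_sd = 300, label_fn_rate = 0.05,
                                   label_fp_rate_per_100kb = 1, seed = 30)
  m2 <- simulate_optical_molecules(src, 7, sizing_sd = 300, label_fn_rate = 0.05,
                                   label_fp_rate_per_100kb = 1, seed = 30)
  expect_identical(m1, m2)
})
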