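test_that("digestion labels motif starts on both strands, deduplicated", {
  set.seed(70)
  motif <- "GCTCTTC"
  bg <- gsub("GCTCTTC|GAAGAGC", "ACAACAA", rand_dna(8000, 0.4))
  s <- paste0(substr(bg, 1, 99), motif,
              substr(bg, 107, 4899), revcomp(motif),
              substr(bg, 4907, 8000))
  m <- digest(s, motif)
  expect_equal(m$labels[[1]], c(100, 4900))
  # motif absent
  expect_equal(digest(strrep("ACAC", 100), motif)$n_labels, 0L)
  # a palindromic-position duplicate is collapsed
  m2 <- digest(paste0("AAAA", motif, "AAAA"), c(motif, motif))
  expect_equal(m2$labels[[1]], 5)
})

test_that("label merging follows the midpoint rule and is idempotent", {
  mk <- function(labs) tibble::tibble(id = "m", length = 1e5,
                                      n_labels = length(labs),
                                      labels = list(labs), channel = 1L)
  expect_equal(merge_labels(mk(c(5000, 5600)))$labels[[1]], 5300)
  expect_equal(merge_labels(mk(c(5000, 6500)))$labels[[1]], c(5000, 6500))
  expect_equal(merge_labels(mk(c(1000, 1500, 2000)))$labels[[1]], 1500)
  set.seed(71)
  for (i in 1:20) {
    m <- mk(sort(sample(1e5, 80)))
    once <- merge_labels(m)
    expect_identical(merge_labels(once)$labels, once$labels)
    expect_true(all(diff(once$labels[[1]]) >= 1000))
  }
})

test_that("molecule QC removes by any rule and partitions exactly", {
  mols <- tibble::tibble(
    molecule_id = paste0("m", 1:5),
    length = c(140000, 200000, 200000, 140000, 151000),
    intensity = c(0.5, 0.7, 0.5, 0.9, 0.6),
    n_labels = c(12L, 12L, 8L, 3L, 9L),
    labels = replicate(5, list(numeric(0))))
  qc <- qc_filter_molecules(mols)
  expect_equal(qc$removed$molecule_id, c("m1", "m2", "m3", "m4"))
  expect_equal(qc$removed$reason,
               c("length", "intensity", "labels", "length,intensity,labels"))
  expect_equal(qc$retained$molecule_id, "m5")  # boundary values survive
  expect_equal(nrow(qc$retained) + nrow(qc$removed), nrow(mols))
  expect_equal(length(intersect(qc$retained$molecule_id,
                                qc$removed$molecule_id)), 0)
})

test_that("repetitive maps are removed by the modal-interval rule", {
  mk <- function(labs) tibble::tibble(id = "m", length = max(labs) + 1000,
                                      n_labels = length(labs),
                                      labels = list(labs), channel = 1L)
  tandem <- mk(seq(1000, by = 3000, length.out = 51))
  expect_equal(nrow(filter_repetitive_maps(tandem)$removed), 1)
  set.seed(72)
  irregular <- mk(cumsum(c(1000, runif(49, 2000, 50000))))
  expect_equal(nrow(filter_repetitive_maps(irregular)$removed), 0)
  two_labels <- mk(c(1000, 4000))
  expect_equal(nrow(filter_repetitive_maps(two_labels)$removed), 0)
})

test_that("map alignment: identity, mirror, and single deletion", {
  set.seed(73)
  labs <- sort(sample(5e5, 40))
  m <- tibble::tibble(id = "src", length = 5e5, n_labels = 40,
                      labels = list(labs), channel = 1L)
  al <- align_maps(m, m)
  expect_equal(al$orientation, "forward")
  expect_equal(al$n_matched, 40)
  expect_equal(al$skips_a + al$skips_b, 0)
  expect_equal(al$pairs$a_index, al$pairs$b_index)

  mirror <- tibble::tibble(id = "mir", length = 5e5, n_labels = 40,
                           labels = list(sort(5e5 - labs + 1)), channel = 1L)
  al2 <- align_maps(m, mirror)
  expect_equal(al2$orientation, "reverse")
  expect_equal(al2$n_matched, 40)

  # one label deleted: everything else matches with exactly one skip on a
  drop <- 17
  del <- tibble::tibble(id = "del", length = 5e5, n_labels = 39,
                        labels = list(labs[-drop]), channel = 1L)
  al3 <- align_maps(m, del)
  expect_equal(al3$n_matched, 39)
  expect_equal(al3$skips_a, 1)
  expect_equal(al3$skips_b, 0)
  expect_false(drop %in% al3$pairs$a_index)
})

test_that("clean simulated molecules realign with zero skips; sizing error degrades matching", {
  set.seed(74)
  labs <- sort(sample(1e6, 120))
  src <- tibble::tibble(id = "map1", length = 1e6, n_labels = 120,
                        labels = list(labs), channel = 1L)
  mols <- simulate_optical_molecules(src, 6, seed = 75)
  for (i in seq_len(nrow(mols))) {
    mol <- as.list(mols[i, ])
    if (mol$n_labels < 2) next
    al <- align_maps(src, mols[i, ])
    expect_equal(al$n_matched, mol$n_labels)
    expect_equal(al$skips_a + al$skips_b, 0)
    # aligned span covers the true source window
    aspan <- range(labs[al$pairs$a_index])
    expect_gte(aspan[1], mol$source_start)
    expect_lte(aspan[2], mol$source_end)
  }
  # matched fraction degrades monotonically (on average) with sizing error
  frac <- vapply(c(0, 2000), function(sdv) {
    ms <- simulate_optical_molecules(src, 8, sizing_sd = sdv, seed = 76)
    matched <- vapply(seq_len(nrow(ms)), function(i) {
      al <- align_maps(src, ms[i, ], sizing_tolerance = 800)
      al$n_matched / ms$n_labels[i]
    }, numeric(1))
    mean(matched)
  }, numeric(1))
  expect_gt(frac[1], frac[2])
})

test_that("region coverage applies the strict 30-molecule rule", {
  mk_spans <- function(n) tibble::tibble(ref_start = rep(1, n),
                                         ref_end = rep(1e5, n))
  ref <- tibble::tibble(id = "r", length = 2e5, n_labels = 2,
                        labels = list(c(1, 2e5)), channel = 1L)
  spans35 <- lapply(seq_len(35), function(i) mk_spans(1))
  r35 <- region_coverage(spans35, ref, 2e4, 8e4)
  expect_equal(r35$depth, 35)
  expect_true(r35$retained)
  spans29 <- lapply(seq_len(29), function(i) mk_spans(1))
  r29 <- region_coverage(spans29, ref, 2e4, 8e4)
  expect_false(r29$retained)
  spans30 <- lapply(seq_len(30), function(i) mk_spans(1))
  expect_true(region_coverage(spans30, ref, 2e4, 8e4)$retained)
  r0 <- region_coverage(list(), ref, 2e4, 8e4)
  expect_equal(r0$depth, 0)
  expect_false(r0$retained)
})

test_that("CMAP and molecule TSV round-trip", {
  set.seed(77)
  maps <- tibble::tibble(id = c("a", "b"), length = c(1e5, 2e5),
                         n_labels = c(5L, 8L),
                         labels = list(sort(sample(1e5, 5)),
                                       sort(sample(2e5, 8))),
                         channel = 1L)
  tmp <- withr::local_tempfile(fileext = ".cmap")
  write_cmap(maps, tmp)
  back <- read_cmap(tmp, ids = maps$id)
  expect_equal(back$length, maps$length)
  expect_equal(lapply(back$labels, as.numeric), lapply(maps$labels, as.numeric))

  mols <- simulate_optical_molecules(
    list(id = "a", length = 1e5, labels = maps$labels[1]), 4,
    length_dist = function(n) rep(5e4, n), seed = 78)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_molecules_tsv(mols, tmp2)
  back2 <- read_molecules_tsv(tmp2)
  expect_equal(back2$molecule_id, mols$molecule_id)
  expect_equal(back2$labels, mols$labels)
})
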