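mk_pair <- function(ref_gap, qry_gap, strand = "+") {
  left_re <- 1000L
  tibble::tibble(
    ref_chrom = "r1", qry_chrom = "q1", strand = strand,
    left_ref_start = 1L, left_ref_end = left_re,
    right_ref_start = left_re + ref_gap + 1L,
    right_ref_end = left_re + ref_gap + 1000L,
    left_qry_start = if (strand == "+") 1L else 9000L,
    left_qry_end = if (strand == "+") 1000L else 9999L,
    right_qry_start = if (strand == "+") 1000L + qry_gap + 1L else 9000L - qry_gap - 1000L,
    right_qry_end = if (strand == "+") 2000L + qry_gap else 9000L - qry_gap - 1L,
    ref_gap = as.integer(ref_gap), qry_gap = as.integer(qry_gap))
}

test_that("insertion calling applies strict gap thresholds", {
  expect_equal(nrow(call_insertions(mk_pair(49, 1549))), 1)
  expect_equal(call_insertions(mk_pair(49, 1549))$length, 1549)
  # strict > on the query gap
  expect_equal(nrow(call_insertions(mk_pair(0, 1000))), 0)
  expect_equal(nrow(call_insertions(mk_pair(0, 1001))), 1)
  # strict < on the reference gap
  expect_equal(nrow(call_insertions(mk_pair(100, 2000))), 0)
  expect_equal(nrow(call_insertions(mk_pair(99, 2000))), 1)
  # contiguous blocks and overlaps call nothing
  expect_equal(nrow(call_insertions(mk_pair(0, 0))), 0)
  expect_equal(nrow(call_insertions(mk_pair(-5, 2000))), 0)
  # minus-strand call takes the query interval between query-proximal ends
  cm <- call_insertions(mk_pair(0, 1500, strand = "-"))
  expect_equal(cm$qry_end - cm$qry_start + 1L, 1500L)
})

test_that("threshold monotonicity: tighter rgap_max yields a subset", {
  set.seed(50)
  pairs <- dplyr::bind_rows(lapply(1:50, function(i) {
    mk_pair(sample(-10:150, 1), sample(500:3000, 1))
  }))
  loose <- call_insertions(pairs, rgap_max = 100)
  tight <- call_insertions(pairs, rgap_max = 0)
  expect_true(nrow(tight) <= nrow(loose))
  key <- function(x) paste(x$ref_chrom, x$site_start, x$length)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("TE classification unions overlaps and uses a strict 80% rule", {
  calls <- tibble::tibble(
    ref_chrom = "r1", site_start = 1000L, site_end = 1000L,
    qry_chrom = "q1", qry_start = 2001L, qry_end = 3549L,
    length = 1549L, strand = "+")
  # 1300 of 1549 covered -> 0.839 -> TE
  te <- tibble::tibble(chrom = "q1", start = 2100L, end = 3399L, te_id = "TE1")
  cl <- classify_te_insertions(calls, te)
  expect_equal(cl$te_fraction, 1300 / 1549)
  expect_true(cl$is_te_insertion)
  # overlapping annotations are unioned before measuring
  te2 <- dplyr::bind_rows(te, tibble::tibble(chrom = "q1", start = 2200L,
                                             end = 3000L, te_id = "TE2"))
  expect_equal(classify_te_insertions(calls, te2)$te_fraction, 1300 / 1549)
  expect_equal(classify_te_insertions(calls, te2)$te_fraction,
               coverage_fraction_oracle(2001, 3549, te2$start, te2$end))
  # exactly 80% covered is NOT a TE insertion
  calls80 <- dplyr::mutate(calls, qry_start = 2001L, qry_end = 3500L,
                           length = 1500L)
  te80 <- tibble::tibble(chrom = "q1", start = 2001L, end = 3200L, te_id = "TE1")
  cl80 <- classify_te_insertions(calls80, te80)
  expect_equal(cl80$te_fraction, 0.8)
  expect_false(cl80$is_te_insertion)
  # no overlap
  te0 <- tibble::tibble(chrom = "q1", start = 9000L, end = 9500L, te_id = "TE1")
  cl0 <- classify_te_insertions(calls, te0)
  expect_equal(cl0$te_fraction, 0)
  expect_false(cl0$is_te_insertion)
  # annotation on unknown chromosome warns and is ignored
  teu <- tibble::tibble(chrom = "qX", start = 1L, end = 10L, te_id = "TEx")
  expect_warning(classify_te_insertions(calls, dplyr::bind_rows(te, teu)), "qX")
})

test_that("TE-affected genes respect the 500 bp flank boundary", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "r1", start = 5000L,
                          end = 6000L, strand = "+")
  mk_call <- function(site, is_te = TRUE) tibble::tibble(
    ref_chrom = "r1", site_start = site, site_end = site,
    qry_chrom = "q1", qry_start = 1L, qry_end = 2000L, length = 2000L,
    strand = "+", te_fraction = 1, is_te_insertion = is_te)
  expect_equal(find_te_affected_genes(mk_call(6400L), genes)$gene_id, "g1")
  expect_equal(find_te_affected_genes(mk_call(6500L), genes)$gene_id, "g1")
  expect_equal(nrow(find_te_affected_genes(mk_call(6501L), genes)), 0)
  expect_equal(find_te_affected_genes(mk_call(4500L), genes)$gene_id, "g1")
  expect_equal(nrow(find_te_affected_genes(mk_call(4499L), genes)), 0)
  expect_equal(find_te_affected_genes(mk_call(5500L), genes)$gene_id, "g1")
  # non-TE insertions never contribute
  expect_equal(nrow(find_te_affected_genes(mk_call(5500L, is_te = FALSE), genes)), 0)
})

# block builder: one row per (ref interval, qry chrom, qry interval, strand)
mk_blocks <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(ref_chrom = r[[1]], ref_start = r[[2]], ref_end = r[[3]],
                   qry_chrom = r[[4]], qry_start = r[[5]], qry_end = r[[6]],
                   strand = r[[7]], identity = 1)
  }))
}

test_that("detect_large_svs applies run rules with a strict >100 Kb threshold", {
  # 150 Kb minus-strand run inside plus context -> inversion
  b <- mk_blocks(
    list("c1", 1, 1e6, "q1", 1, 1e6, "+"),
    list("c1", 1000001, 1150000, "q1", 1000001, 1150000, "-"),
    list("c1", 1150001, 3e6, "q1", 1150001, 3e6, "+"))
  svs <- detect_large_svs(b)
  expect_equal(svs$kind, "inversion")
  expect_equal(svs$size, 150000)
  expect_equal(svs$bp_left, 1e6)
  expect_equal(svs$bp_right, 1150001)
  # 90 Kb run is below the threshold
  b90 <- mk_blocks(
    list("c1", 1, 1e6, "q1", 1, 1e6, "+"),
    list("c1", 1000001, 1090000, "q1", 1000001, 1090000, "-"),
    list("c1", 1090001, 3e6, "q1", 1090001, 3e6, "+"))
  expect_equal(nrow(detect_large_svs(b90)), 0)

  # segment mapping to a different query chromosome than its flanks
  bt <- mk_blocks(
    list("c1", 1, 2e6, "q1", 1, 2e6, "+"),
    list("c1", 2000001, 2500000, "q2", 1, 500000, "+"),
    list("c1", 2500001, 5e6, "q1", 2000001, 4.5e6, "+"))
  svt <- detect_large_svs(bt)
  expect_equal(svt$kind, "inter_translocation")
  expect_equal(svt$qry_chrom, "q2")
  expect_equal(svt$size, 500000)

  # displaced query order on the same chromosome pair
  bi <- mk_blocks(
    list("c1", 1, 2e6, "q1", 1, 2e6, "+"),
    list("c1", 2000001, 2200000, "q1", 3800001, 4e6, "+"),
    list("c1", 2200001, 3800000, "q1", 2000001, 3.6e6, "+"),
    list("c1", 3800001, 4e6, "q1", 3600001, 3.8e6, "+"))
  svi <- detect_large_svs(bi)
  expect_true("intra_translocation" %in% svi$kind)

  # invariant to input row order
  expect_equal(detect_large_svs(b[sample(nrow(b)), ]), detect_large_svs(b))
})

test_that("QTL-region comparison filters small blocks and unions overlaps", {
  # identical regions: one full-length block
  full <- mk_blocks(list("r", 1, 5e4, "q", 1, 5e4, "+"))
  res <- compare_qtl_regions(full, 5e4, 5e4)
  expect_equal(res$fraction_region1, 1)
  expect_equal(res$fraction_region2, 1)
  # a single 500 bp block is filtered -> fraction 0
  small <- mk_blocks(list("r", 1, 500, "q", 1, 500, "+"))
  res2 <- compare_qtl_regions(small, 5e4, 5e4)
  expect_equal(res2$fraction_region1, 0)
  expect_equal(res2$n_blocks, 0)
  # overlapping blocks are counted once
  ov <- mk_blocks(list("r", 1, 3000, "q", 1, 3000, "+"),
                  list("r", 2001, 6000, "q", 2001, 6000, "+"))
  res3 <- compare_qtl_regions(ov, 1e4, 1e4)
  expect_equal(res3$aligned_bp_region1, 6000)
})
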