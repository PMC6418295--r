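#' Call insertions in the query genome from adjacent block gaps
#'
#' An adjacent pair of alignment blocks calls an insertion in the query
#' genome when the query-side gap exceeds `qgap_min` (strictly) and the
#' reference-side gap is non-negative and below `rgap_max` (strictly):
#' the query gap is the inserted sequence and the reference gap is the
#' insertion site. Overlapping blocks (negative reference gap) never call an
#' insertion — an overlap is not a gap.
#'
#' @param pairs tibble from [pair_adjacent()].
#' @param qgap_min minimum query gap in bp (strict `>`; default 1000).
#' @param rgap_max maximum reference gap in bp (strict `<`; default 100).
#' @return tibble of insertion calls: `ref_chrom`, `site_start`, `site_end`
#'   (reference insertion-site interval; zero-length sites are collapsed to
#'   the first base after the left block), `qry_chrom`, `qry_start`,
#'   `qry_end` (inserted query interval), `length`, `strand`.
#' @export
call_insertions <- function(pairs, qgap_min = 1000, rgap_max = 100) {
  hit <- filter(pairs, .data$qry_gap > qgap_min,
                .data$ref_gap >= 0, .data$ref_gap < rgap_max)
  tibble(
    ref_chrom = hit$ref_chrom,
    site_start = hit$left_ref_end + 1L,
    site_end = pmax(hit$right_ref_start - 1L, hit$left_ref_end + 1L),
    qry_chrom = hit$qry_chrom,
    qry_start = if_else(hit$strand == "+", hit$left_qry_end + 1L,
                        hit$right_qry_end + 1L),
    qry_end = if_else(hit$strand == "+", hit$right_qry_start - 1L,
                      hit$left_qry_start - 1L),
    length = hit$qry_gap,
    strand = hit$strand)
}

#' Classify insertions as TE insertions by annotation occupancy
#'
#' For each call, TE intervals on the query genome are unioned and
#' intersected with the inserted query interval; `te_fraction` is the
#' covered fraction of the insertion. An insertion is a TE insertion when
#' strictly more than `threshold` of it is TE-covered.
#'
#' @param calls insertion-call tibble from [call_insertions()].
#' @param te_annotation tibble of TE intervals on query coordinates
#'   (`chrom`, `start`, `end`, 1-based closed).
#' @param threshold occupancy threshold (strict `>`; default 0.8).
#' @return `calls` with `te_fraction` and `is_te_insertion` columns.
#' @export
classify_te_insertions <- function(calls, te_annotation, threshold = 0.8) {
  known <- unique(calls$qry_chrom)
  stray <- setdiff(unique(te_annotation$chrom), known)
  if (length(stray) && nrow(calls)) {
    warn(paste0("TE intervals on chromosomes without calls ignored: ",
                paste(stray, collapse = ", ")))
  }
  te_fraction <- map_dbl(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    te <- filter(te_annotation, .data$chrom == cl$qry_chrom,
                 .data$end >= cl$qry_start, .data$start <= cl$qry_end)
    if (nrow(te) == 0) return(0)
    covered <- interval_union_width(pmax(te$start, cl$qry_start),
                                    pmin(te$end, cl$qry_end))
    covered / (cl$qry_end - cl$qry_start + 1)
  })
  mutate(calls, te_fraction = te_fraction,
         is_te_insertion = te_fraction > threshold)
}

#' Find genes affected by TE insertions
#'
#' A gene is TE-affected when a TE insertion site on the reference genome
#' falls within the gene or within `flank` bp of it (closed intervals; a
#' site exactly `flank` bp away counts). Only calls classified as TE
#' insertions contribute.
#'
#' @param calls classified calls from [classify_te_insertions()].
#' @param genes tibble of gene intervals on the reference (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @param flank flanking distance in bp (default 500).
#' @return tibble (`call_index`, `ref_chrom`, `site_start`, `site_end`,
#'   `gene_id`), one row per affected gene per TE insertion.
#' @export
find_te_affected_genes <- function(calls, genes, flank = 500) {
  te_calls <- mutate(calls, call_index = row_number())
  te_calls <- filter(te_calls, .data$is_te_insertion)
  rows <- map(seq_len(nrow(te_calls)), function(i) {
    cl <- te_calls[i, ]
    hit <- filter(genes, .data$chrom == cl$ref_chrom,
                  .data$start - flank <= cl$site_end,
                  .data$end + flank >= cl$site_start)
    if (nrow(hit) == 0) return(NULL)
    tibble(call_index = cl$call_index, ref_chrom = cl$ref_chrom,
           site_start = cl$site_start, site_end = cl$site_end,
           gene_id = hit$gene_id)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(call_index = integer(), ref_chrom = character(),
                  site_start = integer(), site_end = integer(),
                  gene_id = character())
  }
  out
}

#' Detect large structural variants from synteny blocks
#'
#' Block-run rules over whole-genome alignment blocks (sorting is internal,
#' so input order does not matter):
#' * **inversion** — a maximal run of minus-strand blocks embedded in a
#'   plus-strand context (or vice versa) on one chromosome pair, with
#'   reference span above `min_size`;
#' * **intra_translocation** — a maximal run whose query order is displaced
#'   relative to the flanking reference order on the same chromosome pair;
#' * **inter_translocation** — a maximal run mapping a reference segment to
#'   a different query chromosome than its flanks.
#'
#' Breakpoints are reported as the bounding coordinates between the run and
#' its flanking collinear blocks, to anchor resolution.
#'
#' @param blocks alignment block tibble.
#' @param min_size minimum reference span in bp (strict `>`; default 100 Kb).
#' @return tibble of variants: `kind`, `ref_chrom`, `ref_start`, `ref_end`,
#'   `qry_chrom`, `qry_start`, `qry_end`, `size`, `bp_left`, `bp_right`
#'   (reference coordinates of the flanking collinear blocks, `NA` at
#'   chromosome ends), `n_blocks`.
#' @export
detect_large_svs <- function(blocks, min_size = 1e5) {
  blocks <- arrange(blocks, .data$ref_chrom, .data$ref_start)
  out <- list()
  for (ch in unique(blocks$ref_chrom)) {
    b <- filter(blocks, .data$ref_chrom == ch)
    span <- b$ref_end - b$ref_start + 1
    # dominant query chromosome for this reference chromosome
    dom_q <- b %>% group_by(.data$qry_chrom) %>%
      summarise(s = sum(.data$ref_end - .data$ref_start + 1), .groups = "drop") %>%
      arrange(desc(.data$s), .data$qry_chrom) %>% pull(.data$qry_chrom) %>% first()
    out[[length(out) + 1]] <-
      sv_runs(b, b$qry_chrom != dom_q, "inter_translocation", min_size)
    bd <- filter(b, .data$qry_chrom == dom_q)
    if (nrow(bd)) {
      dom_s <- bd %>% group_by(.data$strand) %>%
        summarise(s = sum(.data$ref_end - .data$ref_start + 1), .groups = "drop") %>%
        arrange(desc(.data$s), .data$strand) %>% pull(.data$strand) %>% first()
      out[[length(out) + 1]] <-
        sv_runs(bd, bd$strand != dom_s, "inversion", min_size)
      bs <- filter(bd, .data$strand == dom_s)
      if (nrow(bs) > 1) {
        displaced <- displaced_mask(bs, dom_s == "-")
        out[[length(out) + 1]] <-
          sv_runs(bs, displaced, "intra_translocation", min_size)
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(kind = character(), ref_chrom = character(),
                  ref_start = integer(), ref_end = integer(),
                  qry_chrom = character(), qry_start = integer(),
                  qry_end = integer(), size = integer(),
                  bp_left = integer(), bp_right = integer(),
                  n_blocks = integer())
  }
  arrange(res, .data$ref_chrom, .data$ref_start)
}

# summarize maximal TRUE-runs of `mask` over ref-sorted blocks `b`
sv_runs <- function(b, mask, kind, min_size) {
  if (!any(mask)) return(NULL)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    size <- b$ref_end[max(idx)] - b$ref_start[min(idx)] + 1
    if (size <= min_size) next
    rows[[length(rows) + 1]] <- tibble(
      kind = kind, ref_chrom = b$ref_chrom[1],
      ref_start = b$ref_start[min(idx)], ref_end = b$ref_end[max(idx)],
      qry_chrom = b$qry_chrom[min(idx)],
      qry_start = min(b$qry_start[idx]), qry_end = max(b$qry_end[idx]),
      size = size,
      bp_left = if (min(idx) > 1) b$ref_end[min(idx) - 1] else NA_integer_,
      bp_right = if (max(idx) < nrow(b)) b$ref_start[max(idx) + 1] else NA_integer_,
      n_blocks = length(idx))
  }
  bind_rows(rows)
}

# blocks whose query order is displaced relative to the dominant collinear
# chain: everything off the heaviest increasing (or decreasing) subsequence
displaced_mask <- function(bs, decreasing) {
  q <- if (decreasing) -bs$qry_start else bs$qry_start
  w <- bs$ref_end - bs$ref_start + 1
  m <- length(q)
  best <- w
  prev <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1)) {
      if (q[j] < q[i] && best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]; prev[i] <- j
      }
    }
  }
  keep <- logical(m)
  i <- which.max(best)
  while (!is.na(i)) { keep[i] <- TRUE; i <- prev[i] }
  !keep
}

#' Aligned-overlap summary between two QTL region sequences
#'
#' Filters alignment blocks below `min_block` (reference span, strictly
#' smaller removed), unions the surviving aligned intervals on each region,
#' and reports the union length and aligned fraction of each region. This is
#' the comparison used to decide whether QTL intervals detected against two
#' different assemblies describe the same region.
#'
#' @param blocks alignment blocks between the two region sequences
#'   (region 1 as reference, region 2 as query).
#' @param region1_len,region2_len region lengths in bp.
#' @param min_block minimum block length in bp (default 1000).
#' @return one-row tibble: `aligned_bp_region1`, `aligned_bp_region2`,
#'   `fraction_region1`, `fraction_region2`, `n_blocks`.
#' @export
compare_qtl_regions <- function(blocks, region1_len, region2_len,
                                min_block = 1000) {
  kept <- filter_blocks(blocks, min_block)
  a1 <- interval_union_width(kept$ref_start, kept$ref_end)
  a2 <- interval_union_width(kept$qry_start, kept$qry_end)
  tibble(aligned_bp_region1 = a1, aligned_bp_region2 = a2,
         fraction_region1 = a1 / region1_len,
         fraction_region2 = a2 / region2_len,
         n_blocks = nrow(kept))
}
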