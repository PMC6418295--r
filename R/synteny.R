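#' Whole-genome alignment blocks from unique k-mer anchors
#'
#' A self-contained aligner in the maximal-unique-match (MUM) tradition:
#' k-mers that occur exactly once in each genome (counting both strands) are
#' matched between the two genomes, collapsed into same-diagonal runs, and
#' chained per (reference chromosome, query chromosome, strand) by a
#' weighted longest-increasing-subsequence over reference-then-query order.
#' Chained runs become alignment blocks; no extension beyond exact anchors
#' is performed, so block edges are resolved to within one anchor length.
#'
#' @param ref,qry genomes as [Biostrings::DNAStringSet] (or lists from
#'   [generate_reference()] / [derive_variant_genome()]).
#' @param k anchor k-mer length (>= 15; <= 26 so 4^k stays exactly
#'   representable in a double).
#' @param min_chain minimum reference span of a reported block in bp.
#' @param join_gap same-diagonal runs separated by at most this many bp are
#'   merged into one block (bridges isolated substitutions).
#'
#' @return tibble of alignment blocks with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `qry_chrom`, `qry_start`, `qry_end` (1-based, inclusive,
#'   start <= end), `strand` ("+"/"-") and `identity` (anchored fraction of
#'   the reference span).
#' @export
anchor_align <- function(ref, qry, k = 21, min_chain = 1000, join_gap = 500) {
  if (is.list(ref) && !is.null(ref$genome)) ref <- ref$genome
  if (is.list(qry) && !is.null(qry$genome)) qry <- qry$genome
  assert_that(k >= 15 && k <= 26, "`k` must be in [15, 26]")
  if (length(ref) == 0 || length(qry) == 0 ||
      all(Biostrings::width(ref) < k) || all(Biostrings::width(qry) < k)) {
    return(empty_blocks())
  }
  ru <- unique_kmer_table(ref, k)
  qu <- unique_kmer_table(qry, k)

  # plus-strand anchors: ref forward k-mer == qry forward k-mer
  ip <- match(ru$fwd$val, qu$fwd$val)
  # minus-strand anchors: ref forward k-mer == qry reverse-strand k-mer
  im <- match(ru$fwd$val, qu$rc$val)
  anchors <- bind_rows(
    tibble(ref_ci = ru$fwd$chrom[!is.na(ip)], ref_pos = ru$fwd$pos[!is.na(ip)],
           qry_ci = qu$fwd$chrom[ip[!is.na(ip)]], qry_pos = qu$fwd$pos[ip[!is.na(ip)]],
           strand = "+"),
    tibble(ref_ci = ru$fwd$chrom[!is.na(im)], ref_pos = ru$fwd$pos[!is.na(im)],
           qry_ci = qu$rc$chrom[im[!is.na(im)]], qry_pos = qu$rc$pos[im[!is.na(im)]],
           strand = "-"))
  if (nrow(anchors) == 0) return(empty_blocks())
  segs <- anchors_to_segments(anchors, k, join_gap)
  segs <- mutate(segs, ref_chrom = names(ref)[.data$ref_ci],
                 qry_chrom = names(qry)[.data$qry_ci])
  segs <- chain_segments(segs)
  blocks <- segs %>%
    mutate(identity = pmin(1, .data$anchor_bases / (.data$ref_end - .data$ref_start + 1))) %>%
    filter(.data$ref_end - .data$ref_start + 1 >= min_chain) %>%
    select("ref_chrom", "ref_start", "ref_end", "qry_chrom", "qry_start",
           "qry_end", "strand", "identity") %>%
    arrange(.data$ref_chrom, .data$ref_start)
  trim_ref_overlaps(blocks, max_trim = k)
}

# anchors can extend a few bases across an event edge by base coincidence,
# making consecutive blocks overlap slightly on the reference; trim the
# right block so blocks abut (larger overlaps, e.g. repeat-induced, are left)
trim_ref_overlaps <- function(blocks, max_trim) {
  n <- nrow(blocks)
  if (n < 2) return(blocks)
  for (i in 2:n) {
    if (blocks$ref_chrom[i] != blocks$ref_chrom[i - 1]) next
    o <- blocks$ref_end[i - 1] - blocks$ref_start[i] + 1
    if (o >= 1 && o <= max_trim) {
      blocks$ref_start[i] <- blocks$ref_start[i] + o
      if (blocks$strand[i] == "+") {
        blocks$qry_start[i] <- blocks$qry_start[i] + o
      } else {
        blocks$qry_end[i] <- blocks$qry_end[i] - o
      }
    }
  }
  blocks
}

empty_blocks <- function() {
  tibble(ref_chrom = character(), ref_start = integer(), ref_end = integer(),
         qry_chrom = character(), qry_start = integer(), qry_end = integer(),
         strand = character(), identity = numeric())
}

# 2-bit-encode a chromosome; non-ACGT -> NA
encode_dna <- function(seq) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt("a")] <- 0L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("g")] <- 2L; lut[utf8ToInt("t")] <- 3L
  lut[utf8ToInt(as.character(seq))]
}

# numeric k-mer codes for every window start (exact for k <= 26)
kmer_values <- function(codes, k) {
  n <- length(codes) - k + 1
  if (n <= 0) return(numeric(0))
  h <- numeric(n)
  pow <- 4^((k - 1):0)
  for (j in seq_len(k)) h <- h + codes[j:(j + n - 1)] * pow[j]
  h
}

# forward and reverse-strand k-mer tables for one genome, keeping only
# k-mers unique across both strands of the whole genome
unique_kmer_table <- function(genome, k) {
  fwd <- list(); rc <- list()
  for (ci in seq_along(genome)) {
    codes <- encode_dna(genome[[ci]])
    if (length(codes) < k) next
    fv <- kmer_values(codes, k)
    # reverse-strand k-mer whose forward window starts at i: value of the
    # reverse-complemented chromosome at the mirrored window start
    rv <- rev(kmer_values(rev(3L - codes), k))
    n <- length(fv)
    fwd[[ci]] <- tibble(val = fv, chrom = ci, pos = seq_len(n))
    rc[[ci]] <- tibble(val = rv, chrom = ci, pos = seq_len(n))
  }
  fwd <- bind_rows(fwd); rc <- bind_rows(rc)
  allv <- c(fwd$val, rc$val)
  dup <- duplicated(allv) | duplicated(allv, fromLast = TRUE)
  nf <- nrow(fwd)
  ok_f <- !dup[seq_len(nf)] & !is.na(fwd$val)
  ok_r <- !dup[nf + seq_len(nrow(rc))] & !is.na(rc$val)
  list(fwd = fwd[ok_f, ], rc = rc[ok_r, ])
}

# collapse per-base anchors into same-diagonal runs and merge nearby runs
anchors_to_segments <- function(anchors, k, join_gap) {
  ord <- order(anchors$ref_ci, anchors$qry_ci, anchors$strand, anchors$ref_pos)
  anchors <- anchors[ord, ]
  n_a <- nrow(anchors)
  same_grp <- c(FALSE, anchors$ref_ci[-1] == anchors$ref_ci[-n_a] &
                  anchors$qry_ci[-1] == anchors$qry_ci[-n_a] &
                  anchors$strand[-1] == anchors$strand[-n_a])
  dr <- c(0, diff(anchors$ref_pos))
  dq <- c(0, diff(anchors$qry_pos))
  step <- if_else(anchors$strand == "+", 1, -1)
  contiguous <- same_grp & dr == 1 & dq == step
  run_id <- cumsum(!contiguous)
  # base-R rle-style aggregation: runs are contiguous in the sorted order
  first_i <- which(!contiguous)
  last_i <- c(first_i[-1] - 1L, n_a)
  segs <- tibble(
    ref_ci = anchors$ref_ci[first_i], qry_ci = anchors$qry_ci[first_i],
    strand = anchors$strand[first_i],
    ref_start = anchors$ref_pos[first_i],
    ref_end = anchors$ref_pos[last_i] + k - 1,
    q_lo = pmin(anchors$qry_pos[first_i], anchors$qry_pos[last_i]),
    q_hi = pmax(anchors$qry_pos[first_i], anchors$qry_pos[last_i]) + k - 1,
    n_anchor = last_i - first_i + 1L) %>%
    mutate(anchor_bases = .data$n_anchor + k - 1,
           diag = if_else(.data$strand == "+", .data$q_lo - .data$ref_start,
                          .data$q_hi + .data$ref_start)) %>%
    arrange(.data$ref_ci, .data$qry_ci, .data$strand, .data$diag,
            .data$ref_start)
  # merge runs on the same diagonal separated by small gaps (SNP scars)
  n <- nrow(segs)
  if (n > 1) {
    prev_same <- c(FALSE,
      segs$ref_ci[-1] == segs$ref_ci[-n] &
      segs$qry_ci[-1] == segs$qry_ci[-n] &
      segs$strand[-1] == segs$strand[-n] &
      segs$diag[-1] == segs$diag[-n] &
      (segs$ref_start[-1] - segs$ref_end[-n] - 1) <= join_gap)
    mid <- cumsum(!prev_same)
    segs <- segs %>%
      mutate(mid = mid) %>%
      group_by(.data$mid) %>%
      summarise(ref_ci = first(.data$ref_ci), qry_ci = first(.data$qry_ci),
                strand = first(.data$strand), diag = first(.data$diag),
                ref_start = min(.data$ref_start), ref_end = max(.data$ref_end),
                q_lo = min(.data$q_lo), q_hi = max(.data$q_hi),
                anchor_bases = sum(.data$anchor_bases), .groups = "drop") %>%
      select(-"mid")
  }
  segs %>%
    mutate(qry_start = .data$q_lo, qry_end = .data$q_hi) %>%
    select(-"q_lo", -"q_hi")
}

# chain co-linear runs per (ref_chrom, qry_chrom, strand) by iterated
# weighted longest-increasing-subsequence extraction: the best chain is
# pulled out, then the next among the remainder, and so on, so that
# displaced runs (translocated segments) survive as their own chains.
# Ties break toward smaller total gap, then earlier runs (deterministic).
chain_segments <- function(segs) {
  out <- segs %>%
    group_by(.data$ref_chrom, .data$qry_chrom, .data$strand) %>%
    group_split() %>%
    map(function(g) {
      g <- arrange(g, .data$ref_start, .data$qry_start)
      kept <- list()
      while (nrow(g) > 0) {
        idx <- best_chain_indices(g)
        kept[[length(kept) + 1]] <- g[idx, , drop = FALSE]
        g <- g[-idx, , drop = FALSE]
      }
      bind_rows(kept)
    })
  bind_rows(out)
}

best_chain_indices <- function(g) {
  m <- nrow(g)
  if (m == 1) return(1L)
  minus <- g$strand[1] == "-"
  score <- g$anchor_bases
  best <- score
  gap_tot <- numeric(m)
  prev <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1)) {
      ok <- g$ref_start[i] > g$ref_end[j] &&
        (if (minus) g$qry_end[i] < g$qry_start[j]
         else g$qry_start[i] > g$qry_end[j])
      if (!ok) next
      cand <- best[j] + score[i]
      gp <- gap_tot[j] + (g$ref_start[i] - g$ref_end[j]) +
        (if (minus) g$qry_start[j] - g$qry_end[i]
         else g$qry_start[i] - g$qry_end[j])
      if (cand > best[i] || (cand == best[i] && gp < gap_tot[i])) {
        best[i] <- cand; prev[i] <- j; gap_tot[i] <- gp
      }
    }
  }
  end <- which.max(best)  # first maximum: deterministic
  keep <- integer(0)
  i <- end
  while (!is.na(i)) { keep <- c(i, keep); i <- prev[i] }
  keep
}

#' Pair adjacent alignment blocks along the reference
#'
#' Blocks are sorted by (ref_chrom, ref_start); pairs are formed only between
#' consecutive blocks sharing reference chromosome, query chromosome and
#' strand, with query order consistent with the strand. Gaps are signed:
#' `ref_gap = right.ref_start - left.ref_end - 1`, and `qry_gap` is measured
#' between the query-proximal ends analogously (strand-aware), so
#' overlapping blocks give negative gaps.
#'
#' @param blocks tibble of alignment blocks (one genome comparison).
#' @return tibble with left/right block coordinates and `ref_gap`, `qry_gap`.
#' @export
pair_adjacent <- function(blocks) {
  blocks <- arrange(blocks, .data$ref_chrom, .data$ref_start, .data$ref_end)
  n <- nrow(blocks)
  if (n < 2) return(empty_pairs())
  l <- blocks[-n, ]; r <- blocks[-1, ]
  ok <- l$ref_chrom == r$ref_chrom & l$qry_chrom == r$qry_chrom &
    l$strand == r$strand & l$ref_end < r$ref_start &
    if_else(l$strand == "+", r$qry_start > l$qry_start, r$qry_end < l$qry_end)
  l <- l[ok, ]; r <- r[ok, ]
  tibble(
    ref_chrom = l$ref_chrom, qry_chrom = l$qry_chrom, strand = l$strand,
    left_ref_start = l$ref_start, left_ref_end = l$ref_end,
    right_ref_start = r$ref_start, right_ref_end = r$ref_end,
    left_qry_start = l$qry_start, left_qry_end = l$qry_end,
    right_qry_start = r$qry_start, right_qry_end = r$qry_end,
    ref_gap = r$ref_start - l$ref_end - 1,
    qry_gap = if_else(l$strand == "+",
                      r$qry_start - l$qry_end - 1,
                      l$qry_start - r$qry_end - 1))
}

empty_pairs <- function() {
  tibble(ref_chrom = character(), qry_chrom = character(), strand = character(),
         left_ref_start = integer(), left_ref_end = integer(),
         right_ref_start = integer(), right_ref_end = integer(),
         left_qry_start = integer(), left_qry_end = integer(),
         right_qry_start = integer(), right_qry_end = integer(),
         ref_gap = integer(), qry_gap = integer())
}

#' Filter alignment blocks by reference span
#'
#' Blocks whose reference span is smaller than `min_len` are removed
#' (strictly smaller: a block of exactly `min_len` bp is retained).
#'
#' @param blocks alignment block tibble.
#' @param min_len minimum reference span in bp (>= 0).
#' @export
filter_blocks <- function(blocks, min_len = 1000) {
  assert_that(min_len >= 0, "`min_len` must be >= 0")
  filter(blocks, .data$ref_end - .data$ref_start + 1 >= min_len)
}
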