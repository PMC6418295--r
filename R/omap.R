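#' In silico digestion of sequences into an optical map
#'
#' Places a label at the forward-strand start coordinate of every occurrence
#' of each nicking-enzyme recognition motif on either strand (e.g. GCTCTTC
#' for Nt.BspQI-type enzymes, CACGAG for Nb.BssSI-type). Duplicate positions
#' are collapsed. The nick offset within the motif is constant per enzyme
#' and cancels in comparisons, so it is ignored.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or single DNAString/character,
#'   or list with `genome`).
#' @param recognition_motifs character vector of motifs over A/C/G/T.
#' @param channel enzyme/channel label stored with the map (default 1).
#' @return map tibble, one row per sequence: `id`, `length`, `n_labels`,
#'   `labels` (list column of sorted positions), `channel`.
#' @export
digest <- function(seqs, recognition_motifs, channel = 1L) {
  if (is.list(seqs) && !is.null(seqs$genome)) seqs <- seqs$genome
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (inherits(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(list(seqs))
  assert_that(all(grepl("^[ACGT]+$", recognition_motifs)),
              "motifs must be over A/C/G/T")
  if (is.null(names(seqs))) names(seqs) <- paste0("map", seq_along(seqs))
  rows <- map(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    pos <- integer(0)
    for (m in recognition_motifs) {
      pats <- unique(c(m, revcomp_chr(m)))
      for (p in pats) {
        pos <- c(pos, Biostrings::start(Biostrings::matchPattern(p, s)))
      }
    }
    labs <- sort(unique(pos))
    tibble(id = names(seqs)[i], length = length(s),
           n_labels = length(labs), labels = list(labs),
           channel = as.integer(channel))
  })
  bind_rows(rows)
}

#' Merge nearby optical-map labels
#'
#' Signals closer than the detection resolution cannot be distinguished on
#' an optical map, so labels within `min_gap` of their neighbour are merged:
#' greedy left-to-right clustering of labels whose neighbour gap is below
#' `min_gap`, each cluster replaced by the rounded midpoint of its extremes.
#' Output labels are pairwise at least `min_gap` apart and the operation is
#' idempotent.
#'
#' @param maps map tibble (from [digest()] or molecule rows).
#' @param min_gap merge distance in bp (default 1 Kb).
#' @return map tibble with merged `labels` and updated `n_labels`.
#' @export
merge_labels <- function(maps, min_gap = 1000) {
  out <- maps
  out$labels <- map(maps$labels, function(l) {
    l <- sort(l)
    if (length(l) < 2) return(l)
    cl <- cumsum(c(TRUE, diff(l) >= min_gap))
    as.numeric(vapply(split(l, cl),
                      function(x) round((min(x) + max(x)) / 2), numeric(1)))
  })
  out$n_labels <- map_int(out$labels, length)
  out
}

#' Quality-control filter for optical molecules
#'
#' Removes low-quality molecules: length below `min_len`, signal intensity
#' above `max_intensity`, or fewer than `min_labels` labels. A molecule is
#' removed if any criterion triggers; all triggered reasons are recorded.
#'
#' @param mols molecule tibble with `length`, `intensity`, `n_labels`.
#' @param min_len minimum molecule length in bp (default 150 Kb; strict `<`
#'   removal).
#' @param max_intensity maximum signal intensity (default 0.6; strict `>`
#'   removal).
#' @param min_labels minimum label count (default 9; strict `<` removal).
#' @return list: `retained` and `removed` tibbles (removed has a `reason`
#'   column with comma-separated triggers); the two partition the input.
#' @export
qc_filter_molecules <- function(mols, min_len = 150e3, max_intensity = 0.6,
                                min_labels = 9) {
  reason <- pmap(list(mols$length, mols$intensity, mols$n_labels),
    function(len, int, nl) {
      r <- c(if (len < min_len) "length",
             if (int > max_intensity) "intensity",
             if (nl < min_labels) "labels")
      if (length(r)) paste(r, collapse = ",") else NA_character_
    })
  reason <- unlist(reason)
  removed <- mols[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(retained = mols[is.na(reason), , drop = FALSE], removed = removed)
}

#' Remove maps consisting only of repetitive segments
#'
#' A map whose inter-label intervals are dominated by one interval size is a
#' tandem-repeat signature and is uninformative for alignment. A map is
#' removed when at least `modal_fraction` of its intervals lie within
#' `±tol` (relative) of the modal interval. Maps with fewer than 3 labels
#' are never removed by this rule.
#'
#' @param maps map tibble.
#' @param modal_fraction fraction of intervals near the mode that triggers
#'   removal (default 0.9).
#' @param tol relative tolerance around the modal interval (default 0.1).
#' @return list: `retained`, `removed` tibbles.
#' @export
filter_repetitive_maps <- function(maps, modal_fraction = 0.9, tol = 0.1) {
  repetitive <- map_lgl(maps$labels, function(l) {
    if (length(l) < 3) return(FALSE)
    d <- diff(sort(l))
    frac <- vapply(d, function(x) mean(abs(d - x) <= tol * x), numeric(1))
    max(frac) >= modal_fraction
  })
  list(retained = maps[!repetitive, , drop = FALSE],
       removed = maps[repetitive, , drop = FALSE])
}

#' Align two optical maps by dynamic programming over label spacings
#'
#' Matches labels of `a` and `b` so that cumulative inter-label distances
#' between consecutive matched pairs agree within `sizing_tolerance` per
#' spanned interval, with penalties for skipped (missing/false) labels.
#' Both orientations of `b` are tried and the better-scoring one returned;
#' ties break toward fewer skips, then forward orientation. The alignment
#' is fitted: unaligned margins of `a` (the longer, reference-side map) are
#' free, unaligned labels of `b` outside the matched range are counted as
#' skips of `b`.
#'
#' @param a,b one-row map tibbles (or lists with `id`, `length`, `labels`);
#'   both need >= 2 labels.
#' @param sizing_tolerance allowed per-interval sizing discrepancy in bp
#'   (default 1500).
#' @param miss_penalty penalty per skipped label of `a` inside the aligned
#'   region (default 1).
#' @param fp_penalty penalty per skipped label of `b` (default 1).
#' @param match_award score per matched label pair (default 3).
#' @param max_skip maximum consecutive skips considered per side (default 5).
#' @return list: `ref_id`, `qry_id`, `orientation` ("forward"/"reverse"),
#'   `pairs` (tibble `a_index`, `b_index` — indices into the *input* label
#'   vectors), `score`, `n_matched`, `skips_a`, `skips_b`, `unmatched_b`.
#' @export
align_maps <- function(a, b, sizing_tolerance = 1500, miss_penalty = 1,
                       fp_penalty = 1, match_award = 3, max_skip = 5) {
  if (is.data.frame(a)) a <- as.list(a[1, ])
  if (is.data.frame(b)) b <- as.list(b[1, ])
  la <- sort(unlist(a$labels)); lb <- sort(unlist(b$labels))
  assert_that(length(la) >= 2 && length(lb) >= 2,
              "both maps need at least 2 labels")
  fwd <- om_dp(la, lb, sizing_tolerance, miss_penalty, fp_penalty,
               match_award, max_skip)
  lbr <- sort(b$length - lb + 1)
  rev_ <- om_dp(la, lbr, sizing_tolerance, miss_penalty, fp_penalty,
                match_award, max_skip)
  use_rev <- rev_$score > fwd$score ||
    (rev_$score == fwd$score && rev_$skips < fwd$skips)
  best <- if (use_rev) rev_ else fwd
  pairs <- best$pairs
  if (use_rev && nrow(pairs)) {
    # map indices on the mirrored label vector back to input order
    pairs$b_index <- length(lb) + 1L - pairs$b_index
  }
  n_matched <- nrow(pairs)
  list(ref_id = a$id %||% "a", qry_id = b$id %||% "b",
       orientation = if (use_rev) "reverse" else "forward",
       pairs = pairs, score = best$score, n_matched = n_matched,
       skips_a = best$skips_a, skips_b = best$skips_b,
       unmatched_b = length(lb) - n_matched)
}

# fitted DP: maximize matches - penalties; dp over (i in a, j in b) = best
# score of an alignment whose last matched pair is (i, j)
om_dp <- function(la, lb, tol, miss_pen, fp_pen, award, max_skip) {
  na <- length(la); nb <- length(lb)
  dp <- matrix(-Inf, na, nb)
  ska <- matrix(0L, na, nb); skb <- matrix(0L, na, nb)
  pi_ <- matrix(0L, na, nb); pj_ <- matrix(0L, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      # starting pair: b prefix labels before j are unexplained skips of b
      best <- award - fp_pen * (j - 1)
      bska <- 0L; bskb <- j - 1L; bi <- 0L; bj <- 0L
      for (di in seq_len(min(max_skip + 1, i - 1))) {
        for (dj in seq_len(min(max_skip + 1, j - 1))) {
          pi <- i - di; pj <- j - dj
          if (dp[pi, pj] == -Inf) next
          if (abs((la[i] - la[pi]) - (lb[j] - lb[pj])) >
              tol * max(di, dj)) next
          cand <- dp[pi, pj] + award - miss_pen * (di - 1) - fp_pen * (dj - 1)
          if (cand > best) {
            best <- cand
            bska <- ska[pi, pj] + di - 1L; bskb <- skb[pi, pj] + dj - 1L
            bi <- pi; bj <- pj
          }
        }
      }
      dp[i, j] <- best; ska[i, j] <- bska; skb[i, j] <- bskb
      pi_[i, j] <- bi; pj_[i, j] <- bj
    }
  }
  # closing: b suffix labels after the last matched j are skips of b
  close_pen <- outer(rep(0, na), (nb - seq_len(nb)) * fp_pen, `+`)
  tot <- dp - close_pen
  bi <- which(tot == max(tot), arr.ind = TRUE)[1, ]
  i <- unname(bi[1]); j <- unname(bi[2])
  score <- tot[i, j]
  pairs <- list()
  skips_a <- ska[i, j]; skips_b <- skb[i, j] + (nb - j)
  while (i > 0) {
    pairs[[length(pairs) + 1]] <- c(i, j)
    ni <- pi_[i, j]; nj <- pj_[i, j]
    i <- ni; j <- nj
  }
  pairs <- do.call(rbind, rev(pairs))
  pairs <- tibble(a_index = as.integer(pairs[, 1]), b_index = as.integer(pairs[, 2]))
  list(score = score, pairs = pairs, skips_a = skips_a, skips_b = skips_b,
       skips = skips_a + skips_b)
}

#' Molecule coverage over a region of a reference map
#'
#' Counts molecules whose aligned span fully covers a target region of the
#' reference (in silico) map; maps/regions supported by fewer than
#' `min_coverage` molecules are flagged for exclusion from comparative
#' analysis.
#'
#' @param alignments list of [align_maps()] results of molecules against the
#'   reference map, or a tibble with `ref_start`/`ref_end` aligned spans.
#' @param ref_map the reference map (one-row tibble or list) the alignments
#'   refer to; used to translate matched label indices to positions.
#' @param region_start,region_end target region on the reference map (bp).
#' @param min_coverage minimum spanning-molecule count (default 30; strict
#'   `<` exclusion).
#' @return list: `depth` (spanning molecules), `retained` (logical),
#'   `spans` tibble.
#' @export
region_coverage <- function(alignments, ref_map, region_start, region_end,
                            min_coverage = 30) {
  if (is.data.frame(ref_map)) ref_map <- as.list(ref_map[1, ])
  ref_labels <- sort(unlist(ref_map$labels))
  spans <- map(alignments, function(al) {
    if (is.data.frame(al)) {
      tibble(ref_start = al$ref_start[1], ref_end = al$ref_end[1])
    } else {
      idx <- al$pairs$a_index
      if (length(idx) == 0) return(tibble(ref_start = NA_real_, ref_end = NA_real_))
      tibble(ref_start = ref_labels[min(idx)], ref_end = ref_labels[max(idx)])
    }
  })
  spans <- bind_rows(spans)
  if (nrow(spans) == 0) {
    spans <- tibble(ref_start = numeric(), ref_end = numeric())
  }
  depth <- sum(!is.na(spans$ref_start) &
                 spans$ref_start <= region_start & spans$ref_end >= region_end)
  list(depth = depth, retained = depth >= min_coverage, spans = spans)
}
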