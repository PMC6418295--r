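#' Merge two scaffold orderings into superscaffolds with evidence classes
#'
#' Builds an orientation-aware adjacency graph from two independent contig
#' orderings (typically Hi-C scaffolds and optical-map hybrid scaffolds).
#' An adjacency and its mirror image are the same edge. Edges present in
#' both sources get evidence `"both"`; source-exclusive edges are kept with
#' evidence `"hic"` or `"map"` unless the other source places a different
#' neighbour on one of the same contig ends — such contradictions are not
#' joined and are listed in the conflict report. Connected paths of the
#' surviving edges are emitted as superscaffolds.
#'
#' @param hic,hybrid chain tibbles: `chain_id`, `contig`, `orientation`
#'   ("+"/"-"), rows ordered within chains. A contig may appear at most once
#'   per source.
#' @return list: `superscaffolds` (tibble `superscaffold_id`, `position`,
#'   `contig`, `orientation`), `linkages` (tibble `left_contig`,
#'   `left_orientation`, `right_contig`, `right_orientation`, `evidence` in
#'   both/map/hic), `conflicts` (tibble of dropped adjacencies with their
#'   source).
#' @export
merge_scaffolds <- function(hic, hybrid) {
  for (nm in c("hic", "hybrid")) {
    src <- if (nm == "hic") hic else hybrid
    dup <- src$contig[duplicated(src$contig)]
    if (length(dup)) {
      abort(sprintf("contig %s appears more than once in the %s chains",
                    dup[1], nm))
    }
  }
  e_hic <- chain_edges(hic)
  e_hyb <- chain_edges(hybrid)
  e_hic$source <- "hic"; e_hyb$source <- "map"
  both_keys <- intersect(e_hic$key, e_hyb$key)
  e_both <- filter(e_hic, .data$key %in% both_keys) %>% mutate(evidence = "both")
  x_hic <- filter(e_hic, !.data$key %in% both_keys) %>% mutate(evidence = "hic")
  x_hyb <- filter(e_hyb, !.data$key %in% both_keys) %>% mutate(evidence = "map")
  # a source-exclusive edge conflicts when the other source uses one of its
  # contig ends for a different neighbour
  ends_of <- function(e) c(e$end1, e$end2)
  conflict_hic <- x_hic$end1 %in% ends_of(e_hyb) | x_hic$end2 %in% ends_of(e_hyb)
  conflict_hyb <- x_hyb$end1 %in% ends_of(e_hic) | x_hyb$end2 %in% ends_of(e_hic)
  conflicts <- bind_rows(x_hic[conflict_hic, ], x_hyb[conflict_hyb, ])
  edges <- bind_rows(e_both, x_hic[!conflict_hic, ], x_hyb[!conflict_hyb, ])
  # exclusive edges from different sources can still collide on an end
  # (each conflicts with nothing in the other source's chains but both grab
  # the same end); treat those as conflicts too, conservatively
  all_ends <- c(edges$end1, edges$end2)
  dup_ends <- unique(all_ends[duplicated(all_ends)])
  if (length(dup_ends)) {
    clash <- edges$end1 %in% dup_ends | edges$end2 %in% dup_ends
    clash <- clash & edges$evidence != "both"
    conflicts <- bind_rows(conflicts, edges[clash, ])
    edges <- edges[!clash, ]
  }
  contigs <- union(hic$contig, hybrid$contig)
  ss <- walk_paths(edges, contigs)
  list(superscaffolds = ss,
       linkages = select(edges, left_contig = "c1", left_orientation = "o1",
                         right_contig = "c2", right_orientation = "o2",
                         "evidence"),
       conflicts = select(conflicts, left_contig = "c1", left_orientation = "o1",
                          right_contig = "c2", right_orientation = "o2",
                          "source"))
}

# canonical oriented adjacencies of one chain set; (A+,B+) == (B-,A-)
chain_edges <- function(chains) {
  if (nrow(chains) == 0) {
    return(tibble(c1 = character(), o1 = character(), c2 = character(),
                  o2 = character(), end1 = character(), end2 = character(),
                  key = character()))
  }
  rows <- chains %>%
    group_by(.data$chain_id) %>%
    group_split() %>%
    map(function(g) {
      if (nrow(g) < 2) return(NULL)
      tibble(c1 = g$contig[-nrow(g)], o1 = g$orientation[-nrow(g)],
             c2 = g$contig[-1], o2 = g$orientation[-1])
    })
  e <- bind_rows(rows)
  if (nrow(e) == 0) {
    return(tibble(c1 = character(), o1 = character(), c2 = character(),
                  o2 = character(), end1 = character(), end2 = character(),
                  key = character()))
  }
  # the joined ends: tail of left contig (head if "-"), head of right
  e <- mutate(e,
    end1 = paste0(.data$c1, if_else(.data$o1 == "+", ":tail", ":head")),
    end2 = paste0(.data$c2, if_else(.data$o2 == "+", ":head", ":tail")))
  # canonicalize mirror image: keep lexicographically smaller end first
  swap <- e$end2 < e$end1
  e2 <- e
  e2$end1[swap] <- e$end2[swap]; e2$end2[swap] <- e$end1[swap]
  flip <- function(o) if_else(o == "+", "-", "+")
  e2$c1[swap] <- e$c2[swap]; e2$o1[swap] <- flip(e$o2[swap])
  e2$c2[swap] <- e$c1[swap]; e2$o2[swap] <- flip(e$o1[swap])
  mutate(e2, key = paste(.data$end1, .data$end2, sep = "|"))
}

# assemble simple paths from surviving edges; isolated contigs become
# singleton superscaffolds
walk_paths <- function(edges, contigs) {
  nb <- list()
  add_nb <- function(end, other) {
    nb[[end]] <<- c(nb[[end]], other)
  }
  for (i in seq_len(nrow(edges))) {
    add_nb(edges$end1[i], edges$end2[i])
    add_nb(edges$end2[i], edges$end1[i])
  }
  end_of <- function(contig, side) paste0(contig, ":", side)
  other_side <- function(end) {
    parts <- strsplit(end, ":", fixed = TRUE)[[1]]
    paste0(parts[1], ":", if (parts[2] == "head") "tail" else "head")
  }
  contig_of <- function(end) strsplit(end, ":", fixed = TRUE)[[1]][1]
  visited <- character(0)
  out <- list()
  ss_i <- 0
  for (ct in sort(contigs)) {
    if (ct %in% visited) next
    # walk left from this contig's head, then right from its tail
    path <- ct
    orient <- "+"
    # extend rightward
    ext <- function(path, orients, dir) {
      repeat {
        lastc <- if (dir == "right") path[length(path)] else path[1]
        lasto <- if (dir == "right") orients[length(orients)] else orients[1]
        side <- if (dir == "right") {
          if (lasto == "+") "tail" else "head"
        } else {
          if (lasto == "+") "head" else "tail"
        }
        nxt <- nb[[end_of(lastc, side)]]
        if (is.null(nxt)) break
        nc <- contig_of(nxt[1])
        if (nc %in% path) break  # guard (cycles cannot normally occur)
        # orientation of the next contig: joined at its head => same-sense
        nside <- strsplit(nxt[1], ":", fixed = TRUE)[[1]][2]
        no <- if (dir == "right") {
          if (nside == "head") "+" else "-"
        } else {
          if (nside == "tail") "+" else "-"
        }
        if (dir == "right") {
          path <- c(path, nc); orients <- c(orients, no)
        } else {
          path <- c(nc, path); orients <- c(no, orients)
        }
      }
      list(path = path, orients = orients)
    }
    r <- ext(ct, "+", "right")
    r <- ext(r$path, r$orients, "left")
    visited <- c(visited, r$path)
    ss_i <- ss_i + 1
    out[[ss_i]] <- tibble(superscaffold_id = sprintf("SS%04d", ss_i),
                          position = seq_along(r$path), contig = r$path,
                          orientation = r$orients)
  }
  bind_rows(out)
}

#' Find redundant (head-to-tail identical) gap-flanking sequences
#'
#' Assembly gaps are sometimes flanked by two copies of the same sequence —
#' one on each side of the N-run — when the assembler failed to join
#' overlapping contigs. This searches for the longest head-to-tail overlap:
#' a suffix of the left flank matching a prefix of the right flank at
#' `>= min_identity` over `>= min_len` bp.
#'
#' @param seq sequence containing a gap (run of `N`), as DNAString or
#'   character; alternatively pass `left`/`right` flanks explicitly.
#' @param left,right explicit flank sequences (used when `seq` is `NULL`).
#' @param max_flank maximal flank length examined (default 20 Kb).
#' @param min_identity minimum overlap identity (default 0.98).
#' @param min_len minimum overlap length in bp (default 500).
#' @return `NULL` when no candidate; else list `overlap_len`, `identity`,
#'   `left_flank_len`, `right_flank_len`.
#' @export
find_redundant_gap_flanks <- function(seq = NULL, left = NULL, right = NULL,
                                      max_flank = 2e4, min_identity = 0.98,
                                      min_len = 500) {
  if (!is.null(seq)) {
    s <- as.character(seq)
    gap <- regmatches(s, regexpr("N+", s))
    if (length(gap) == 0) return(NULL)
    at <- regexpr("N+", s)
    left <- substr(s, 1, at - 1)
    right <- substr(s, at + attr(at, "match.length"), nchar(s))
  }
  left <- as.character(left); right <- as.character(right)
  left <- substr(left, max(1, nchar(left) - max_flank + 1), nchar(left))
  right <- substr(right, 1, min(max_flank, nchar(right)))
  nl <- nchar(left); nr <- nchar(right)
  if (nl < min_len || nr < min_len) return(NULL)
  # candidate overlap lengths from exact 20-mer probes of the right prefix
  probe_starts <- seq(1, min(200, nr - 19), by = 20)
  cand <- integer(0)
  for (ps in probe_starts) {
    probe <- substr(right, ps, ps + 19)
    occ <- Biostrings::start(Biostrings::matchPattern(
      probe, Biostrings::DNAString(left)))
    cand <- c(cand, nl - (occ - ps))  # implied overlap length
  }
  cand <- sort(unique(cand[cand >= min_len & cand <= min(nl, nr)]),
               decreasing = TRUE)
  for (L in cand) {
    lchars <- substr(left, nl - L + 1, nl)
    rchars <- substr(right, 1, L)
    mism <- Biostrings::neditStartingAt(Biostrings::DNAString(lchars),
                                        Biostrings::DNAString(rchars),
                                        starting.at = 1, with.indels = FALSE)
    ident <- 1 - mism / L
    if (ident >= min_identity) {
      return(list(overlap_len = as.integer(L), identity = ident,
                  left_flank_len = nl, right_flank_len = nr))
    }
  }
  NULL
}

#' Decide whether to close a gap with redundant flanks
#'
#' Long-range evidence (mate-pair insert-size concordance, optical-molecule
#' spans) is abstracted to counts supporting a single copy of the flank
#' (redundancy: close and trim) versus two copies (true tandem repeat:
#' keep the gap). The gap is closed only when one-copy support strictly
#' exceeds two-copy support and reaches `min_support`; ties keep the gap —
#' sequence is never destroyed on ambiguous evidence.
#'
#' @param candidate result of [find_redundant_gap_flanks()].
#' @param one_copy,two_copy non-negative evidence counts.
#' @param min_support minimum one-copy count to close (default 5).
#' @return list: `decision` ("close_and_trim" or "keep_gap"), `one_copy`,
#'   `two_copy`, `min_support`, `overlap_len`.
#' @export
resolve_gap <- function(candidate, one_copy, two_copy, min_support = 5) {
  assert_that(one_copy >= 0 && two_copy >= 0, "evidence counts must be non-negative")
  decision <- if (!is.null(candidate) && one_copy > two_copy &&
                    one_copy >= min_support) "close_and_trim" else "keep_gap"
  list(decision = decision, one_copy = one_copy, two_copy = two_copy,
       min_support = min_support,
       overlap_len = candidate$overlap_len %||% NA_integer_)
}

#' Close a gap by trimming one copy of the redundant overlap
#'
#' Applies a `close_and_trim` decision: joins the flanks keeping a single
#' copy of the overlap, so joined length = left + right - overlap.
#'
#' @param left,right flank sequences (character or DNAString).
#' @param overlap_len overlap length from the candidate.
#' @return joined sequence (character).
#' @export
close_gap <- function(left, right, overlap_len) {
  left <- as.character(left); right <- as.character(right)
  paste0(left, substr(right, overlap_len + 1, nchar(right)))
}
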