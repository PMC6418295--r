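#' Derive a diverged query genome from a reference and an event plan
#'
#' Applies planted structural events to the reference in a fixed order —
#' translocations, then inversions, then insertions, then background SNPs —
#' so that every event's ancestor coordinates stay well defined, and emits a
#' liftover of every planted breakpoint into query coordinates.
#'
#' Background SNPs are never placed within 200 bp of a planted breakpoint,
#' keeping anchor alignment unambiguous near events.
#'
#' @param reference a genome list from [generate_reference()] (or any list
#'   with `genome` (DNAStringSet), `te_library`, `te_annotation` and `gc`).
#' @param plan an [sv_plan()] tibble (an empty plan is allowed).
#' @param snp_rate per-bp substitution probability for background SNPs.
#' @param seed integer seed for reproducibility.
#'
#' @return list with `genome` (query DNAStringSet) and `truth`, itself a list:
#'   `events` (plan rows with realized query coordinates `qry_chrom`,
#'   `qry_start`, `qry_end` and `te_fraction`), `liftover` (piece table
#'   mapping reference to query coordinates), `te_annotation` (TE intervals
#'   in query coordinates: lifted reference copies plus planted TE inserts),
#'   `snp_positions` (query coordinates) and `n_snps`.
#' @export
derive_variant_genome <- function(reference, plan = sv_plan(tibble()),
                                  snp_rate = 0, seed = NULL) {
  genome <- reference$genome
  if (nrow(plan) == 0 && !"event_id" %in% names(plan)) plan$event_id <- integer()
  check_plan_bounds(plan, genome)
  with_seed_or_not(seed, {
    pieces <- init_pieces(genome)
    ord <- c("inter_translocation", "intra_translocation", "inversion",
             "te_insertion", "novel_insertion")
    plan_ord <- plan[order(match(plan$kind, ord)), , drop = FALSE]
    ins_meta <- list()
    for (i in seq_len(nrow(plan_ord))) {
      ev <- plan_ord[i, ]
      pieces <- switch(ev$kind,
        inter_translocation = apply_inter_translocation(pieces, ev),
        intra_translocation = apply_intra_translocation(pieces, ev),
        inversion = apply_inversion(pieces, ev),
        te_insertion = ,
        novel_insertion = {
          res <- apply_insertion(pieces, ev, reference)
          ins_meta[[as.character(ev$event_id)]] <- res$meta
          res$pieces
        })
    }
    mat <- materialize_pieces(pieces, genome)
    truth_events <- locate_events(plan, mat$liftover, ins_meta)
    te_qry <- query_te_annotation(reference, mat$liftover, truth_events, ins_meta)
    snp <- apply_background_snps(mat$genome, mat$liftover, snp_rate)
    list(genome = snp$genome,
         truth = list(events = truth_events, liftover = mat$liftover,
                      te_annotation = te_qry,
                      snp_positions = snp$positions, n_snps = snp$n))
  })
}

check_plan_bounds <- function(plan, genome) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(plan))) {
    ev <- plan[i, ]
    assert_that(ev$chrom %in% names(lens),
                sprintf("event %d targets unknown chromosome %s", ev$event_id, ev$chrom))
    hi <- switch(ev$kind,
      inversion = ,
      intra_translocation = ev$pos + ev$length - 1,
      ev$pos)
    assert_that(ev$pos >= 1 && hi <= lens[[ev$chrom]],
                sprintf("event %d does not fit within %s", ev$event_id, ev$chrom))
    if (ev$kind == "inter_translocation")
      assert_that(!is.na(ev$chrom2) && ev$chrom2 %in% names(lens) &&
                    ev$pos2 >= 1 && ev$pos2 <= lens[[ev$chrom2]],
                  sprintf("event %d second breakpoint out of bounds", ev$event_id))
  }
  invisible(TRUE)
}

# ---- piece bookkeeping -----------------------------------------------------
# each query chromosome is an ordered tibble of pieces; a piece is either a
# reference interval (src_chrom/src_start/src_end, strand) or a literal
# insert (seq). event_id marks pieces created by an event.

init_pieces <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    tibble(src_chrom = ch, src_start = 1L,
           src_end = Biostrings::width(genome)[match(ch, names(genome))],
           strand = "+", seq = NA_character_, event_id = NA_integer_)
  })
  stats::setNames(out, names(genome))
}

# ensure a piece boundary exists immediately after ancestor position pos
split_after <- function(pieces, chrom, pos) {
  for (qc in names(pieces)) {
    p <- pieces[[qc]]
    hit <- which(!is.na(p$src_chrom) & p$src_chrom == chrom & p$strand == "+" &
                   p$src_start <= pos & p$src_end > pos)
    if (length(hit) == 1) {
      row <- p[hit, ]
      left <- mutate(row, src_end = as.integer(pos))
      right <- mutate(row, src_start = as.integer(pos + 1))
      after <- p[seq(hit + 1, length.out = nrow(p) - hit), , drop = FALSE]
      pieces[[qc]] <- bind_rows(p[seq_len(hit - 1), , drop = FALSE],
                                left, right, after)
      return(pieces)
    }
  }
  pieces  # boundary already exists (pos at a piece end) or pos beyond ends
}

# locate the (query chrom, piece index) whose source interval contains pos
find_piece <- function(pieces, chrom, pos) {
  for (qc in names(pieces)) {
    p <- pieces[[qc]]
    hit <- which(!is.na(p$src_chrom) & p$src_chrom == chrom &
                   p$src_start <= pos & p$src_end >= pos)
    if (length(hit)) return(list(qc = qc, idx = hit[1]))
  }
  abort(sprintf("internal: ancestor position %s:%d not found in pieces", chrom, pos))
}

apply_inter_translocation <- function(pieces, ev) {
  pieces <- split_after(pieces, ev$chrom, ev$pos)
  pieces <- split_after(pieces, ev$chrom2, ev$pos2)
  a <- find_piece(pieces, ev$chrom, ev$pos)
  b <- find_piece(pieces, ev$chrom2, ev$pos2)
  assert_that(a$qc != b$qc,
              sprintf("event %d: breakpoints resolve to the same query chromosome", ev$event_id))
  pa <- pieces[[a$qc]]; pb <- pieces[[b$qc]]
  heada <- pa[seq_len(a$idx), ]; taila <- pa[-seq_len(a$idx), , drop = FALSE]
  headb <- pb[seq_len(b$idx), ]; tailb <- pb[-seq_len(b$idx), , drop = FALSE]
  pieces[[a$qc]] <- bind_rows(heada, tailb)
  pieces[[b$qc]] <- bind_rows(headb, taila)
  pieces
}

apply_intra_translocation <- function(pieces, ev) {
  from <- ev$pos; to <- ev$pos + ev$length - 1
  pieces <- split_after(pieces, ev$chrom, from - 1)
  pieces <- split_after(pieces, ev$chrom, to)
  loc <- find_piece(pieces, ev$chrom, from)
  p <- pieces[[loc$qc]]
  seg_idx <- which(!is.na(p$src_chrom) & p$src_chrom == ev$chrom &
                     p$src_start >= from & p$src_end <= to)
  seg <- mutate(p[seg_idx, ], event_id = ev$event_id)
  p <- p[-seg_idx, , drop = FALSE]
  pieces[[loc$qc]] <- p
  pieces <- split_after(pieces, ev$chrom, ev$pos2)
  dest <- find_piece(pieces, ev$chrom, ev$pos2)
  pd <- pieces[[dest$qc]]
  at <- dest$idx
  pieces[[dest$qc]] <- bind_rows(pd[seq_len(at), ], seg,
                                 pd[-seq_len(at), , drop = FALSE])
  pieces
}

apply_inversion <- function(pieces, ev) {
  from <- ev$pos; to <- ev$pos + ev$length - 1
  pieces <- split_after(pieces, ev$chrom, from - 1)
  pieces <- split_after(pieces, ev$chrom, to)
  loc <- find_piece(pieces, ev$chrom, from)
  p <- pieces[[loc$qc]]
  seg_idx <- which(!is.na(p$src_chrom) & p$src_chrom == ev$chrom &
                     p$src_start >= from & p$src_end <= to)
  seg <- p[rev(seg_idx), ]
  seg$strand <- if_else(seg$strand == "+", "-", "+")
  seg$event_id <- ev$event_id
  p[seg_idx, ] <- seg
  pieces[[loc$qc]] <- p
  pieces
}

apply_insertion <- function(pieces, ev, reference) {
  len <- as.integer(ev$length)
  if (ev$kind == "te_insertion") {
    lib <- reference$te_library
    te_id <- ev$te_id
    if (is.na(te_id)) te_id <- sample(names(lib), 1)
    te_len <- as.integer(round(ev$te_fraction * len))
    el <- as.character(lib[[te_id]])
    te_seq <- paste(rep(el, ceiling(te_len / nchar(el))), collapse = "")
    te_seq <- substr(te_seq, 1, te_len)
    filler <- random_dna(len - te_len, reference$gc %||% 0.5)
    ins <- paste0(te_seq, filler)
    meta <- list(te_id = te_id, te_len = te_len,
                 te_fraction = te_len / len)
  } else {
    ins <- random_dna(len, reference$gc %||% 0.5)
    meta <- list(te_id = NA_character_, te_len = 0L, te_fraction = 0)
  }
  pieces <- split_after(pieces, ev$chrom, ev$pos)
  loc <- find_piece(pieces, ev$chrom, ev$pos)
  p <- pieces[[loc$qc]]
  newp <- tibble(src_chrom = NA_character_, src_start = NA_integer_,
                 src_end = NA_integer_, strand = "+", seq = ins,
                 event_id = ev$event_id)
  pieces[[loc$qc]] <- bind_rows(p[seq_len(loc$idx), ], newp,
                                p[-seq_len(loc$idx), , drop = FALSE])
  list(pieces = pieces, meta = meta)
}

materialize_pieces <- function(pieces, genome) {
  out_seqs <- character(length(pieces))
  lift <- list()
  for (i in seq_along(pieces)) {
    qc <- names(pieces)[i]
    p <- pieces[[qc]]
    segs <- character(nrow(p))
    w <- integer(nrow(p))
    for (j in seq_len(nrow(p))) {
      if (!is.na(p$seq[j])) {
        segs[j] <- p$seq[j]
      } else {
        s <- Biostrings::subseq(genome[[p$src_chrom[j]]], p$src_start[j], p$src_end[j])
        if (p$strand[j] == "-") s <- Biostrings::reverseComplement(s)
        segs[j] <- as.character(s)
      }
      w[j] <- nchar(segs[j])
    }
    qend <- cumsum(w)
    qstart <- qend - w + 1L
    out_seqs[i] <- paste(segs, collapse = "")
    lift[[i]] <- mutate(p, qry_chrom = qc, qry_start = as.integer(qstart),
                        qry_end = as.integer(qend), seq = NULL)
  }
  qry <- Biostrings::DNAStringSet(out_seqs)
  names(qry) <- names(pieces)
  list(genome = qry, liftover = bind_rows(lift))
}

# realized query coordinates of every planted event
locate_events <- function(plan, liftover, ins_meta) {
  if (nrow(plan) == 0) {
    return(mutate(plan, qry_chrom = character(), qry_start = integer(),
                  qry_end = integer()))
  }
  qc <- character(nrow(plan)); qs <- qe <- integer(nrow(plan))
  tef <- plan$te_fraction
  for (i in seq_len(nrow(plan))) {
    ev <- plan[i, ]
    if (ev$kind %in% c("te_insertion", "novel_insertion", "inversion",
                       "intra_translocation")) {
      rows <- filter(liftover, .data$event_id %in% ev$event_id)
      qc[i] <- rows$qry_chrom[1]
      qs[i] <- min(rows$qry_start); qe[i] <- max(rows$qry_end)
      if (ev$kind == "te_insertion")
        tef[i] <- ins_meta[[as.character(ev$event_id)]]$te_fraction
    } else {  # inter_translocation: junction on the first derived chromosome
      row <- filter(liftover, .data$src_chrom == ev$chrom &
                      .data$src_end == ev$pos & .data$strand == "+")
      qc[i] <- row$qry_chrom[1]
      qs[i] <- qe[i] <- row$qry_end[1]
    }
  }
  mutate(plan, qry_chrom = qc, qry_start = qs, qry_end = qe, te_fraction = tef)
}

# TE intervals in query coordinates: lifted reference annotation + TE inserts
query_te_annotation <- function(reference, liftover, truth_events, ins_meta) {
  lifted <- list()
  ann <- reference$te_annotation
  for (i in seq_len(nrow(ann))) {
    row <- lift_interval(liftover, ann$chrom[i], ann$start[i], ann$end[i])
    if (!is.null(row)) {
      lifted[[length(lifted) + 1]] <- mutate(row, te_id = ann$te_id[i])
    }
  }
  planted <- filter(truth_events, .data$kind == "te_insertion")
  if (nrow(planted)) {
    planted <- transmute(planted,
      chrom = .data$qry_chrom, start = .data$qry_start,
      end = .data$qry_start +
        map_int(.data$event_id, ~ ins_meta[[as.character(.x)]]$te_len) - 1L,
      te_id = map_chr(.data$event_id, ~ ins_meta[[as.character(.x)]]$te_id))
    lifted[[length(lifted) + 1]] <- planted
  }
  out <- bind_rows(lifted)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  te_id = character())
  }
  arrange(out, .data$chrom, .data$start)
}

#' Lift a reference position to query coordinates
#'
#' @param liftover piece table from [derive_variant_genome()] truth.
#' @param chrom,pos reference chromosome and 1-based position.
#' @return one-row tibble (`qry_chrom`, `qry_pos`) or `NULL` when the position
#'   falls on no lifted piece.
#' @export
lift_position <- function(liftover, chrom, pos) {
  hit <- filter(liftover, !is.na(.data$src_chrom) & .data$src_chrom == chrom &
                  .data$src_start <= pos & .data$src_end >= pos)
  if (nrow(hit) == 0) return(NULL)
  hit <- hit[1, ]
  qpos <- if (hit$strand == "+") hit$qry_start + (pos - hit$src_start)
          else hit$qry_end - (pos - hit$src_start)
  tibble(qry_chrom = hit$qry_chrom, qry_pos = as.integer(qpos))
}

# lift a closed reference interval fully contained in one piece
lift_interval <- function(liftover, chrom, start, end) {
  hit <- filter(liftover, !is.na(.data$src_chrom) & .data$src_chrom == chrom &
                  .data$src_start <= start & .data$src_end >= end)
  if (nrow(hit) == 0) return(NULL)
  hit <- hit[1, ]
  if (hit$strand == "+") {
    tibble(chrom = hit$qry_chrom,
           start = hit$qry_start + (start - hit$src_start),
           end = hit$qry_start + (end - hit$src_start))
  } else {
    tibble(chrom = hit$qry_chrom,
           start = hit$qry_end - (end - hit$src_start),
           end = hit$qry_end - (start - hit$src_start))
  }
}

apply_background_snps <- function(genome, liftover, snp_rate) {
  if (snp_rate <= 0) {
    return(list(genome = genome, positions = tibble(chrom = character(), pos = integer()),
                n = 0L))
  }
  pos_rows <- list()
  for (qc in names(genome)) {
    len <- Biostrings::width(genome)[match(qc, names(genome))]
    k <- rbinom(1, len, snp_rate)
    if (k == 0) next
    pos <- sort(sample.int(len, k))
    bnd <- filter(liftover, .data$qry_chrom == qc)
    bnd <- sort(unique(c(bnd$qry_start, bnd$qry_end)))
    # drop sites within 200 bp of any piece boundary (planted breakpoints)
    near <- vapply(pos, function(p) min(abs(p - bnd)) <= 200, logical(1))
    pos <- pos[!near]
    if (length(pos) == 0) next
    s <- as.character(genome[[qc]])
    cur <- substring(s, pos, pos)
    alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    genome[[qc]] <- Biostrings::replaceLetterAt(
      genome[[qc]], pos, paste(alt, collapse = ""))
    pos_rows[[qc]] <- tibble(chrom = qc, pos = as.integer(pos))
  }
  positions <- bind_rows(pos_rows)
  if (nrow(positions) == 0) {
    positions <- tibble(chrom = character(), pos = integer())
  }
  list(genome = genome, positions = positions, n = nrow(positions))
}
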