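#' Generate a random reference genome with TE and gene annotations
#'
#' Builds a synthetic ancestor genome to exercise the comparison pipeline:
#' random chromosomes at a target GC content, a library of transposable
#' element (TE) sequences (500 bp to 10 Kb), TE copies planted into the
#' chromosomes (recorded as annotation intervals), and non-overlapping gene
#' intervals. Everything is deterministic given `seed`.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths integer vector of chromosome lengths in bp (recycled to
#'   `n_chrom`). Chromosomes of at least 100 Kb are recommended so that
#'   window-based statistics are meaningful.
#' @param gc target GC fraction, strictly between 0 and 1.
#' @param te_library_size number of distinct TE elements to generate.
#' @param n_te_copies number of TE copies written into the genome (annotated).
#' @param n_genes number of non-overlapping gene intervals per genome.
#' @param seed integer seed; the generator is bit-reproducible given a seed.
#'
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet]),
#'   `te_library` (DNAStringSet), `te_annotation` (tibble: chrom, start, end,
#'   te_id; 1-based closed intervals), `genes` (tibble: gene_id, chrom,
#'   start, end, strand) and `gc` (the target GC used).
#' @export
generate_reference <- function(n_chrom = 1, lengths = 1e6, gc = 0.35,
                               te_library_size = 20, n_te_copies = 2 * te_library_size,
                               n_genes = 50, seed = NULL) {
  assert_that(is_scalar_number(gc) && gc > 0 && gc < 1,
              "`gc` must be strictly between 0 and 1")
  lengths <- as.integer(rep_len(lengths, n_chrom))
  assert_that(all(lengths > 0), "chromosome lengths must be positive")
  with_seed_or_not(seed, {
    chroms <- Biostrings::DNAStringSet(vapply(
      lengths, function(n) random_dna(n, gc), character(1)))
    names(chroms) <- paste0("chr", seq_len(n_chrom))

    te_lens <- sample(500:10000, te_library_size, replace = TRUE)
    te_library <- Biostrings::DNAStringSet(vapply(
      te_lens, function(n) random_dna(n, gc), character(1)))
    names(te_library) <- sprintf("TE%03d", seq_len(te_library_size))

    te_annotation <- plant_te_copies(chroms, te_library, n_te_copies)
    chroms <- te_annotation$genome
    genes <- sample_gene_intervals(lengths, names(chroms), n_genes)

    list(genome = chroms, te_library = te_library,
         te_annotation = te_annotation$intervals, genes = genes, gc = gc)
  })
}

# overwrite random windows with TE library copies; windows kept non-overlapping
plant_te_copies <- function(chroms, te_library, n_copies) {
  intervals <- list()
  if (n_copies > 0) {
    picks <- sample(length(te_library), n_copies, replace = TRUE)
    chrom_pick <- sample(length(chroms), n_copies, replace = TRUE)
    for (i in seq_len(n_copies)) {
      ci <- chrom_pick[i]
      w <- Biostrings::width(te_library)[picks[i]]
      len <- Biostrings::width(chroms)[ci]
      if (len < w + 2000) next
      start <- sample.int(len - w - 1000, 1) + 500
      # skip placements colliding with an earlier copy on the same chromosome
      prev <- intervals[vapply(intervals, function(x) x$chrom_i == ci, logical(1))]
      if (length(prev) && any(vapply(prev, function(x)
        start <= x$end && (start + w - 1) >= x$start, logical(1)))) next
      chroms[[ci]] <- Biostrings::replaceAt(
        chroms[[ci]], IRanges::IRanges(start, start + w - 1),
        as.character(te_library[[picks[i]]]))
      intervals[[length(intervals) + 1]] <- list(
        chrom_i = ci, start = start, end = start + w - 1,
        te_id = names(te_library)[picks[i]])
    }
  }
  tbl <- if (length(intervals)) {
    tibble(
      chrom = names(chroms)[vapply(intervals, `[[`, integer(1), "chrom_i")],
      start = vapply(intervals, function(x) as.integer(x$start), integer(1)),
      end = vapply(intervals, function(x) as.integer(x$end), integer(1)),
      te_id = vapply(intervals, `[[`, character(1), "te_id"))
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           te_id = character())
  }
  list(genome = chroms, intervals = arrange(tbl, .data$chrom, .data$start))
}

sample_gene_intervals <- function(lengths, chrom_names, n_genes) {
  out <- tibble(gene_id = character(), chrom = character(),
                start = integer(), end = integer(), strand = character())
  if (n_genes == 0) return(out)
  per_chrom <- table(sample(seq_along(lengths), n_genes, replace = TRUE,
                            prob = lengths / sum(lengths)))
  rows <- list()
  for (ci in as.integer(names(per_chrom))) {
    k <- per_chrom[[as.character(ci)]]
    glen <- pmin(sample(1000:5000, k, replace = TRUE), lengths[ci] %/% 4L)
    starts <- sort(sample.int(max(lengths[ci] - max(glen), 1), k))
    ends <- pmin(starts + glen - 1L, lengths[ci])
    keep <- !logical(k)
    if (k > 1) for (j in 2:k) if (starts[j] <= max(ends[seq_len(j - 1)][keep[seq_len(j - 1)]])) keep[j] <- FALSE
    rows[[length(rows) + 1]] <- tibble(
      chrom = chrom_names[ci], start = as.integer(starts[keep]),
      end = as.integer(ends[keep]), strand = sample(c("+", "-"), sum(keep), TRUE))
  }
  out <- bind_rows(rows)
  out <- arrange(out, .data$chrom, .data$start)
  mutate(out, gene_id = sprintf("gene%04d", row_number()),
         .before = "chrom")
}

#' Construct and validate a structural-variation plan
#'
#' A plan is a tibble of events to plant into an ancestor genome, one row per
#' event, with columns `kind` (one of `te_insertion`, `novel_insertion`,
#' `inversion`, `intra_translocation`, `inter_translocation`), `chrom`,
#' `pos` (1-based ancestor coordinate), `length` (bp; ignored for
#' inter-chromosomal translocations), `chrom2`/`pos2` (second breakpoint for
#' translocations), `te_id` (library element for TE insertions; `NA` samples
#' one) and `te_fraction` (fraction of the inserted sequence covered by the
#' TE element).
#'
#' Events must be non-overlapping in ancestor coordinates: insertions and
#' translocation breakpoints occupy their breakpoint position, inversions and
#' moved segments their full span. Overlaps are rejected with the offending
#' pair named.
#'
#' @param events a data frame with the columns above (missing optional
#'   columns are filled with `NA`/defaults).
#' @return the validated plan tibble, with class `sv_plan`.
#' @export
sv_plan <- function(events) {
  events <- as_tibble(events)
  if (is.null(events[["kind"]])) events$kind <- character()
  if (is.null(events[["chrom"]])) events$chrom <- character()
  if (is.null(events[["pos"]])) events$pos <- numeric()
  kinds <- c("te_insertion", "novel_insertion", "inversion",
             "intra_translocation", "inter_translocation")
  assert_that(all(events$kind %in% kinds),
              paste0("unknown event kind; must be one of: ",
                     paste(kinds, collapse = ", ")))
  for (col in c("chrom2", "te_id")) if (is.null(events[[col]]))
    events[[col]] <- NA_character_
  for (col in c("pos2", "length")) if (is.null(events[[col]]))
    events[[col]] <- NA_real_
  if (is.null(events[["te_fraction"]])) events$te_fraction <- NA_real_
  events$te_fraction <- if_else(
    events$kind == "te_insertion" & is.na(events$te_fraction), 1,
    events$te_fraction)
  events$event_id <- seq_len(nrow(events))
  if (nrow(events) == 0) {
    class(events) <- c("sv_plan", class(events))
    return(events)
  }

  iv <- plan_intervals(events)
  iv <- arrange(iv, .data$chrom, .data$start)
  if (nrow(iv) > 1) {
    for (ch in unique(iv$chrom)) {
      sub <- filter(iv, .data$chrom == ch)
      if (nrow(sub) > 1) {
        bad <- which(sub$start[-1] <= sub$end[-nrow(sub)])
        if (length(bad)) {
          abort(sprintf(
            "planted events %d and %d overlap on %s (ancestor coordinates)",
            sub$event_id[bad[1]], sub$event_id[bad[1] + 1], ch))
        }
      }
    }
  }
  class(events) <- c("sv_plan", class(events))
  events
}

# ancestor-coordinate footprint of each event, for overlap validation
plan_intervals <- function(events) {
  rows <- pmap(events, function(kind, chrom, pos, length, chrom2, pos2, ...) {
    ev <- list(...)$event_id
    switch(kind,
      te_insertion = ,
      novel_insertion = tibble(chrom = chrom, start = pos, end = pos, event_id = ev),
      inversion = tibble(chrom = chrom, start = pos, end = pos + length - 1, event_id = ev),
      intra_translocation = tibble(
        chrom = c(chrom, chrom), start = c(pos, pos2),
        end = c(pos + length - 1, pos2), event_id = ev),
      inter_translocation = tibble(
        chrom = c(chrom, chrom2), start = c(pos, pos2),
        end = c(pos, pos2), event_id = ev))
  })
  bind_rows(rows)
}
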