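# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the insertion oracle walks the two sequences
# base by base, the nxx oracle enumerates candidate lengths.

# insertions in `qry` relative to `ref` for sequences differing ONLY by
# insertions: returns tibble(ref_pos, qry_start, length) where ref_pos is
# the last reference base before the insertion
diff_insertion_oracle <- function(ref, qry, w = 40) {
  r <- strsplit(as.character(ref), "")[[1]]
  q <- strsplit(as.character(qry), "")[[1]]
  i <- 1L; j <- 1L
  out <- list()
  while (i <= length(r)) {
    if (j <= length(q) && r[i] == q[j]) {
      i <- i + 1L; j <- j + 1L
      next
    }
    win <- r[i:min(i + w - 1L, length(r))]
    d <- 1L
    repeat {
      cand <- q[(j + d):(j + d + length(win) - 1L)]
      if (length(cand) == length(win) && !anyNA(cand) && all(cand == win)) break
      d <- d + 1L
      if (j + d + length(win) > length(q) + 1L) stop("oracle: no resync (not insertion-only?)")
    }
    out[[length(out) + 1L]] <- data.frame(ref_pos = i - 1L, qry_start = j,
                                          length = d)
    j <- j + d
  }
  if (length(out) == 0) {
    return(data.frame(ref_pos = integer(), qry_start = integer(),
                      length = integer()))
  }
  do.call(rbind, out)
}

# largest candidate length L (among the input lengths, descending) with
# sum(lengths >= L) >= x% of total
nxx_oracle <- function(lengths, x) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= x / 100 * total) return(L)
  }
  min(lengths)
}

# covered fraction of [start, end] by intervals, via a per-base logical mask
coverage_fraction_oracle <- function(start, end, iv_start, iv_end) {
  mask <- logical(end - start + 1)
  for (k in seq_along(iv_start)) {
    lo <- max(iv_start[k], start); hi <- min(iv_end[k], end)
    if (lo <= hi) mask[(lo - start + 1):(hi - start + 1)] <- TRUE
  }
  mean(mask)
}

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# a compact repeat-free reference for alignment tests
tiny_reference <- function(len = 5e4, n_chrom = 1, seed = 1, gc = 0.45) {
  generate_reference(n_chrom = n_chrom, lengths = rep(len, n_chrom), gc = gc,
                     te_library_size = 0, n_te_copies = 0, n_genes = 0,
                     seed = seed)
}
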