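#' Nxx assembly statistic
#'
#' The smallest piece length L such that pieces of length >= L together
#' cover at least `x` percent of the total assembly (N50, N90, ...).
#'
#' @param lengths positive piece lengths in bp.
#' @param x percentage in (0, 100].
#' @return length in bp.
#' @export
nxx <- function(lengths, x = 50) {
  assert_that(length(lengths) > 0, "`lengths` must be non-empty")
  assert_that(all(lengths > 0), "`lengths` must be positive")
  assert_that(is_scalar_number(x) && x > 0 && x <= 100,
              "`x` must be in (0, 100]")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= x / 100 * sum(s))[1]]
}

#' Windowed feature-occupancy track
#'
#' Fraction of each sliding window covered by the union of feature
#' intervals (overlaps are unioned first, so occupancy never exceeds 1).
#' The default 1 Mb window with 500 Kb step matches common chromosome-scale
#' repeat/gene density tracks. The final partial window is normalized by its
#' actual span and flagged.
#'
#' @param features tibble of intervals (`start`, `end`, 1-based closed) on
#'   one chromosome.
#' @param chrom_len chromosome length in bp.
#' @param window window size in bp (default 1e6).
#' @param step step size in bp (default 5e5; must be <= window).
#' @return tibble (`start`, `end`, `occupancy`, `partial`).
#' @export
window_track <- function(features, chrom_len, window = 1e6, step = 5e5) {
  assert_that(window >= step, "`window` must be >= `step`")
  starts <- seq(1, max(chrom_len - step + 1, 1), by = step)
  ends <- pmin(starts + window - 1, chrom_len)
  red <- IRanges::reduce(IRanges::IRanges(
    pmax(features$start, 1), pmin(features$end, chrom_len)))
  win <- IRanges::IRanges(starts, ends)
  ov <- IRanges::findOverlaps(win, red)
  covered <- numeric(length(win))
  if (length(ov)) {
    inter_w <- IRanges::width(IRanges::pintersect(
      win[S4Vectors::queryHits(ov)], red[S4Vectors::subjectHits(ov)]))
    agg <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  tibble(start = as.integer(starts), end = as.integer(ends),
         occupancy = covered / (ends - starts + 1),
         partial = ends - starts + 1 < window)
}

#' GC-content track in non-overlapping windows
#'
#' (G+C)/(A+C+G+T) per window, so ambiguous bases (N) are excluded from the
#' denominator; a window with no unambiguous base is `NA`.
#'
#' @param seq a [Biostrings::DNAString] (or coercible character).
#' @param window window size in bp (default 200 Kb).
#' @return tibble (`start`, `end`, `gc`, `partial`).
#' @export
gc_track <- function(seq, window = 2e5) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  len <- length(seq)
  starts <- seq(1, len, by = window)
  ends <- pmin(starts + window - 1, len)
  v <- Biostrings::Views(seq, start = starts, end = ends)
  freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  acgt <- rowSums(freq)
  gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
  tibble(start = as.integer(starts), end = as.integer(ends), gc = gc,
         partial = ends - starts + 1 < window)
}

#' Detect telomeric tandem repeat arrays at chromosome ends
#'
#' Scans for tandem arrays of the plant telomeric motif (`CCCTAAA` on one
#' strand reads `TTTAGGG` on the other, so both strands are searched) with
#' at most one mismatch per motif copy. An end is telomeric when an array of
#' at least `min_copies` consecutive copies lies within `terminal_window` of
#' that end.
#'
#' @param seq chromosome sequence ([Biostrings::DNAString] or character).
#' @param motif telomeric motif (default `"CCCTAAA"`).
#' @param terminal_window terminal search window in bp (default 10 Kb).
#' @param min_copies minimum consecutive motif copies (default 10).
#' @param max_mismatch_per_copy mismatches tolerated per copy (default 1).
#' @return list: `status` ("both", "single", "none"), `start_end`,
#'   `distal_end` (logicals) and `arrays` (tibble `start`, `end`,
#'   `copy_count`, `strand`).
#' @export
detect_telomeres <- function(seq, motif = "CCCTAAA", terminal_window = 1e4,
                             min_copies = 10, max_mismatch_per_copy = 1) {
  assert_that(nchar(motif) > 0, "`motif` must be non-empty")
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  len <- length(seq)
  w <- nchar(motif)
  arrays <- bind_rows(
    motif_arrays(seq, motif, w, max_mismatch_per_copy, "+"),
    motif_arrays(seq, revcomp_chr(motif), w, max_mismatch_per_copy, "-"))
  arrays <- filter(arrays, .data$copy_count >= min_copies)
  start_end <- any(arrays$start <= terminal_window)
  distal_end <- any(arrays$end >= len - terminal_window + 1)
  status <- if (start_end && distal_end) "both"
            else if (start_end || distal_end) "single" else "none"
  list(status = status, start_end = start_end, distal_end = distal_end,
       arrays = arrange(arrays, .data$start))
}

# maximal chains of motif occurrences spaced exactly one motif length apart
motif_arrays <- function(seq, motif, w, max_mm, strand) {
  hits <- Biostrings::matchPattern(motif, seq, max.mismatch = max_mm,
                                   with.indels = FALSE)
  pos <- Biostrings::start(hits)
  if (length(pos) == 0) {
    return(tibble(start = integer(), end = integer(),
                  copy_count = integer(), strand = character()))
  }
  pos <- sort(unique(pos))
  run_id <- cumsum(c(TRUE, diff(pos) != w))
  grp <- split(pos, run_id)
  rows <- map(grp, function(p) {
    tibble(start = as.integer(min(p)), end = as.integer(max(p) + w - 1),
           copy_count = length(p), strand = strand)
  })
  bind_rows(rows)
}

#' Detect centromeric repeat arrays by monomer matching
#'
#' Substitution-only matches of a centromeric monomer (e.g. the soybean
#' 91/92 bp classes; monomers are user inputs, not bundled) at
#' `>= min_identity` on both strands; hits closer than one monomer length
#' are merged and merged spans of at least `min_span` are reported.
#'
#' @param seq chromosome sequence.
#' @param monomer monomer sequence (>= 20 bp).
#' @param min_identity minimum per-hit identity (default 0.8).
#' @param min_span minimum merged span in bp (default 5 monomer lengths).
#' @return tibble (`start`, `end`, `n_hits`).
#' @export
detect_centromeric_repeats <- function(seq, monomer, min_identity = 0.8,
                                       min_span = 5 * nchar(monomer)) {
  assert_that(nchar(monomer) >= 20, "`monomer` must be at least 20 bp")
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  w <- nchar(monomer)
  max_mm <- floor(w * (1 - min_identity))
  pos <- integer(0)
  for (m in c(monomer, revcomp_chr(monomer))) {
    hits <- Biostrings::matchPattern(m, seq, max.mismatch = max_mm,
                                     with.indels = FALSE)
    pos <- c(pos, Biostrings::start(hits))
  }
  if (length(pos) == 0) {
    return(tibble(start = integer(), end = integer(), n_hits = integer()))
  }
  ir <- IRanges::IRanges(start = pos, width = w)
  merged <- IRanges::reduce(ir, min.gapwidth = w)
  hits_per <- IRanges::countOverlaps(merged, ir)
  out <- tibble(start = IRanges::start(merged), end = IRanges::end(merged),
                n_hits = as.integer(hits_per))
  filter(out, .data$end - .data$start + 1 >= min_span)
}

#' In silico PCR
#'
#' Finds binding sites of each primer on both strands with at most
#' `max_mismatch` substitutions and an exact 3'-terminal trinucleotide, then
#' forms products from site pairs on opposite strands with facing 3' ends
#' and product size strictly below `max_product`. Pairs with exactly one
#' product at their best (fewest total mismatches) tier are retained; pairs
#' with none or with multiple best products are reported as filtered,
#' mirroring standard electronic-PCR practice.
#'
#' @param genome [Biostrings::DNAStringSet] (or list with `genome`).
#' @param pairs tibble of primer pairs: `id`, `fwd`, `rev` (A/C/G/T only,
#'   >= 15 bp).
#' @param max_product maximum product size in bp (strict `<`; default 1000).
#' @param max_mismatch substitutions tolerated per primer (default 2).
#' @return list: `retained` (tibble `id`, `chrom`, `start`, `end`,
#'   `product_size`, `orientation`, `mismatches`) and `rejected` (tibble
#'   `id`, `reason` in `no_hit`/`multi_hit`).
#' @export
in_silico_pcr <- function(genome, pairs, max_product = 1000, max_mismatch = 2) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  assert_that(all(grepl("^[ACGT]+$", pairs$fwd)) &&
                all(grepl("^[ACGT]+$", pairs$rev)),
              "primers must contain only A/C/G/T (no degenerate bases)")
  assert_that(all(nchar(pairs$fwd) >= 15) && all(nchar(pairs$rev) >= 15),
              "primers must be at least 15 bp")
  retained <- list(); rejected <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    prods <- pcr_products(genome, pr$fwd, pr$rev, max_product, max_mismatch)
    if (nrow(prods) == 0) {
      rejected[[length(rejected) + 1]] <- tibble(id = pr$id, reason = "no_hit")
      next
    }
    best <- filter(prods, .data$mismatches == min(.data$mismatches))
    if (nrow(best) > 1) {
      rejected[[length(rejected) + 1]] <- tibble(id = pr$id, reason = "multi_hit")
    } else {
      retained[[length(retained) + 1]] <- mutate(best, id = pr$id, .before = 1)
    }
  }
  list(
    retained = if (length(retained)) bind_rows(retained) else
      tibble(id = character(), chrom = character(), start = integer(),
             end = integer(), product_size = integer(),
             orientation = character(), mismatches = integer()),
    rejected = if (length(rejected)) bind_rows(rejected) else
      tibble(id = character(), reason = character()))
}

# all valid products of one primer pair over all chromosomes
pcr_products <- function(genome, fwd, rev, max_product, max_mismatch) {
  rows <- list()
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    # plus-strand sites of each primer, and minus-strand sites (searched as
    # the reverse complement on the plus strand; 3' end faces leftward)
    sf_p <- primer_sites(seq, fwd, max_mismatch, minus = FALSE)
    sr_m <- primer_sites(seq, rev, max_mismatch, minus = TRUE)
    sr_p <- primer_sites(seq, rev, max_mismatch, minus = FALSE)
    sf_m <- primer_sites(seq, fwd, max_mismatch, minus = TRUE)
    rows[[length(rows) + 1]] <- orient_products(sf_p, sr_m, ch, max_product, "FR")
    rows[[length(rows) + 1]] <- orient_products(sr_p, sf_m, ch, max_product, "RF")
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  product_size = integer(), orientation = character(),
                  mismatches = integer())
  }
  distinct(out)
}

# binding sites with <= max_mm substitutions and exact 3'-terminal 3 bases;
# coordinates are always the plus-strand interval of the site
primer_sites <- function(seq, primer, max_mm, minus) {
  pat <- if (minus) revcomp_chr(primer) else primer
  hits <- Biostrings::matchPattern(pat, seq, max.mismatch = max_mm,
                                   with.indels = FALSE)
  if (length(hits) == 0) {
    return(tibble(start = integer(), end = integer(), mm = integer()))
  }
  mm <- Biostrings::neditAt(pat, seq, at = Biostrings::start(hits),
                            with.indels = FALSE)
  # 3' end: last 3 bases of the primer = last 3 of plus pattern, or first 3
  # of the minus-strand pattern on plus coordinates
  tri <- if (minus) substr(pat, 1, 3) else substr(pat, nchar(pat) - 2, nchar(pat))
  obs <- as.character(Biostrings::extractAt(seq, IRanges::IRanges(
    start = if (minus) Biostrings::start(hits) else Biostrings::end(hits) - 2,
    width = 3)))
  ok <- obs == tri
  tibble(start = Biostrings::start(hits)[ok], end = Biostrings::end(hits)[ok],
         mm = as.integer(mm)[ok])
}

orient_products <- function(plus_sites, minus_sites, ch, max_product, orientation) {
  if (nrow(plus_sites) == 0 || nrow(minus_sites) == 0) return(NULL)
  grid <- expand.grid(p = seq_len(nrow(plus_sites)),
                      m = seq_len(nrow(minus_sites)))
  ps <- plus_sites[grid$p, ]; ms <- minus_sites[grid$m, ]
  size <- ms$end - ps$start + 1
  ok <- ms$start > ps$end & size > 0 & size < max_product
  if (!any(ok)) return(NULL)
  tibble(chrom = ch, start = as.integer(ps$start[ok]),
         end = as.integer(ms$end[ok]), product_size = as.integer(size[ok]),
         orientation = orientation, mismatches = as.integer(ps$mm[ok] + ms$mm[ok]))
}
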