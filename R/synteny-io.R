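#' Read whole-genome alignment blocks
#'
#' Parses aligner output into the internal 1-based inclusive block
#' convention. Two dialects are supported: `"coords"`, the tab-delimited
#' `show-coords -rclT` table of the MUMmer suite (S1 E1 S2 E2 LEN1 LEN2
#' %IDY LENR LENQ COVR COVQ REF QRY), and `"paf"`, the 12+ column PAF format
#' of minimap2-style aligners. PAF's 0-based half-open query/target
#' coordinates are shifted to 1-based inclusive; minus-strand query
#' intervals are normalized to start <= end with the strand recorded; percent
#' identity in coords is converted to a fraction, and PAF identity is
#' `matches / alignment_length`.
#'
#' In PAF the *target* is taken as the reference genome and the *query* as
#' the query genome.
#'
#' @param path file path.
#' @param dialect `"coords"` or `"paf"`.
#' @return alignment block tibble (see [anchor_align()]).
#' @export
read_alignment_blocks <- function(path, dialect = c("coords", "paf")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "coords") {
    parse_coords_lines(fields)
  } else {
    parse_paf_lines(fields)
  }
}

parse_coords_lines <- function(fields) {
  rows <- imap(fields, function(f, i) {
    if (length(f) < 13) abort(sprintf("malformed coords line %d: expected 13 fields, got %d", i, length(f)))
    num <- suppressWarnings(as.numeric(f[1:11]))
    if (anyNA(num)) abort(sprintf("malformed coords line %d: non-numeric coordinate field", i))
    s2 <- num[3]; e2 <- num[4]
    tibble(ref_chrom = f[12], ref_start = as.integer(num[1]), ref_end = as.integer(num[2]),
           qry_chrom = f[13], qry_start = as.integer(min(s2, e2)),
           qry_end = as.integer(max(s2, e2)),
           strand = if (s2 <= e2) "+" else "-",
           identity = num[7] / 100)
  })
  bind_rows(rows)
}

parse_paf_lines <- function(fields) {
  rows <- imap(fields, function(f, i) {
    if (length(f) < 12) abort(sprintf("malformed PAF line %d: expected >= 12 fields, got %d", i, length(f)))
    num <- suppressWarnings(as.numeric(f[c(2:4, 7:12)]))
    if (anyNA(num)) abort(sprintf("malformed PAF line %d: non-numeric coordinate field", i))
    if (!f[5] %in% c("+", "-")) abort(sprintf("malformed PAF line %d: bad strand '%s'", i, f[5]))
    tibble(ref_chrom = f[6],
           ref_start = as.integer(num[5] + 1), ref_end = as.integer(num[6]),
           qry_chrom = f[1],
           qry_start = as.integer(num[2] + 1), qry_end = as.integer(num[3]),
           strand = f[5],
           identity = num[7] / num[8])
  })
  bind_rows(rows)
}

#' Write alignment blocks
#'
#' Inverse of [read_alignment_blocks()]: emits either the tab `coords`
#' table (with query coordinates swapped on the minus strand, as MUMmer
#' prints them) or 12-column PAF. Round-trips losslessly for the fields the
#' block model carries.
#'
#' @param blocks alignment block tibble.
#' @param path output path.
#' @param dialect `"coords"` or `"paf"`.
#' @param ref_lengths,qry_lengths optional named vectors of sequence lengths
#'   used for the length/coverage columns; unknown lengths are written as the
#'   block span (coverage then refers to the block itself).
#' @return `path`, invisibly.
#' @export
write_alignment_blocks <- function(blocks, path, dialect = c("coords", "paf"),
                                   ref_lengths = NULL, qry_lengths = NULL) {
  dialect <- match.arg(dialect)
  rl <- function(ch, span) if (!is.null(ref_lengths) && ch %in% names(ref_lengths))
    ref_lengths[[ch]] else span
  ql <- function(ch, span) if (!is.null(qry_lengths) && ch %in% names(qry_lengths))
    qry_lengths[[ch]] else span
  lines <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    len1 <- b$ref_end - b$ref_start + 1
    len2 <- b$qry_end - b$qry_start + 1
    lenr <- rl(b$ref_chrom, len1); lenq <- ql(b$qry_chrom, len2)
    if (dialect == "coords") {
      s2 <- if (b$strand == "+") b$qry_start else b$qry_end
      e2 <- if (b$strand == "+") b$qry_end else b$qry_start
      lines[i] <- paste(c(b$ref_start, b$ref_end, s2, e2, len1, len2,
                          sprintf("%.2f", b$identity * 100), lenr, lenq,
                          sprintf("%.2f", 100 * len1 / lenr),
                          sprintf("%.2f", 100 * len2 / lenq),
                          b$ref_chrom, b$qry_chrom), collapse = "\t")
    } else {
      alen <- max(len1, len2)
      lines[i] <- paste(c(b$qry_chrom, lenq, b$qry_start - 1, b$qry_end,
                          b$strand, b$ref_chrom, lenr, b$ref_start - 1,
                          b$ref_end, round(b$identity * alen), alen, 60),
                        collapse = "\t")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
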