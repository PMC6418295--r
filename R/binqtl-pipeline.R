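#' Sliding-window breakpoints for every line of a SNP table
#'
#' Convenience wrapper running [sliding_window_genotypes()] and
#' [detect_breakpoints()] per line and chromosome of a (filtered) SNP call
#' table, also recording each line's starting homozygous state, which
#' [build_binmap()] needs.
#'
#' @param geno SNP table (see [filter_snps()]): `chrom`, `pos`, optional
#'   metadata columns, then one column per line.
#' @inheritParams sliding_window_genotypes
#' @return list: `breakpoints` (tibble `line`, `chrom`, `pos`,
#'   `interval_start`, `interval_end`, `from`, `to`), `line_states` (tibble
#'   `line`, `chrom`, `state`).
#' @export
ril_breakpoints <- function(geno, window = 15, step = 1, majority = 11,
                            min_informative = 5) {
  meta_cols <- intersect(c("chrom", "pos", "qual", "allele_a", "allele_b"),
                         names(geno))
  line_cols <- setdiff(names(geno), meta_cols)
  bp_rows <- list(); st_rows <- list()
  for (ch in unique(geno$chrom)) {
    sub <- geno[geno$chrom == ch, , drop = FALSE]
    pos <- sub$pos
    for (lc in line_cols) {
      wc <- sliding_window_genotypes(sub[[lc]], pos, window, step,
                                     majority, min_informative)
      hom <- wc$call[wc$call %in% c("A", "B")]
      st_rows[[length(st_rows) + 1]] <- tibble(
        line = lc, chrom = ch,
        state = if (length(hom)) hom[1] else "-")
      bp <- detect_breakpoints(wc)
      if (nrow(bp)) {
        bp_rows[[length(bp_rows) + 1]] <- mutate(bp, line = lc, chrom = ch,
                                                 .before = 1)
      }
    }
  }
  breakpoints <- if (length(bp_rows)) bind_rows(bp_rows) else
    tibble(line = character(), chrom = character(), from = character(),
           to = character(), interval_start = numeric(),
           interval_end = numeric(), pos = numeric())
  list(breakpoints = breakpoints, line_states = bind_rows(st_rows))
}
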