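#' Simulate optical molecules from a source map
#'
#' Molecules are random subintervals of a source optical map. True labels
#' inside the molecule window are perturbed by Gaussian sizing error, dropped
#' at a false-negative rate, and mixed with false labels at a rate per
#' 100 Kb of molecule length. Each molecule carries a length, a label count
#' and an opaque signal intensity drawn from `intensity_dist`, matching the
#' attributes used by downstream molecule quality control.
#'
#' @param map a one-row map tibble (see [digest()]) or a list with `id`,
#'   `length` and `labels`.
#' @param n number of molecules; `n = 0` returns an empty tibble.
#' @param length_dist function of `n` returning molecule lengths in bp
#'   (default: uniform 150-400 Kb, the upper range of real runs).
#' @param label_fn_rate per-label drop-out probability in [0,1).
#' @param label_fp_rate_per_100kb expected false labels per 100 Kb.
#' @param sizing_sd Gaussian label sizing error SD in bp (>= 0).
#' @param intensity_dist function of `n` returning molecule intensities
#'   (default: uniform 0.2-0.55, passing the 0.6 QC ceiling).
#' @param seed integer seed.
#'
#' @return tibble with one row per molecule: `molecule_id`, `length`,
#'   `intensity`, `n_labels`, `labels` (list column of sorted positions),
#'   plus truth columns `source_start`, `source_end`, `n_true`, `n_dropped`,
#'   `n_false`.
#' @export
simulate_optical_molecules <- function(map, n,
                                       length_dist = function(n) runif(n, 150e3, 400e3),
                                       label_fn_rate = 0,
                                       label_fp_rate_per_100kb = 0,
                                       sizing_sd = 0,
                                       intensity_dist = function(n) runif(n, 0.2, 0.55),
                                       seed = NULL) {
  assert_that(label_fn_rate >= 0 && label_fn_rate < 1 &&
                label_fp_rate_per_100kb >= 0,
              "rates must lie in [0, 1) / be non-negative")
  assert_that(sizing_sd >= 0, "`sizing_sd` must be >= 0")
  if (is.data.frame(map)) map <- as.list(map[1, ])
  src_labels <- sort(unlist(map$labels))
  src_len <- map$length
  empty <- tibble(molecule_id = character(), length = numeric(),
                  intensity = numeric(), n_labels = integer(),
                  labels = list(), source_start = numeric(),
                  source_end = numeric(), n_true = integer(),
                  n_dropped = integer(), n_false = integer())
  if (n == 0) return(empty)
  with_seed_or_not(seed, {
    lens <- pmin(pmax(round(length_dist(n)), 1), src_len)
    starts <- vapply(lens, function(L) sample.int(src_len - L + 1, 1), numeric(1))
    intens <- intensity_dist(n)
    rows <- map(seq_len(n), function(i) {
      L <- lens[i]; s <- starts[i]
      inside <- src_labels[src_labels >= s & src_labels <= s + L - 1]
      rel <- inside - s + 1
      n_true <- length(rel)
      keep <- runif(n_true) >= label_fn_rate
      rel <- rel[keep]
      if (sizing_sd > 0 && length(rel)) {
        rel <- pmin(pmax(round(rel + rnorm(length(rel), sd = sizing_sd)), 1), L)
      }
      n_fp <- rpois(1, label_fp_rate_per_100kb * L / 1e5)
      fp <- if (n_fp > 0) sample.int(L, min(n_fp, L)) else numeric(0)
      labs <- sort(unique(c(rel, fp)))
      tibble(molecule_id = sprintf("mol%05d", i), length = L,
             intensity = intens[i], n_labels = length(labs),
             labels = list(labs), source_start = s, source_end = s + L - 1,
             n_true = n_true, n_dropped = n_true - sum(keep),
             n_false = length(fp))
    })
    bind_rows(rows)
  })
}
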