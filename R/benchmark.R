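#' Standard planted-variation benchmark genome pair
#'
#' The package's reference evaluation scenario: a 10 Mb, 3-chromosome
#' ancestor genome and a derived query carrying five TE/novel insertions of
#' 1.5-8 Kb with TE occupancies straddling the 0.8 classification threshold
#' (0.95, 0.88, 0.82, 0.80, 0.65), a 150 Kb inversion, a 90 Kb inversion
#' (below the large-SV reporting threshold), a reciprocal inter-chromosomal
#' translocation exchanging the 1 Mb tails of two chromosomes, and
#' background SNPs at 2 x 10^-3 per bp — divergence in the range seen
#' between wild and cultivated soybean assemblies.
#'
#' @param seed integer seed controlling both the ancestor and the derived
#'   query.
#' @return list: `reference` (see [generate_reference()]), `plan`
#'   (the [sv_plan()]), `query` (DNAStringSet) and `truth` (see
#'   [derive_variant_genome()]).
#' @export
sv_benchmark <- function(seed = 1) {
  ref <- generate_reference(
    n_chrom = 3, lengths = c(4e6, 3e6, 3e6), gc = 0.35,
    te_library_size = 20, n_genes = 200, seed = seed)
  plan <- sv_plan(tibble::tribble(
    ~kind,                 ~chrom,  ~pos,   ~length, ~chrom2, ~pos2, ~te_fraction,
    "inter_translocation", "chr1",  3e6,    NA,      "chr2",  2e6,   NA,
    "inversion",           "chr1",  1e6,    15e4,    NA,      NA,    NA,
    "inversion",           "chr2",  1e6,    9e4,     NA,      NA,    NA,
    "te_insertion",        "chr3",  5e5,    1500,    NA,      NA,    0.95,
    "te_insertion",        "chr3",  15e5,   8000,    NA,      NA,    0.88,
    "te_insertion",        "chr3",  25e5,   3000,    NA,      NA,    0.82,
    "te_insertion",        "chr2",  5e5,    2000,    NA,      NA,    0.80,
    "te_insertion",        "chr2",  28e5,   5000,    NA,      NA,    0.65))
  vg <- derive_variant_genome(ref, plan, snp_rate = 0.002,
                              seed = seed + 1)
  list(reference = ref, plan = plan, query = vg$genome, truth = vg$truth)
}
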