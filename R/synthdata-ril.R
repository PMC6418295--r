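#' Simulate a recombinant inbred line (RIL) population with planted truth
#'
#' Crossovers per line and chromosome are drawn Poisson with mean
#' `genetic_length_cM / 50`: one expected crossover per Morgan per F1
#' meiosis, doubled for the classical map expansion of selfed RILs, so that
#' multi-generation selfing does not need to be simulated explicitly. Lines
#' are fully homozygous mosaics of the two parents (A/B); observed genotype
#' calls can carry missingness and genotyping error. The phenotype is the sum
#' of additive QTL effects plus Gaussian noise calibrated so that realized
#' heritability converges to `h2` for large populations.
#'
#' @param n_lines number of RI lines (>= 2).
#' @param chrom_lengths_cM named numeric vector of chromosome genetic lengths
#'   in centiMorgans.
#' @param n_snps total number of SNP loci, distributed over chromosomes
#'   proportionally to genetic length (uniform in bp within a chromosome).
#' @param qtl optional tibble (`chrom`, `pos` in bp, `effect`) of additive
#'   QTLs; genotype coded A = +1, B = -1, so a QTL contributes `effect * x`.
#' @param h2 narrow-sense heritability in (0,1); required when `qtl` is given.
#' @param missing_rate per-call probability of a missing genotype.
#' @param genotype_error_rate per-call probability that a homozygous call is
#'   flipped to the other parent.
#' @param bp_per_cM physical scale of the genome (bp per cM); chromosome
#'   physical length = genetic length * `bp_per_cM`.
#' @param seed integer seed; identical seeds give identical genotype matrices.
#'
#' @return list with `geno` (tibble: chrom, pos, qual, then one column per
#'   line with calls in A/B/H/-), `pheno` (tibble: line, phenotype) and
#'   `truth` (list: `crossovers` tibble (line, chrom, pos), `initial_state`
#'   tibble, `geno_true` matrix lines x SNPs, `qtl`, `h2`, `sigma_e`,
#'   `genetic_values`).
#' @export
simulate_ril_population <- function(n_lines, chrom_lengths_cM, n_snps,
                                    qtl = NULL, h2 = NULL,
                                    missing_rate = 0, genotype_error_rate = 0,
                                    bp_per_cM = 1e5, seed = NULL) {
  assert_that(n_lines >= 2, "`n_lines` must be >= 2")
  assert_that(missing_rate >= 0 && missing_rate < 1 &&
                genotype_error_rate >= 0 && genotype_error_rate < 1,
              "rates must lie in [0, 1)")
  if (!is.null(qtl) && nrow(qtl) > 0) {
    assert_that(is_scalar_number(h2) && h2 > 0 && h2 < 1,
                "`h2` must be strictly between 0 and 1 when QTLs are planted")
  }
  if (is.null(names(chrom_lengths_cM)))
    names(chrom_lengths_cM) <- paste0("chr", seq_along(chrom_lengths_cM))
  chrom_bp <- pmax(1L, as.integer(round(chrom_lengths_cM * bp_per_cM)))

  with_seed_or_not(seed, {
    # SNP loci: apportion across chromosomes, uniform in bp
    weights <- if (sum(chrom_lengths_cM) > 0) chrom_lengths_cM else rep(1, length(chrom_bp))
    n_per <- round_apportion(n_snps, weights / sum(weights))
    loci <- bind_rows(imap(stats::setNames(n_per, names(chrom_lengths_cM)),
      function(k, ch) {
        nb <- chrom_bp[[match(ch, names(chrom_lengths_cM))]]
        tibble(chrom = ch, pos = sort(sample_positions(min(k, nb), nb)))
      }))
    lines <- sprintf("RIL%03d", seq_len(n_lines))

    xo_rows <- list()
    init <- matrix("A", n_lines, length(chrom_lengths_cM),
                   dimnames = list(lines, names(chrom_lengths_cM)))
    geno_true <- matrix(NA_character_, n_lines, nrow(loci),
                        dimnames = list(lines, NULL))
    for (ci in seq_along(chrom_lengths_cM)) {
      ch <- names(chrom_lengths_cM)[ci]
      idx <- which(loci$chrom == ch)
      pos <- loci$pos[idx]
      for (li in seq_len(n_lines)) {
        n_xo <- rpois(1, chrom_lengths_cM[[ci]] / 50)
        xo <- sort(sample_positions(min(n_xo, chrom_bp[[ci]] - 1L),
                                    chrom_bp[[ci]] - 1L))
        start_allele <- sample(c("A", "B"), 1)
        init[li, ci] <- start_allele
        if (length(xo)) {
          xo_rows[[length(xo_rows) + 1]] <-
            tibble(line = lines[li], chrom = ch, pos = xo)
        }
        seg <- findInterval(pos, xo + 0.5)  # segment index per SNP
        flip <- seg %% 2 == 1
        g <- rep(start_allele, length(pos))
        g[flip] <- if (start_allele == "A") "B" else "A"
        geno_true[li, idx] <- g
      }
    }
    crossovers <- if (length(xo_rows)) bind_rows(xo_rows) else
      tibble(line = character(), chrom = character(), pos = integer())

    # phenotype
    if (!is.null(qtl) && nrow(qtl) > 0) {
      x <- vapply(seq_len(nrow(qtl)), function(i) {
        st <- genotype_state_at(crossovers, init, lines, qtl$chrom[i], qtl$pos[i])
        if_else(st == "A", 1, -1)
      }, numeric(n_lines))
      g <- as.numeric(x %*% qtl$effect)
      sigma_e <- sqrt(sum(qtl$effect^2) * (1 - h2) / h2)
    } else {
      g <- numeric(n_lines)
      sigma_e <- 1
    }
    pheno <- tibble(line = lines, phenotype = g + rnorm(n_lines, sd = sigma_e))

    # observed calls with error and missingness
    obs <- geno_true
    if (genotype_error_rate > 0) {
      err <- matrix(runif(length(obs)) < genotype_error_rate, nrow(obs))
      obs[err] <- if_else(geno_true[err] == "A", "B", "A")
    }
    if (missing_rate > 0) {
      obs[matrix(runif(length(obs)) < missing_rate, nrow(obs))] <- "-"
    }
    geno <- bind_cols(
      mutate(loci, qual = round(runif(nrow(loci), 40, 60), 1)),
      as_tibble(stats::setNames(as.data.frame(t(obs), stringsAsFactors = FALSE),
                                lines)))
    list(geno = geno, pheno = pheno,
         truth = list(crossovers = crossovers,
                      initial_state = as_tibble(init, rownames = "line"),
                      geno_true = geno_true, qtl = qtl, h2 = h2,
                      sigma_e = sigma_e, genetic_values = g))
  })
}

# k distinct positions in 1..n without the O(n) allocation of sample.int
sample_positions <- function(k, n) {
  if (k <= 0 || n <= 0) return(integer(0))
  pos <- unique(ceiling(runif(k * 1.1 + 5) * n))
  while (length(pos) < k) pos <- unique(c(pos, ceiling(runif(k) * n)))
  pos[seq_len(k)]
}

# integer apportionment of n among weights (largest remainder)
round_apportion <- function(n, w) {
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# true parental state of every line at one physical position
genotype_state_at <- function(crossovers, init, lines, chrom, pos) {
  vapply(seq_along(lines), function(li) {
    xo <- crossovers$pos[crossovers$line == lines[li] & crossovers$chrom == chrom]
    n_before <- sum(xo < pos)
    st <- init[li, chrom]
    if (n_before %% 2 == 1) st <- if (st == "A") "B" else "A"
    st
  }, character(1))
}
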