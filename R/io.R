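#' Genome and annotation writers
#'
#' Thin wrappers around the standard Bioconductor exporters so every
#' synthetic dataset can be written to (and read back from) the field's
#' plain-text formats: FASTA for genomes, GFF3 for genes, BED for TE
#' intervals (0-based half-open on disk, converted at the boundary), TSV
#' for genotype matrices and phenotypes, JSON for truth objects.
#'
#' @param genome a [Biostrings::DNAStringSet] (or list with `genome`).
#' @param path output path.
#' @return `path`, invisibly.
#' @name soykit-io
NULL

#' @rdname soykit-io
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname soykit-io
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname soykit-io
#' @param intervals tibble with `chrom`, `start`, `end` (1-based closed) and
#'   an id column (`te_id`/`gene_id`/`name`).
#' @export
write_bed <- function(intervals, path) {
  idcol <- intersect(c("te_id", "gene_id", "name"), names(intervals))[1]
  df <- tibble(chrom = intervals$chrom, start = intervals$start - 1L,
               end = intervals$end,
               name = if (!is.na(idcol)) intervals[[idcol]] else ".")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname soykit-io
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                        col_types = "ciic")
  transmute(df, chrom = .data$chrom, start = .data$start + 1L,
            end = .data$end, name = .data$name)
}

#' @rdname soykit-io
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsoykit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname soykit-io
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble(gene_id = sub("^ID=", "", map_chr(f, 9)),
         chrom = map_chr(f, 1),
         start = as.integer(map_chr(f, 4)),
         end = as.integer(map_chr(f, 5)),
         strand = map_chr(f, 7))
}

#' @rdname soykit-io
#' @param geno genotype tibble (see [filter_snps()]).
#' @export
write_genotypes_tsv <- function(geno, path) {
  readr::write_tsv(geno, path)
  invisible(path)
}

#' @rdname soykit-io
#' @export
read_genotypes_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    .default = readr::col_character()))
}

#' @rdname soykit-io
#' @param truth any truth list (tibbles are flattened to data frames).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
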