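#' Write an optical map tibble as CMAP v0.1
#'
#' Emits the minimal single-channel column set (CMapId, ContigLength,
#' NumSites, SiteID, LabelChannel, Position, StdDev, Coverage, Occurrence),
#' one site row per label plus the conventional end-of-map row (channel 0 at
#' the map length).
#'
#' @param maps map tibble (see [digest()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# CMAP File Version:\t0.1",
               "# Label Channels:\t1",
               paste0("#h CMapId\tContigLength\tNumSites\tSiteID\t",
                      "LabelChannel\tPosition\tStdDev\tCoverage\tOccurrence"),
               paste0("#f int\tfloat\tint\tint\tint\tfloat\tfloat\tint\tint")),
             con)
  for (i in seq_len(nrow(maps))) {
    labs <- sort(unlist(maps$labels[[i]]))
    n <- length(labs)
    id <- i
    rows <- sprintf("%d\t%.1f\t%d\t%d\t%d\t%.1f\t%.1f\t%d\t%d",
                    id, maps$length[i], n, seq_len(n + 1),
                    c(rep(1L, n), 0L), c(labs, maps$length[i]),
                    1, 1, 1)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a CMAP file into a map tibble
#'
#' @param path CMAP path (v0.1-style single channel).
#' @param ids optional character map ids (defaults to `map<CMapId>`).
#' @return map tibble with `id`, `length`, `n_labels`, `labels`, `channel`.
#' @export
read_cmap <- function(path, ids = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(id = character(), length = numeric(), n_labels = integer(),
                  labels = list(), channel = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- tibble(map_id = map_chr(f, 1), len = as.numeric(map_chr(f, 2)),
               channel = as.integer(map_chr(f, 5)),
               pos = as.numeric(map_chr(f, 6)))
  out <- df %>%
    group_by(.data$map_id) %>%
    summarise(length = first(.data$len),
              labels = list(sort(.data$pos[.data$channel != 0])),
              .groups = "drop") %>%
    mutate(n_labels = lengths(.data$labels), channel = 1L)
  out$id <- if (!is.null(ids)) ids else paste0("map", out$map_id)
  select(out, "id", "length", "n_labels", "labels", "channel")
}

#' Write / read optical molecules as TSV
#'
#' Plain-text molecule exchange format: `molecule_id`, `length`,
#' `intensity`, and comma-separated label positions.
#'
#' @param mols molecule tibble.
#' @param path file path.
#' @return `path` / molecule tibble.
#' @export
write_molecules_tsv <- function(mols, path) {
  out <- tibble(molecule_id = mols$molecule_id, length = mols$length,
                intensity = mols$intensity,
                labels = map_chr(mols$labels, ~ paste(.x, collapse = ",")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_molecules_tsv
#' @export
read_molecules_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    molecule_id = readr::col_character(), length = readr::col_double(),
    intensity = readr::col_double(), labels = readr::col_character()))
  mutate(df,
         labels = map(.data$labels, ~ if (is.na(.x) || .x == "") numeric(0)
                      else as.numeric(strsplit(.x, ",", fixed = TRUE)[[1]])),
         n_labels = lengths(.data$labels))
}
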