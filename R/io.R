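# cli_io module: validated TSV readers/writers for the tables the
# pipeline exchanges, plus Newick/FASTA pass-throughs via ape/Biostrings.

#' Read a pipeline table from TSV
#'
#' All pipeline tables are tab-separated with a header row and the
#' site/taxon/species identifier in the first column.  `NA` marks
#' missing cells.  Duplicate identifiers and non-numeric data cells are
#' errors, named in the message.
#'
#' @param path file path.
#' @param kind one of `"environment"`, `"abundance"`, `"optima"`,
#'   `"traits"` -- controls only the error messages; the format is the
#'   same.
#' @return tibble with the identifier in column 1 and numeric columns.
#' @export
read_niche_table <- function(path,
                             kind = c("environment", "abundance",
                                      "optima", "traits")) {
  kind <- match.arg(kind)
  out <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), na = "NA", progress = FALSE)
  ids <- out[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate id in %s table: %s", kind,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (v in names(out)[-1]) {
    num <- suppressWarnings(as.numeric(out[[v]]))
    bad <- !is.na(out[[v]]) & is.na(num)
    if (any(bad)) {
      abort(sprintf("non-numeric cell(s) in %s table, column %s: %s",
                    kind, v, paste(head(out[[v]][bad], 3), collapse = ", ")))
    }
    out[[v]] <- num
  }
  out
}

#' Write a pipeline table to TSV
#'
#' @param data tibble (identifier first).
#' @param path output path.
#' @return `data`, invisibly.
#' @export
write_niche_table <- function(data, path) {
  readr::write_tsv(data, path, na = "NA", progress = FALSE)
  invisible(data)
}

#' Read reference or read sequences from FASTA
#'
#' @param path FASTA file.
#' @param id_name name for the identifier column.
#' @return tibble with the identifier and `sequence`.
#' @export
read_fasta_table <- function(path, id_name = "otu") {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- tibble(id = names(seqs), sequence = unname(as.character(seqs)))
  names(out)[1] <- id_name
  out
}
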