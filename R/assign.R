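# read-assignment module: amplicon reads -> reference taxa at a 99%
# identity cutoff, with fractionated counting of multi-matching reads.

#' Match amplicon reads against reference sequences
#'
#' Each read is aligned against every reference with a global-local
#' pairwise alignment (the full read against the best-matching region of
#' the reference; match +1, mismatch -1, linear gap -2) and the identity
#' is the fraction of matching positions over all aligned columns,
#' including gap columns.  References reaching `cutoff` (inclusive) are
#' reported.
#'
#' @param reads data frame with columns `read_id` and `sequence` (plus
#'   any others, e.g. `site`, carried along by [assign_reads()]).
#' @param refs data frame with columns `otu` and `sequence` holding the
#'   reference representatives.
#' @param cutoff identity threshold in `[0, 1]`; the default 0.99 is the
#'   maximum error rate of the short-read platform.
#' @param min_length reads shorter than this are rejected.
#' @return tibble with one row per (read, matching reference):
#'   `read_id`, `otu`, `identity`.  Reads matching nothing are absent.
#' @export
match_reads <- function(reads, refs, cutoff = 0.99, min_length = 50) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)),
            all(c("otu", "sequence") %in% names(refs)))
  if (nrow(refs) == 0) abort("empty reference set")
  if (anyDuplicated(refs$otu)) abort("duplicate reference ids")
  if (any(nchar(reads$sequence) < min_length)) {
    abort(sprintf("reads shorter than %d bases", min_length))
  }
  pat <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  hits <- purrr::map_dfr(seq_len(nrow(refs)), function(j) {
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::DNAString(refs$sequence[[j]]),
      type = "global-local", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 2)
    # identity over aligned columns including gaps
    idn <- Biostrings::pid(aln, type = "PID1") / 100
    keep <- idn >= cutoff
    tibble(read_id = reads$read_id[keep], otu = refs$otu[[j]],
           identity = idn[keep])
  })
  hits
}

#' Fractionated counting of matched reads
#'
#' A read matching `k` references contributes `1/k` of a read to each of
#' them (a read matching 4 taxa contributes 0.25 to each); unmatched
#' reads contribute nothing.  Counts are accumulated per site.
#'
#' @param matches match table from [match_reads()] (`read_id`, `otu`).
#' @param reads data frame with `read_id` and `site` for every read.
#' @param otus optional vector of taxon ids fixing the row set (taxa
#'   without any match get zero rows).
#' @return wide abundance tibble: first column `otu`, one column of
#'   fractional counts per site present in `reads`.
#' @export
fractionate_counts <- function(matches, reads, otus = NULL) {
  stopifnot(all(c("read_id", "otu") %in% names(matches)),
            all(c("read_id", "site") %in% names(reads)))
  sites <- unique(as.character(reads$site))
  otus <- otus %||% sort(unique(matches$otu))
  m <- matrix(0, nrow = length(otus), ncol = length(sites),
              dimnames = list(otus, sites))
  if (nrow(matches) > 0) {
    w <- dplyr::left_join(matches, reads[c("read_id", "site")], by = "read_id") |>
      dplyr::add_count(.data$read_id, name = "k") |>
      dplyr::mutate(weight = 1 / .data$k) |>
      dplyr::summarise(count = sum(.data$weight),
                       .by = c("otu", "site"))
    m[cbind(match(w$otu, otus), match(as.character(w$site), sites))] <- w$count
  }
  matrix_to_table(m, "otu")
}

#' Assign reads to reference taxa and build the abundance table
#'
#' Convenience wrapper: [match_reads()] followed by
#' [fractionate_counts()], keeping all reference taxa as rows.
#'
#' @inheritParams match_reads
#' @param reads data frame with `read_id`, `site` and `sequence`.
#' @return wide abundance tibble of fractional counts.
#' @export
assign_reads <- function(reads, refs, cutoff = 0.99) {
  matches <- match_reads(reads, refs, cutoff)
  fractionate_counts(matches, reads, otus = refs$otu)
}

#' Filter taxa by site prevalence
#'
#' Retains taxa observed (fractional count > 0) in at least `min_sites`
#' sites.  Idempotent.
#'
#' @param abundance wide abundance tibble (first column the taxon id).
#' @param min_sites minimum number of occupied sites; must not exceed the
#'   number of site columns.
#' @return filtered abundance tibble.
#' @export
prevalence_filter <- function(abundance, min_sites = 25) {
  m <- table_to_matrix(abundance, "abundance table")
  if (min_sites > ncol(m)) {
    abort(sprintf("min_sites (%d) exceeds the number of sites (%d)",
                  min_sites, ncol(m)))
  }
  abundance[rowSums(m > 0) >= min_sites, , drop = FALSE]
}

#' Per-site relative abundances
#'
#' Divides each site column by its total fractional count; sites with no
#' matched reads become `NA`.
#'
#' @param abundance wide abundance tibble.
#' @return tibble of the same shape whose site columns sum to 1.
#' @export
relative_abundance <- function(abundance) {
  m <- table_to_matrix(abundance, "abundance table")
  tot <- colSums(m)
  tot[tot == 0] <- NA_real_
  matrix_to_table(sweep(m, 2, tot, "/"), names(abundance)[[1]])
}
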