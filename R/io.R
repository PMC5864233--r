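# FASTA via Biostrings; TSV via base R. Round trips preserve ids, sequences
# and the taxon tag carried in the description line.

#' Read protein records from FASTA
#'
#' The first whitespace-delimited token of each header is the record id; a
#' `taxon=...` tag in the remainder of the header, if present, is parsed
#' into the record's taxon field. Duplicate ids and non-amino-acid
#' characters are errors.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return named list of [protein_record()]s.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # read without alphabet filtering so invalid residues are reported with
  # their position instead of being silently dropped
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no sequences: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  taxa <- ifelse(grepl("taxon=", headers),
                 sub("^.*taxon=(\\S+).*$", "\\1", headers), NA_character_)
  recs <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]), taxon = taxa[i])
  })
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA
#'
#' @param records list of [protein_record()]s.
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.list(records))
  headers <- vapply(records, function(r) {
    if (!is.na(r$taxon)) paste0(r$id, " taxon=", r$taxon) else r$id
  }, character(1))
  seqs <- Biostrings::AAStringSet(
    vapply(records, `[[`, character(1), "aa_sequence"))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a TSV file with a header row
#'
#' Tolerates CRLF line endings; never converts strings to factors.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
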