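#' @noRd
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Run code with a local RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators never disturb the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Split a sequence string into a character vector of residues
#' @noRd
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' Validate an amino-acid sequence (20 standard residues plus X)
#' @noRd
check_aa <- function(seq, what = "sequence") {
  ch <- seq_chars(seq)
  bad <- which(!ch %in% c(AA_STANDARD, "X"))
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-amino-acid character '%s' at position %d",
                 what, ch[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(paste(ch, collapse = ""))
}

#' Construct a protein record
#'
#' The unit flowing through screening and annotation: an identifier, an
#' upper-case amino-acid sequence (standard 20 residues plus `X` for
#' assembly ambiguity), and optional nucleotide sequence and sample metadata.
#'
#' @param id record identifier.
#' @param aa_sequence amino-acid sequence (one string).
#' @param nt_sequence optional nucleotide sequence; must be 3x the amino-acid
#'   length or 3x(length + 1) when it retains the stop codon.
#' @param sample_id,depth_m,taxon optional sample metadata.
#' @return an object of class `protein_record`.
#' @examples
#' protein_record("g1", "MKLVIN")
#' @export
protein_record <- function(id, aa_sequence, nt_sequence = NULL,
                           sample_id = NA_character_, depth_m = NA_real_,
                           taxon = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(aa_sequence) || length(aa_sequence) != 1L ||
      !nzchar(aa_sequence)) {
    stop("`aa_sequence` must be a non-empty string", call. = FALSE)
  }
  aa <- check_aa(aa_sequence, sprintf("record '%s'", id))
  if (!is.null(nt_sequence)) {
    nl <- nchar(nt_sequence)
    al <- nchar(aa)
    if (nl != 3L * al && nl != 3L * (al + 1L)) {
      stop(sprintf(
        "record '%s': nt_sequence length %d is not 3x or 3x(+1) the aa length %d",
        id, nl, al), call. = FALSE)
    }
  }
  structure(
    list(id = id, aa_sequence = aa, nt_sequence = nt_sequence,
         sample_id = sample_id, depth_m = depth_m, taxon = taxon),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$aa_sequence)))
  if (!is.na(x$taxon)) cat("  taxon:", x$taxon, "\n")
  invisible(x)
}
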