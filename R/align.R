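# Global alignment, position transfer and pairwise identity.
#
# The aligner is a Gotoh three-state dynamic program (src/gotoh.cpp) with
# affine gaps: a gap of length k costs gap_open + k * gap_extend. Identity is
# defined as the maximum number of identical aligned columns achievable by any
# score-optimal alignment, divided by the length of the shorter sequence; the
# second DP makes this well defined when several alignments tie on score.

#' @noRd
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Nucleotide scoring matrix (match 5, mismatch -4, N neutral)
#' @noRd
nt_matrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-4, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 5
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' @noRd
encode_for_matrix <- function(seq, mat, what = "sequence") {
  ch <- seq_chars(seq)
  idx <- match(ch, rownames(mat))
  if (anyNA(idx)) {
    bad <- ch[which(is.na(idx))[1L]]
    stop(sprintf("%s contains residue '%s' absent from the scoring matrix",
                 what, bad), call. = FALSE)
  }
  idx - 1L
}

#' Global alignment of a query against a reference frame
#'
#' Optimal global (Needleman-Wunsch) alignment under BLOSUM62 with affine gap
#' penalties, with a fixed traceback tie-break (diagonal, then gap in the
#' reference, then gap in the query) so results are byte-stable.
#'
#' @param query amino-acid sequence (string).
#' @param reference a [pr_reference()] frame, or a plain sequence string.
#' @param matrix substitution matrix (residue-named square matrix); default
#'   BLOSUM62 from Biostrings.
#' @param gap_open,gap_extend affine gap penalties (positive numbers); a gap
#'   of length k costs `gap_open + k * gap_extend`.
#' @param query_id identifier stored in the result.
#' @return an object of class `alignment_map`: list with `query_id`,
#'   `ref_name`, `pairs` (two-column matrix of 1-based aligned positions,
#'   query then reference, strictly increasing in both), `score`, `identity`
#'   (max identical columns among score-optimal alignments / shorter length).
#' @examples
#' ref <- pr_reference()
#' aln <- global_align(ref$aa_sequence, ref)
#' aln$identity  # 1
#' @export
global_align <- function(query, reference, matrix = NULL,
                         gap_open = 11, gap_extend = 1,
                         query_id = NA_character_) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop("`query` must be a non-empty string", call. = FALSE)
  }
  ref_seq <- if (inherits(reference, "reference_frame")) {
    reference$aa_sequence
  } else reference
  ref_name <- if (inherits(reference, "reference_frame")) {
    reference$name
  } else NA_character_
  if (is.null(matrix)) matrix <- blosum62()

  a <- encode_for_matrix(query, matrix, "query")
  b <- encode_for_matrix(ref_seq, matrix, "reference")
  res <- gotoh_core(a, b, matrix, gap_open, gap_extend)
  pairs <- res$pairs
  colnames(pairs) <- c("query", "ref")
  structure(
    list(query_id = query_id, ref_name = ref_name, pairs = pairs,
         score = res$score,
         identity = res$max_matches / min(nchar(query), nchar(ref_seq)),
         n_match = res$max_matches),
    class = "alignment_map"
  )
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf(
    "<alignment_map> %s vs %s: score %.1f, identity %.3f, %d aligned columns\n",
    x$query_id, x$ref_name, x$score, x$identity, nrow(x$pairs)))
  invisible(x)
}

#' Map a reference position onto the query
#'
#' @param alignmap an [global_align()] result.
#' @param ref_pos_1based 1-based reference position.
#' @param ref_length reference length used for range checking (optional; taken
#'   from the alignment when omitted).
#' @return 1-based query position, or `NA_integer_` when that reference
#'   column is gapped in the query.
#' @export
map_position <- function(alignmap, ref_pos_1based, ref_length = NULL) {
  stopifnot(inherits(alignmap, "alignment_map"))
  ref_pos_1based <- as.integer(ref_pos_1based)
  if (is.null(ref_length)) ref_length <- max(alignmap$pairs[, "ref"], 0L)
  if (any(ref_pos_1based < 1L | ref_pos_1based > ref_length)) {
    stop(sprintf("reference position out of range [1, %d]", ref_length),
         call. = FALSE)
  }
  idx <- match(ref_pos_1based, alignmap$pairs[, "ref"])
  out <- alignmap$pairs[idx, "query"]
  out[is.na(idx)] <- NA_integer_
  as.integer(out)
}

#' Pairwise sequence identity
#'
#' Identity of the optimal global alignment of two sequences: identical
#' aligned columns (maximized over score-optimal alignments) divided by the
#' length of the shorter sequence (default), or by the number of alignment
#' columns. The shorter-sequence denominator is the usual dereplication
#' convention: a fragment identical to part of a full-length gene scores 1.
#'
#' @param a,b sequences (strings) at the same level.
#' @param level `"amino_acid"` (BLOSUM62, gaps 11/1) or `"nucleotide"`
#'   (match 5 / mismatch -4 / N neutral, gaps 10/1).
#' @param denominator `"shorter"` or `"alignment"`.
#' @return identity fraction in `[0, 1]`; symmetric in `a`, `b`.
#' @examples
#' pairwise_identity("ACDE", "ACDF")  # 0.75
#' @export
pairwise_identity <- function(a, b, level = c("amino_acid", "nucleotide"),
                              denominator = c("shorter", "alignment")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (level == "amino_acid") {
    mat <- blosum62()
    go <- 11; ge <- 1
  } else {
    mat <- nt_matrix()
    go <- 10; ge <- 1
  }
  ai <- encode_for_matrix(a, mat, "sequence `a`")
  bi <- encode_for_matrix(b, mat, "sequence `b`")
  res <- gotoh_core(ai, bi, mat, go, ge)
  denom <- if (denominator == "shorter") {
    min(nchar(a), nchar(b))
  } else {
    # alignment columns: aligned pairs plus residues left unpaired in either
    nrow(res$pairs) + (nchar(a) - nrow(res$pairs)) + (nchar(b) - nrow(res$pairs))
  }
  res$max_matches / denom
}
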