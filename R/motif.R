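# Ion-pumping and spectral-tuning classification of rhodopsin motifs.
#
# The pump motif is the concatenation of residues 97/101/108; the tuning
# residue is 105. The combined label is "PUMP-TUNING", e.g. "DTE-Q" or
# "DTT-T". Rule tables are user-extensible; anything not in the table
# (including the deep-water DTT motif) classifies as "unknown".

#' Default ion-pump rule table
#'
#' Maps pump motifs (residues 97/101/108) to pump classes: DTE and DTD are
#' proton pumps, NDQ sodium, NTQ chloride. Extend by appending named entries,
#' e.g. `c(pump_rules(), DTT = "unknown_nonfunctional_in_assay")`.
#'
#' @return named character vector, motif -> class.
#' @export
pump_rules <- function() {
  c(DTE = "proton_pump", DTD = "proton_pump",
    NDQ = "sodium_pump", NTQ = "chloride_pump")
}

#' Default spectral-tuning rule table
#'
#' Maps the residue at position 105 to an absorption class: Q is blue-shifted,
#' L/M/I green-shifted. T, common in deep-water sequences, has no established
#' absorption and stays "unknown", as does everything else.
#'
#' @return named character vector, residue -> class.
#' @export
tuning_rules <- function() {
  c(Q = "blue", L = "green", M = "green", I = "green")
}

#' Classify the ion-pumping motif
#'
#' @param r97,r101,r108 single residue letters (case-insensitive) or `NA`.
#' @param rules rule table as from [pump_rules()].
#' @return pump class: `"proton_pump"`, `"sodium_pump"`, `"chloride_pump"`,
#'   or `"unknown"` (including any `NA` residue). Vectorized; total.
#' @examples
#' classify_pump("D", "T", "E")  # proton_pump
#' classify_pump("D", "T", "T")  # unknown
#' @export
classify_pump <- function(r97, r101, r108, rules = pump_rules()) {
  motif <- paste0(toupper(r97), toupper(r101), toupper(r108))
  out <- unname(rules[motif])
  out[is.na(out) | is.na(r97) | is.na(r101) | is.na(r108)] <- "unknown"
  out
}

#' Classify the spectral-tuning residue
#'
#' @param r105 single residue letter (case-insensitive) or `NA`.
#' @param rules rule table as from [tuning_rules()].
#' @return `"blue"`, `"green"` or `"unknown"`. Vectorized; total.
#' @examples
#' classify_tuning("Q")  # blue
#' classify_tuning("T")  # unknown
#' @export
classify_tuning <- function(r105, rules = tuning_rules()) {
  out <- unname(rules[toupper(r105)])
  out[is.na(out)] <- "unknown"
  out
}

#' Extract and classify the four functional residues of one record
#'
#' Aligns the query to the reference frame, transfers reference positions
#' 97/101/105/108 onto the query, reads the query residues there, and
#' classifies pump and tuning function. Reference positions gapped in the
#' query (e.g. truncated partial genes) yield `NA` residues and
#' `complete = FALSE`; such records are excluded from motif summaries.
#'
#' @param record a [protein_record()] (or plain sequence string).
#' @param reference a [pr_reference()] frame.
#' @param min_identity alignment-identity floor below which the position
#'   transfer is rejected as unalignable (guards against non-homologs).
#' @param gap_open,gap_extend alignment penalties, see [global_align()].
#' @return an object of class `motif_call`: list with `record_id`, the four
#'   residues, `pump_motif`, `combined_label`, `pump_class`, `tuning_class`,
#'   `complete`, `identity`.
#' @examples
#' ref <- pr_reference()
#' extract_motif(protein_record("ref", ref$aa_sequence), ref)
#' @export
extract_motif <- function(record, reference = pr_reference(),
                          min_identity = 0.25, gap_open = 11,
                          gap_extend = 1) {
  if (is.character(record)) record <- protein_record("query", record)
  stopifnot(inherits(record, "protein_record"),
            inherits(reference, "reference_frame"))
  aln <- global_align(record$aa_sequence, reference, gap_open = gap_open,
                      gap_extend = gap_extend, query_id = record$id)
  if (aln$identity < min_identity) {
    stop(sprintf(
      "record '%s' is unalignable to frame '%s' (identity %.3f < floor %.2f)",
      record$id, reference$name, aln$identity, min_identity),
      call. = FALSE)
  }
  qch <- seq_chars(record$aa_sequence)
  pos <- vapply(reference$motif_positions_pr, function(p) {
    q <- map_position(aln, p, ref_length = nchar(reference$aa_sequence))
    if (is.na(q)) NA_integer_ else q
  }, integer(1))
  res <- ifelse(is.na(pos), NA_character_, qch[pos])
  names(res) <- paste0("residue_", reference$motif_positions_pr)
  complete <- !anyNA(res)

  pump <- if (anyNA(res[c(1L, 2L, 4L)])) NA_character_ else {
    paste0(res[[1L]], res[[2L]], res[[4L]])
  }
  label <- if (!complete) NA_character_ else paste0(pump, "-", res[[3L]])
  structure(
    list(record_id = record$id,
         residue_97 = res[[1L]], residue_101 = res[[2L]],
         residue_105 = res[[3L]], residue_108 = res[[4L]],
         pump_motif = pump, combined_label = label,
         pump_class = classify_pump(res[[1L]], res[[2L]], res[[4L]]),
         tuning_class = classify_tuning(res[[3L]]),
         complete = complete, identity = aln$identity),
    class = "motif_call"
  )
}

#' @export
print.motif_call <- function(x, ...) {
  cat(sprintf("<motif_call> %s: %s (%s, %s)%s\n", x$record_id,
              if (is.na(x$combined_label)) "incomplete" else x$combined_label,
              x$pump_class, x$tuning_class,
              if (x$complete) "" else " [partial sequence]"))
  invisible(x)
}

#' Annotate motifs for a set of records
#'
#' Vectorized [extract_motif()]; unalignable records (identity below the
#' floor) are kept in the table with `NA` residues and reported in a warning
#' rather than aborting the batch.
#'
#' @param records list of [protein_record()]s.
#' @inheritParams extract_motif
#' @return data.frame with one row per record: residues, labels, classes,
#'   `complete` flag and alignment identity.
#' @export
annotate_motifs <- function(records, reference = pr_reference(),
                            min_identity = 0.25, gap_open = 11,
                            gap_extend = 1) {
  stopifnot(is.list(records), length(records) > 0L)
  rows <- lapply(records, function(rec) {
    mc <- tryCatch(
      extract_motif(rec, reference, min_identity, gap_open, gap_extend),
      error = function(e) NULL)
    if (is.null(mc)) {
      data.frame(record_id = rec$id, residue_97 = NA_character_,
                 residue_101 = NA_character_, residue_105 = NA_character_,
                 residue_108 = NA_character_, pump_motif = NA_character_,
                 combined_label = NA_character_, pump_class = "unknown",
                 tuning_class = "unknown", complete = FALSE,
                 identity = NA_real_, unalignable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(record_id = mc$record_id, residue_97 = mc$residue_97,
                 residue_101 = mc$residue_101, residue_105 = mc$residue_105,
                 residue_108 = mc$residue_108, pump_motif = mc$pump_motif,
                 combined_label = mc$combined_label,
                 pump_class = mc$pump_class, tuning_class = mc$tuning_class,
                 complete = mc$complete, identity = mc$identity,
                 unalignable = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_bad <- sum(out$unalignable)
  if (n_bad > 0) {
    warning(sprintf("%d record(s) were unalignable to the reference frame",
                    n_bad), call. = FALSE)
  }
  out
}

#' Build the four motif residues from a combined label
#'
#' Convenience inverse of the "PUMP-TUNING" notation: `"DTE-Q"` means
#' residues D/T/E at 97/101/108 and Q at 105.
#'
#' @param label combined label such as `"DTE-Q"` or `"DTT-T"`.
#' @return named character vector `c(r97, r101, r105, r108)`.
#' @examples
#' motif_from_label("DTQ-Q")
#' @export
motif_from_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  parts <- strsplit(toupper(label), "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || nchar(parts[1L]) != 3L || nchar(parts[2L]) != 1L) {
    stop("label must have the form 'XYZ-W', e.g. 'DTE-Q'", call. = FALSE)
  }
  pump <- seq_chars(parts[1L])
  c(r97 = pump[1L], r101 = pump[2L], r105 = parts[2L], r108 = pump[3L])
}
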