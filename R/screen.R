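# Opsin-architecture screening: seven transmembrane segments from hydropathy
# plus the retinal-binding lysine, located by alignment to the reference
# frame, inside the seventh segment.

#' Default screening parameters
#'
#' Kyte-Doolittle sliding-window transmembrane calling: window 19, threshold
#' 1.6, minimum segment length 15, merge gap 5; lysine membership in TM7 is
#' tested with a +/-2 residue tolerance because window smoothing blurs
#' segment edges; records with more than 20% `X` fail as ambiguous.
#'
#' @param ... overrides for individual parameters.
#' @return named list of screening parameters.
#' @export
screen_params <- function(...) {
  p <- list(window = 19L, threshold = 1.6, min_tm_length = 15L,
            merge_gap = 5L, tm7_tolerance = 2L, max_x_fraction = 0.2,
            min_identity = 0.25, gap_open = 11, gap_extend = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown) > 0) {
    stop("unknown screening parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modifyList(p, ov)
}

#' Screen one protein for opsin architecture
#'
#' A record passes when (i) exactly seven transmembrane segments are called
#' from its hydropathy profile, (ii) the query position aligned to the
#' reference retinal lysine exists and is a lysine, and (iii) that position
#' lies within the seventh called segment extended by `tm7_tolerance`
#' residues. All failures are enumerated, not short-circuited. Sequences
#' shorter than one window, or with more than `max_x_fraction` ambiguous
#' residues, fail as `ambiguous_sequence`.
#'
#' @param record a [protein_record()] (or plain sequence string).
#' @param reference a [pr_reference()] frame.
#' @param params screening parameters from [screen_params()].
#' @return an object of class `screen_result`: list with `record_id`,
#'   `passed`, `tm_count`, `retinal_lysine_position` (1-based query position
#'   or `NA`), `fail_reasons` (character vector, empty iff passed), and the
#'   called `topology`.
#' @examples
#' ref <- pr_reference()
#' screen_opsin(protein_record("ref", ref$aa_sequence), ref)$passed
#' @export
screen_opsin <- function(record, reference = pr_reference(),
                         params = screen_params()) {
  if (is.character(record)) record <- protein_record("query", record)
  stopifnot(inherits(record, "protein_record"),
            inherits(reference, "reference_frame"))
  seq <- record$aa_sequence
  n <- nchar(seq)
  reasons <- character(0)
  tm_count <- NA_integer_
  lys_pos <- NA_integer_
  topo <- NULL

  x_frac <- mean(seq_chars(seq) == "X")
  if (n < params$window || x_frac > params$max_x_fraction) {
    reasons <- c(reasons, "ambiguous_sequence")
  } else {
    prof <- hydropathy_profile(seq, params$window)
    topo <- call_tm_segments(prof, params$threshold, params$min_tm_length,
                             params$merge_gap, window = params$window)
    tm_count <- nrow(topo$segments)
    if (tm_count != 7L) reasons <- c(reasons, "tm_count_not_7")

    aln <- global_align(seq, reference, gap_open = params$gap_open,
                        gap_extend = params$gap_extend,
                        query_id = record$id)
    qpos <- map_position(aln, reference$retinal_lysine_pr,
                         ref_length = nchar(reference$aa_sequence))
    if (is.na(qpos) || substr(seq, qpos, qpos) != "K") {
      reasons <- c(reasons, "no_retinal_lysine")
    } else {
      lys_pos <- qpos
      if (tm_count >= 7L) {
        s7 <- topo$segments[7L, ]
        in_tm7 <- qpos >= s7[["start"]] - params$tm7_tolerance &&
          qpos <= s7[["end"]] + params$tm7_tolerance
        if (!in_tm7) reasons <- c(reasons, "lysine_outside_tm7")
      } else {
        # no seventh segment exists, so the lysine cannot sit in it
        reasons <- c(reasons, "lysine_outside_tm7")
      }
    }
  }

  structure(
    list(record_id = record$id, passed = length(reasons) == 0L,
         tm_count = tm_count, retinal_lysine_position = lys_pos,
         fail_reasons = reasons, topology = topo),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: %s (%s TM segments)%s\n", x$record_id,
              if (x$passed) "PASS" else "FAIL",
              ifelse(is.na(x$tm_count), "?", x$tm_count),
              if (length(x$fail_reasons)) {
                paste0(" [", paste(x$fail_reasons, collapse = ", "), "]")
              } else ""))
  invisible(x)
}

#' Screen a set of records
#'
#' @param records list of [protein_record()]s.
#' @inheritParams screen_opsin
#' @return data.frame with one row per record: `record_id`, `passed`,
#'   `tm_count`, `retinal_lysine_position`, `fail_reasons` (comma-joined).
#' @export
screen_opsins <- function(records, reference = pr_reference(),
                          params = screen_params()) {
  stopifnot(is.list(records), length(records) > 0L)
  rows <- lapply(records, function(rec) {
    sr <- screen_opsin(rec, reference, params)
    data.frame(record_id = sr$record_id, passed = sr$passed,
               tm_count = sr$tm_count,
               retinal_lysine_position = sr$retinal_lysine_position,
               fail_reasons = paste(sr$fail_reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read candidate identifiers from a HMMER3 tabular hits file
#'
#' Parses `--tblout` (18 fixed fields) or `--domtblout` (22 fixed fields)
#' output and returns the target identifiers whose full-sequence E-value is
#' at or below the cutoff. Comment lines (`#`) are ignored.
#'
#' @param path file path.
#' @param evalue_cutoff keep hits with E-value `<=` this value.
#' @param dialect `"auto"` (by field count), `"tblout"` or `"domtblout"`.
#' @return character vector of unique target ids (may be empty).
#' @export
read_hmm_hits <- function(path, evalue_cutoff = 1e-5,
                          dialect = c("auto", "tblout", "domtblout")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  ids <- character(0)
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    dia <- dialect
    if (dia == "auto") {
      dia <- if (length(fields) >= 22L) "domtblout" else "tblout"
    }
    min_fields <- if (dia == "domtblout") 22L else 18L
    ecol <- if (dia == "domtblout") 7L else 5L
    if (length(fields) < min_fields) {
      stop(sprintf("malformed HMMER %s line %d: %d field(s), expected >= %d",
                   dia, i, length(fields), min_fields), call. = FALSE)
    }
    ev <- suppressWarnings(as.numeric(fields[ecol]))
    if (is.na(ev)) {
      stop(sprintf("malformed HMMER %s line %d: E-value '%s' is not numeric",
                   dia, i, fields[ecol]), call. = FALSE)
    }
    if (ev <= evalue_cutoff) ids <- c(ids, fields[1L])
  }
  unique(ids)
}
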