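#' Proteorhodopsin reference frame
#'
#' Loads a reference frame: the sequence whose residue numbering defines the
#' canonical proteorhodopsin positions 97/101/105/108 (ion pumping and
#' spectral tuning) and the retinal-binding lysine, together with its
#' transmembrane-segment layout.
#'
#' The bundled default is a *synthetic* scaffold with proteorhodopsin
#' architecture: seven strongly hydrophobic transmembrane helices separated by
#' hydrophilic loops, the green-absorbing DTE-L motif at 97/101/105/108 in
#' helix 3, and the retinal lysine centred in helix 7 (position 298). It is a
#' designed stand-in, not a database record; it exists so that hydropathy
#' screening and position transfer are exactly reproducible offline.
#'
#' @param fasta,json paths to the frame FASTA and JSON annotation; defaults to
#'   the bundled synthetic scaffold.
#' @return an object of class `reference_frame`: list with `name`,
#'   `aa_sequence`, `motif_positions_pr`, `motif_positions_br`,
#'   `retinal_lysine_pr`, `tm_segments` (two-column matrix, 1-based
#'   inclusive), and `synthetic` flag.
#' @examples
#' ref <- pr_reference()
#' substr(ref$aa_sequence, 97, 108)
#' @export
pr_reference <- function(fasta = NULL, json = NULL) {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "pr_scaffold_synthetic.fasta",
                         package = "opsinscan", mustWork = TRUE)
  }
  if (is.null(json)) {
    json <- system.file("extdata", "pr_scaffold_synthetic.json",
                        package = "opsinscan", mustWork = TRUE)
  }
  seqs <- read_fasta(fasta)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  }
  ann <- jsonlite::read_json(json, simplifyVector = TRUE)
  seq <- seqs[[1L]]$aa_sequence

  frame <- structure(
    list(
      name = ann$name,
      aa_sequence = seq,
      motif_positions_pr = as.integer(ann$motif_positions_pr),
      motif_positions_br = as.integer(ann$motif_positions_br),
      retinal_lysine_pr = as.integer(ann$retinal_lysine_pr),
      tm_segments = matrix(as.integer(t(ann$tm_segments)), ncol = 2L,
                           byrow = TRUE,
                           dimnames = list(NULL, c("start", "end"))),
      synthetic = isTRUE(ann$synthetic)
    ),
    class = "reference_frame"
  )
  validate_reference_frame(frame)
}

#' @noRd
validate_reference_frame <- function(frame) {
  if (substr(frame$aa_sequence, frame$retinal_lysine_pr,
             frame$retinal_lysine_pr) != "K") {
    stop("reference frame residue at retinal_lysine_pr is not K",
         call. = FALSE)
  }
  offs <- frame$motif_positions_pr - frame$motif_positions_br
  if (length(unique(offs)) != 1L) {
    stop("PR/BR numbering offset is not constant across the motif sites",
         call. = FALSE)
  }
  if (nrow(frame$tm_segments) != 7L) {
    stop("reference frame must declare 7 transmembrane segments",
         call. = FALSE)
  }
  frame
}

#' @export
print.reference_frame <- function(x, ...) {
  cat(sprintf("<reference_frame> %s (%d aa%s)\n", x$name,
              nchar(x$aa_sequence), if (x$synthetic) ", synthetic" else ""))
  pos <- x$motif_positions_pr
  res <- vapply(pos, function(p) substr(x$aa_sequence, p, p), character(1))
  cat(sprintf("  motif %s at %s (BR %s); retinal K at %d\n",
              paste(res, collapse = ""), paste(pos, collapse = "/"),
              paste(x$motif_positions_br, collapse = "/"),
              x$retinal_lysine_pr))
  invisible(x)
}

#' Convert a proteorhodopsin position to bacteriorhodopsin numbering
#'
#' The four functional sites map with a constant offset of -12:
#' 97/101/105/108 in proteorhodopsin numbering are 85/89/93/96 in
#' bacteriorhodopsin numbering.
#'
#' @param pr_pos 1-based proteorhodopsin position(s). Positions other than
#'   97, 101, 105, 108 are converted too, with a warning: the constant offset
#'   is established only at the four motif sites.
#' @return integer bacteriorhodopsin position(s).
#' @examples
#' br_numbering(c(97, 101, 105, 108))  # 85 89 93 96
#' @export
br_numbering <- function(pr_pos) {
  pr_pos <- as.integer(pr_pos)
  outside <- setdiff(pr_pos, c(97L, 101L, 105L, 108L))
  if (length(outside) > 0) {
    warning("PR->BR offset is calibrated at positions 97/101/105/108; ",
            "conversion of other positions is an extrapolation",
            call. = FALSE)
  }
  pr_pos - 12L
}
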