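# Greedy dereplication at an identity threshold (CD-HIT style):
# longest-first, first-fit against existing representatives.

#' Greedy identity clustering of sequence records
#'
#' Records are sorted by decreasing sequence length (ties broken by
#' lexicographic id, so the ordering - and hence the clustering - is
#' deterministic). Each record joins the first existing cluster whose
#' representative it matches at `>= threshold` identity
#' ([pairwise_identity()], shorter-sequence denominator), otherwise it founds
#' a new cluster. Every representative therefore has identity `< threshold`
#' to all earlier representatives, and the result is a partition of the
#' input.
#'
#' @param records list of [protein_record()]s.
#' @param threshold identity threshold in `(0, 1]`; the catalog convention
#'   is 0.95.
#' @param level `"amino_acid"` or `"nucleotide"` (uses `nt_sequence`, which
#'   must then be present on every record).
#' @return an object of class `opsin_clusters`: list of clusters, each with
#'   `representative_id`, `member_ids`, `identities` (to the representative),
#'   plus `threshold` and `level` attributes. Use [as.data.frame()] for a
#'   tidy member table.
#' @examples
#' recs <- list(protein_record("a", "MKVLIVLLF"),
#'              protein_record("b", "MKVLIVLLF"),
#'              protein_record("c", "DEQNRKEDE"))
#' length(greedy_cluster(recs, 0.95))  # 2
#' @export
greedy_cluster <- function(records, threshold = 0.95,
                           level = c("amino_acid", "nucleotide")) {
  level <- match.arg(level)
  stopifnot(is.list(records), length(records) >= 1L)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  get_seq <- function(rec) {
    if (level == "amino_acid") rec$aa_sequence else {
      if (is.null(rec$nt_sequence)) {
        stop(sprintf("record '%s' has no nt_sequence", rec$id), call. = FALSE)
      }
      rec$nt_sequence
    }
  }
  ids <- unname(vapply(records, `[[`, character(1), "id"))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- unname(vapply(records, get_seq, character(1)))
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]
  seqs <- seqs[ord]

  clusters <- list()
  rep_seqs <- character(0)
  for (k in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      idy <- pairwise_identity(seqs[k], rep_seqs[ci], level = level)
      if (idy >= threshold) {
        clusters[[ci]]$member_ids <- c(clusters[[ci]]$member_ids, ids[k])
        clusters[[ci]]$identities <- c(clusters[[ci]]$identities, idy)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        representative_id = ids[k], member_ids = ids[k], identities = 1.0)
      rep_seqs <- c(rep_seqs, seqs[k])
    }
  }
  structure(clusters, threshold = threshold, level = level,
            class = "opsin_clusters")
}

#' @export
print.opsin_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$member_ids), integer(1))
  cat(sprintf(
    "<opsin_clusters> %d cluster(s) from %d record(s) at %.0f%% %s identity\n",
    length(x), sum(sizes), 100 * attr(x, "threshold"),
    sub("_", " ", attr(x, "level"))))
  invisible(x)
}

#' @export
as.data.frame.opsin_clusters <- function(x, ...) {
  out <- do.call(rbind, lapply(x, function(cl) {
    data.frame(representative_id = cl$representative_id,
               member_id = cl$member_ids, identity = cl$identities,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
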