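#' Kyte-Doolittle hydropathy indices
#'
#' The classic per-residue hydropathy scale. `X` (ambiguous residue) scores 0.
#'
#' @return named numeric vector over the 20 standard residues plus `X`.
#' @references Kyte & Doolittle (1982) J Mol Biol 157:105-132.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
}

#' Sliding-window hydropathy profile
#'
#' Mean Kyte-Doolittle index over an odd window centred on each residue.
#' Positions closer than half a window to either end use the truncated
#' window mean, so the profile has the same length as the sequence.
#'
#' @param seq amino-acid sequence (one string; standard residues plus `X`).
#' @param window odd window size, between 1 and the sequence length.
#' @return numeric vector of per-residue scores, `length(score) == nchar(seq)`.
#' @examples
#' hydropathy_profile("IIIIIIIII", window = 5)  # all 4.5
#' @export
hydropathy_profile <- function(seq, window = 19L) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a non-empty string", call. = FALSE)
  }
  ch <- seq_chars(check_aa(seq))
  n <- length(ch)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window < 1L || window > n) {
    stop("`window` must be between 1 and the sequence length", call. = FALSE)
  }
  sc <- unname(kyte_doolittle()[ch])
  h <- window %/% 2L
  # truncated-window means via cumulative sums
  cs <- c(0, cumsum(sc))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Maximal runs of scores at or above `threshold`; runs separated by fewer
#' than `merge_gap` sub-threshold positions are merged (in left-to-right
#' order), and merged runs shorter than `min_tm_length` are then discarded.
#'
#' @param scores per-residue hydropathy scores.
#' @param threshold segment-calling threshold on the windowed score.
#' @param min_tm_length minimum segment length kept.
#' @param merge_gap runs closer than this many positions are fused.
#' @param window window size recorded in the result (bookkeeping only).
#' @return an object of class `tm_topology`: list with `segments` (two-column
#'   matrix of 1-based inclusive start/end), `scores`, `threshold`, `window`.
#' @examples
#' prof <- hydropathy_profile(strrep("I", 40))
#' call_tm_segments(prof)
#' @export
call_tm_segments <- function(scores, threshold = 1.6, min_tm_length = 15L,
                             merge_gap = 5L, window = NA_integer_) {
  stopifnot(is.numeric(scores))
  min_tm_length <- as.integer(min_tm_length)
  merge_gap <- as.integer(merge_gap)
  if (min_tm_length < 1L) stop("`min_tm_length` must be >= 1", call. = FALSE)
  if (merge_gap < 0L) stop("`merge_gap` must be >= 0", call. = FALSE)

  above <- scores >= threshold
  segs <- matrix(integer(0), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts, ends)[r$values, , drop = FALSE]
    if (nrow(runs) > 1L) {
      merged <- runs[1L, , drop = FALSE]
      for (k in 2L:nrow(runs)) {
        gap <- runs[k, 1L] - merged[nrow(merged), 2L] - 1L
        if (gap < merge_gap) {
          merged[nrow(merged), 2L] <- runs[k, 2L]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
      runs <- merged
    }
    keep <- (runs[, 2L] - runs[, 1L] + 1L) >= min_tm_length
    segs <- runs[keep, , drop = FALSE]
    dimnames(segs) <- list(NULL, c("start", "end"))
  }
  structure(
    list(segments = segs, scores = scores, threshold = threshold,
         min_tm_length = min_tm_length, merge_gap = merge_gap,
         window = window),
    class = "tm_topology"
  )
}

#' @export
print.tm_topology <- function(x, ...) {
  cat(sprintf("<tm_topology> %d segment(s), threshold %.2f\n",
              nrow(x$segments), x$threshold))
  if (nrow(x$segments) > 0) {
    cat(paste(sprintf("  TM%d: %d-%d", seq_len(nrow(x$segments)),
                      x$segments[, 1], x$segments[, 2]), collapse = "\n"),
        "\n")
  }
  invisible(x)
}
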