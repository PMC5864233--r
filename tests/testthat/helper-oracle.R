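# Independent oracles used against the package implementation.

# Top-down memoized global aligner over explicit alignment columns. A column
# is a match/mismatch, a gap consuming a query residue, or a gap consuming a
# reference residue; opening a gap run costs `open` and every gapped column
# costs `ext`. Returns the optimal score and the maximum number of identical
# columns among score-optimal alignments. Deliberately structured as suffix
# recursion with a previous-column state, unlike the package's bottom-up
# matrix code.
oracle_align <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(c(score = 0, matches = 0))
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cand <- list()
    if (i <= n && j <= m) {
      sub <- rec(i + 1, j + 1, "M")
      cand[[length(cand) + 1]] <- c(sub[1] + mat[av[i], bv[j]],
                                    sub[2] + (av[i] == bv[j]))
    }
    if (i <= n) {
      sub <- rec(i + 1, j, "GA")
      cand[[length(cand) + 1]] <- c(sub[1] - ext - if (prev == "GA") 0 else open,
                                    sub[2])
    }
    if (j <= m) {
      sub <- rec(i, j + 1, "GB")
      cand[[length(cand) + 1]] <- c(sub[1] - ext - if (prev == "GB") 0 else open,
                                    sub[2])
    }
    scores <- vapply(cand, `[`, numeric(1), 1)
    best <- max(scores)
    matches <- max(vapply(cand[scores >= best - 1e-9], `[`, numeric(1), 2))
    out <- c(score = best, matches = matches)
    memo[[key]] <- out
    out
  }
  res <- rec(1, 1, "NONE")
  list(score = unname(res[1]), max_matches = unname(res[2]))
}

oracle_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# direct double-loop windowed mean, independent of the cumulative-sum code
oracle_hydropathy <- function(seq, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  h <- window %/% 2
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    mean(kd[ch[idx]])
  }, numeric(1))
}

random_aa <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                      "G", "H", "I", "L", "K", "M", "F",
                                      "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# planted well-separated clustering instance: `groups` random ancestors,
# `members` sequences each differing from the ancestor at <= 2 positions
# (within-group identity >= (len-4)/len, between-group far below threshold)
make_cluster_instance <- function(seed, groups = 4, members = 5, len = 150) {
  set.seed(seed)
  recs <- list()
  truth <- character(0)
  for (g in seq_len(groups)) {
    anc <- strsplit(random_aa(len), "")[[1]]
    for (k in seq_len(members)) {
      ch <- anc
      pos <- sample(len, 2)
      for (p in pos) ch[p] <- sample(setdiff(LETTERS[LETTERS %in% c(
        "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
        "F", "P", "S", "T", "W", "Y", "V")], ch[p]), 1)
      id <- sprintf("g%d_m%d", g, k)
      recs[[id]] <- protein_record(id, paste(ch, collapse = ""))
      truth[id] <- sprintf("g%d", g)
    }
  }
  list(records = recs, truth = truth)
}
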