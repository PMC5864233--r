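test_that("self-alignment is the identity map with the diagonal score", {
  ref <- pr_reference()
  aln <- global_align(ref$aa_sequence, ref)
  n <- nchar(ref$aa_sequence)
  expect_equal(aln$identity, 1.0)
  expect_equal(unname(aln$pairs[, 1]), seq_len(n))
  expect_equal(unname(aln$pairs[, 2]), seq_len(n))
  b62 <- oracle_blosum62()
  ch <- strsplit(ref$aa_sequence, "")[[1]]
  expect_equal(aln$score, sum(b62[cbind(ch, ch)]))

  small <- global_align("ACDE", "ACDE")
  expect_equal(nrow(small$pairs), 4L)
  expect_equal(small$identity, 1.0)
})

test_that("score and identity match the recursive oracle on random pairs", {
  b62 <- oracle_blosum62()
  alpha <- c("A", "C", "D", "E", "G", "K")
  set.seed(31)
  for (i in 1:60) {
    a <- random_aa(sample(2:12, 1), alpha)
    b <- random_aa(sample(2:12, 1), alpha)
    want <- oracle_align(a, b, b62)
    got <- global_align(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$n_match, want$max_matches)
    expect_equal(pairwise_identity(a, b),
                 want$max_matches / min(nchar(a), nchar(b)))
  }
})

test_that("scores agree with an independent aligner implementation", {
  b62 <- oracle_blosum62()
  set.seed(32)
  for (i in 1:25) {
    a <- random_aa(sample(10:60, 1))
    b <- random_aa(sample(10:60, 1))
    got <- global_align(a, b)$score
    want <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = b62, gapOpening = 11, gapExtension = 1))
    expect_equal(got, want)
  }
})

test_that("position mapping handles identity, gaps and range errors", {
  ref <- pr_reference()
  n <- nchar(ref$aa_sequence)
  self <- global_align(ref$aa_sequence, ref)
  expect_equal(map_position(self, 105, n), 105L)
  expect_equal(map_position(self, 1, n), 1L)

  # query missing the first 110 residues: the motif columns are gapped
  trunc <- global_align(substr(ref$aa_sequence, 111, n), ref)
  expect_true(is.na(map_position(trunc, 105, n)))
  expect_error(map_position(self, 0, n), "out of range")
  expect_error(map_position(self, n + 1, n), "out of range")
})

test_that("position mapping is monotone along the reference", {
  ref <- pr_reference()
  for (seed in 1:10) {
    q <- make_opsin(0.7, seed = seed)$record$aa_sequence
    aln <- global_align(q, ref)
    pos <- vapply(seq(10, 310, by = 20), function(p) {
      out <- map_position(aln, p, nchar(ref$aa_sequence))
      if (is.na(out)) -1L else out
    }, integer(1))
    pos <- pos[pos > 0]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("identity is symmetric, fragment-tolerant and alphabet-checked", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  set.seed(33)
  for (i in 1:10) {
    a <- random_aa(sample(5:40, 1))
    b <- random_aa(sample(5:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  # a perfect fragment scores 1 under the shorter-sequence denominator
  ref <- pr_reference()$aa_sequence
  expect_equal(pairwise_identity(substr(ref, 50, 180), ref), 1.0)
  expect_lt(pairwise_identity(substr(ref, 50, 180), ref,
                              denominator = "alignment"), 1.0)
  # amino-acid letters are rejected by the nucleotide matrix
  expect_error(pairwise_identity("MKW", "MKW", level = "nucleotide"),
               "absent from the scoring matrix")
  expect_error(global_align("ACDE", "AC-E"),
               "absent from the scoring matrix")
})

test_that("bacteriorhodopsin numbering is a constant -12 offset", {
  expect_equal(br_numbering(97), 85L)
  expect_equal(br_numbering(101), 89L)
  expect_equal(br_numbering(105), 93L)
  expect_equal(br_numbering(108), 96L)
  expect_silent(br_numbering(c(97, 101, 105, 108)))
  expect_warning(br_numbering(216), "extrapolation")
})
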