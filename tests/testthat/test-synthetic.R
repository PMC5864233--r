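test_that("a full-identity request with the native motif returns the scaffold", {
  ref <- pr_reference()
  out <- make_opsin(1.0, c("D", "T", "L", "E"), seed = 3, scaffold = ref)
  expect_equal(out$record$aa_sequence, ref$aa_sequence)
  expect_equal(out$truth$realized_identity, 1.0)
})

test_that("generation is deterministic under a fixed seed", {
  a <- make_opsin(0.8, motif_from_label("DTQ-Q"), seed = 7)
  b <- make_opsin(0.8, motif_from_label("DTQ-Q"), seed = 7)
  expect_identical(a, b)
  c1 <- make_decoy("soluble", 5)
  c2 <- make_decoy("soluble", 5)
  expect_identical(c1, c2)
  cc1 <- make_community_coverage(3, c(25, 75, 125), list(g = 0.5), 100,
                                 "poisson", seed = 11)
  cc2 <- make_community_coverage(3, c(25, 75, 125), list(g = 0.5), 100,
                                 "poisson", seed = 11)
  expect_identical(cc1, cc2)
})

test_that("seeded generators leave the session RNG untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_opsin(0.8, seed = 42))
  invisible(make_decoy("soluble", 42))
  invisible(make_transcript_counts(0.02, 1e6, "binomial", seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("realized identity lands within 0.03 of the target", {
  ref <- pr_reference()
  for (ti in c(0.3, 0.45, 0.6, 0.75, 0.9, 0.97, 1.0)) {
    out <- make_opsin(ti, motif_from_label("DTE-Q"), seed = 31,
                      scaffold = ref)
    expect_lt(abs(out$truth$realized_identity - ti), 0.03)
    # realized identity is itself an honest count of mismatches
    a <- strsplit(out$record$aa_sequence, "")[[1]]
    b <- strsplit(ref$aa_sequence, "")[[1]]
    expect_equal(out$truth$realized_identity, mean(a == b))
  }
})

test_that("constrained positions and mutation alphabets are respected", {
  ref <- pr_reference()
  b <- strsplit(ref$aa_sequence, "")[[1]]
  tm_idx <- unlist(apply(ref$tm_segments, 1, function(s) s[1]:s[2],
                         simplify = FALSE))
  lys <- ref$retinal_lysine_pr
  hydro <- c("A", "I", "L", "M", "F", "V", "W")
  for (seed in 1:10) {
    out <- make_opsin(0.6, motif_from_label("NDQ-Q"), seed = seed,
                      scaffold = ref)
    a <- strsplit(out$record$aa_sequence, "")[[1]]
    expect_equal(a[c(97, 101, 105, 108)], c("N", "D", "Q", "Q"))
    expect_equal(a[(lys - 3):(lys + 3)], b[(lys - 3):(lys + 3)])
    changed <- setdiff(which(a != b), c(97, 101, 105, 108))
    expect_true(all(a[intersect(changed, tm_idx)] %in% hydro))
  }
  expect_error(make_opsin(0.2), "target_identity")
  expect_error(make_opsin(0.8, c("D", "T", "B", "E")), "standard")
})

test_that("each decoy class breaks exactly its intended property", {
  ref <- pr_reference()
  for (seed in 1:10) {
    d6 <- make_decoy("six_tm", seed, ref)
    prof <- hydropathy_profile(d6$record$aa_sequence, 19)
    expect_equal(nrow(call_tm_segments(prof)$segments), 6L)

    dn <- make_decoy("no_lysine", seed, ref)
    expect_equal(substr(dn$record$aa_sequence, ref$retinal_lysine_pr,
                        ref$retinal_lysine_pr), "A")

    ds <- make_decoy("soluble", seed, ref)
    expect_lt(max(hydropathy_profile(ds$record$aa_sequence, 19)), 1.6)
  }
  expect_error(make_decoy("weird", 1), "arg")
})

test_that("noise-free coverage tables invert the estimator exactly", {
  cc <- make_community_coverage(1, 25, list(g1 = 0.7), 100, "none", seed = 1)
  expect_equal(copies_per_genome(cc$coverage, "S01", "g1"), 0.7,
               tolerance = 1e-9)
  cc <- make_community_coverage(1, 25, list(g1 = 0), 100, "none", seed = 1)
  expect_equal(cc$coverage$coverage[cc$coverage$gene_id == "g1"], 0)
  # per-sample planted vectors are honoured
  cc <- make_community_coverage(3, c(25, 200, 1000),
                                list(g1 = c(0.9, 0.34, 0.15)), 50, "none",
                                seed = 2)
  got <- vapply(sprintf("S%02d", 1:3),
                function(s) copies_per_genome(cc$coverage, s, "g1"),
                numeric(1))
  expect_equal(unname(got), c(0.9, 0.34, 0.15), tolerance = 1e-9)
  expect_error(make_community_coverage(1, 25, list(), 100), "non-empty")
  expect_error(make_community_coverage(1, 25, list(g = 0.5), 0), "positive")
  expect_error(make_community_coverage(1, 25, list(g = -0.1), 10), ">= 0")
})

test_that("Poisson-noise coverage recovers the planted value on average", {
  cc <- make_community_coverage(50, 25, list(g1 = 0.5), 200, "poisson",
                                seed = 11)
  est <- vapply(sprintf("S%02d", 1:50),
                function(s) copies_per_genome(cc$coverage, s, "g1"),
                numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * se + 1e-12)
  # lognormal noise stays centred too (multiplier has mean one)
  cc <- make_community_coverage(50, 25, list(g1 = 0.5), 200, "lognormal",
                                seed = 12)
  est <- vapply(sprintf("S%02d", 1:50),
                function(s) copies_per_genome(cc$coverage, s, "g1"),
                numeric(1))
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(50) + 1e-12)
})

test_that("transcript counts honour the planted fraction", {
  tc <- make_transcript_counts(0.02, 1e6, "none", seed = 1)
  expect_equal(tc$counts$rhodopsin_reads, 200L)
  tc <- make_transcript_counts(0, 5e5, "binomial", seed = 1)
  expect_equal(tc$counts$rhodopsin_reads, 0L)
  # binomial draw lands inside the 99% interval around the planted fraction
  tc <- make_transcript_counts(0.004, 1e7, "binomial", seed = 3)
  est <- transcript_fraction(tc$counts$rhodopsin_reads,
                             tc$counts$total_nonrrna_reads)
  p <- 0.004 / 100
  half <- 2.576 * sqrt(p * (1 - p) / 1e7) * 100
  expect_lt(abs(est - 0.004), half)
  expect_error(make_transcript_counts(101, 100), "\\[0, 100\\]")
  expect_error(make_transcript_counts(1, 0), ">= 1")
})
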