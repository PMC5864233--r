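test_that("pump classification is total, table-driven and case-insensitive", {
  expect_equal(classify_pump("D", "T", "E"), "proton_pump")
  expect_equal(classify_pump("D", "T", "D"), "proton_pump")
  expect_equal(classify_pump("N", "D", "Q"), "sodium_pump")
  expect_equal(classify_pump("N", "T", "Q"), "chloride_pump")
  expect_equal(classify_pump("D", "T", "T"), "unknown")
  expect_equal(classify_pump("d", "t", "e"), "proton_pump")
  expect_equal(classify_pump(NA, "T", "E"), "unknown")
  expect_equal(classify_pump(c("D", "N"), c("T", "D"), c("E", "Q")),
               c("proton_pump", "sodium_pump"))
  # user-extensible table
  rules <- c(pump_rules(), DTT = "deep_water_unassigned")
  expect_equal(classify_pump("D", "T", "T", rules), "deep_water_unassigned")
})

test_that("tuning classification maps Q blue, L/M/I green, rest unknown", {
  expect_equal(classify_tuning("Q"), "blue")
  expect_equal(classify_tuning(c("L", "M", "I")), rep("green", 3))
  expect_equal(classify_tuning("T"), "unknown")
  expect_equal(classify_tuning("W"), "unknown")
  expect_equal(classify_tuning(NA), "unknown")
  expect_equal(classify_tuning("q"), "blue")
})

test_that("the reference record annotates as its own DTE-L motif", {
  ref <- pr_reference()
  # independent read of the planted residues straight off the sequence
  expect_equal(vapply(c(97, 101, 105, 108),
                      function(p) substr(ref$aa_sequence, p, p),
                      character(1)),
               c("D", "T", "L", "E"))
  mc <- extract_motif(protein_record("ref", ref$aa_sequence), ref)
  expect_equal(mc$pump_motif, "DTE")
  expect_equal(mc$combined_label, "DTE-L")
  expect_equal(mc$pump_class, "proton_pump")
  expect_equal(mc$tuning_class, "green")
  expect_true(mc$complete)
})

test_that("planted motifs are recovered across identities and labels", {
  ref <- pr_reference()
  labels <- c("DTE-Q", "DTE-L", "DTE-M", "DTT-T", "DTQ-Q", "NDQ-Q", "NTQ-Q")
  idents <- c(0.6, 0.75, 0.9)
  k <- 0
  for (lab in labels) {
    for (ti in idents) {
      k <- k + 1
      planted <- motif_from_label(lab)
      out <- make_opsin(ti, planted, seed = 1000 + k, scaffold = ref)
      mc <- extract_motif(out$record, ref)
      expect_equal(c(mc$residue_97, mc$residue_101, mc$residue_105,
                     mc$residue_108),
                   unname(planted[c("r97", "r101", "r105", "r108")]))
      expect_equal(mc$combined_label, lab)
    }
  }
  # the label grammar round-trips
  expect_equal(unname(motif_from_label("DTQ-Q")), c("D", "T", "Q", "Q"))
  expect_error(motif_from_label("DT-Q"), "form")
})

test_that("partial sequences yield incomplete calls, never classifications", {
  ref <- pr_reference()
  n <- nchar(ref$aa_sequence)
  # truncated before the motif block: all four sites unmapped
  tail_only <- protein_record("tail", substr(ref$aa_sequence, 111, n))
  mc <- extract_motif(tail_only, ref)
  expect_false(mc$complete)
  expect_true(is.na(mc$combined_label))
  expect_equal(mc$pump_class, "unknown")
  # truncated after 101: 105/108 missing, 97/101 still read
  head_only <- protein_record("head", substr(ref$aa_sequence, 1, 103))
  mc <- extract_motif(head_only, ref)
  expect_false(mc$complete)
  expect_equal(mc$residue_97, "D")
  expect_true(is.na(mc$residue_105))
})

test_that("non-homologs are rejected by the identity floor", {
  ref <- pr_reference()
  set.seed(77)
  junk <- protein_record("junk", random_aa(300))
  expect_error(extract_motif(junk, ref), "unalignable")
  recs <- list(protein_record("ok", ref$aa_sequence), junk)
  expect_warning(tab <- annotate_motifs(recs, ref), "unalignable")
  expect_equal(nrow(tab), 2L)
  expect_true(tab$complete[1])
  expect_true(tab$unalignable[2])
})
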