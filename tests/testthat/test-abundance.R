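mk_cov <- function(uscg = rep(100, 10), genes = c(pr1 = 70),
                   sample_id = "s1") {
  coverage_table(data.frame(
    sample_id = sample_id,
    gene_id = c(uscg_cogs(), names(genes)),
    coverage = c(uscg, unname(genes)),
    is_uscg = c(rep(TRUE, 10), rep(FALSE, length(genes))),
    stringsAsFactors = FALSE))
}

test_that("copies per genome is coverage over mean marker coverage", {
  expect_equal(copies_per_genome(mk_cov(genes = c(g = 100)), "s1", "g"), 1.0)
  expect_equal(copies_per_genome(mk_cov(genes = c(g = 0)), "s1", "g"), 0.0)
  # markers 2..20 have mean 11; 7.7 / 11 = 0.7
  tab <- mk_cov(uscg = seq(2, 20, by = 2), genes = c(g = 7.7))
  expect_equal(copies_per_genome(tab, "s1", "g"), 0.7)
  # genes absent from the table count as zero coverage
  expect_equal(copies_per_genome(tab, "s1", c("g", "ghost")), 0.7)
  # median option is robust to one inflated marker
  tab <- mk_cov(uscg = c(rep(100, 9), 1e5), genes = c(g = 70))
  expect_equal(copies_per_genome(tab, "s1", "g", uscg_stat = "median"), 0.7)
})

test_that("marker problems are reported with sample and marker names", {
  tab <- mk_cov()
  expect_error(copies_per_genome(tab, "nope", "pr1"), "nope")
  bad <- tab
  bad$coverage[bad$gene_id == "COG0016"] <- 0
  expect_error(copies_per_genome(bad, "s1", "pr1"), "COG0016")
  expect_error(coverage_table(data.frame(sample_id = 1, gene_id = 1,
                                         coverage = -1, is_uscg = FALSE)),
               ">= 0")
  expect_error(coverage_table(data.frame(a = 1)), "lacks column")
})

test_that("copies per genome is scale-invariant and additive", {
  set.seed(51)
  genes <- setNames(runif(6, 0, 50), paste0("g", 1:6))
  tab <- mk_cov(uscg = runif(10, 80, 120), genes = genes)
  v1 <- copies_per_genome(tab, "s1", names(genes))
  scaled <- tab
  scaled$coverage <- scaled$coverage * 7.3
  expect_equal(copies_per_genome(scaled, "s1", names(genes)), v1,
               tolerance = 1e-12)
  parts <- copies_per_genome(tab, "s1", paste0("g", 1:3)) +
    copies_per_genome(tab, "s1", paste0("g", 4:6))
  expect_equal(parts, v1, tolerance = 1e-12)
})

test_that("profiles aggregate genes into categories per sample", {
  cc <- make_community_coverage(3, c(25, 75, 125),
                                list(a1 = 0.3, a2 = 0.2, b1 = 0.1),
                                100, "none", seed = 5)
  prof <- copy_number_profile(cc$coverage,
                              categories = c(a1 = "A", a2 = "A", b1 = "B"))
  a <- prof$copies_per_genome[prof$category == "A"]
  expect_equal(a, rep(0.5, 3), tolerance = 1e-12)
  # unmapped genes fall into "unassigned"
  prof <- copy_number_profile(cc$coverage, categories = c(a1 = "A"))
  expect_setequal(unique(prof$category), c("A", "unassigned"))
})

test_that("depth summaries group by exact depth", {
  prof <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     category = "pr",
                     copies_per_genome = c(0.6, 0.7, 0.8, 0.34))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     depth_m = c(25, 25, 25, 200))
  dp <- depth_profile(prof, meta)
  row25 <- dp[dp$depth_m == 25, ]
  expect_equal(row25$n, 3L)
  expect_equal(row25$mean, 0.7)
  expect_equal(row25$median, 0.7)
  row200 <- dp[dp$depth_m == 200, ]
  expect_equal(row200$mean, 0.34)
  expect_equal(row200$q1, row200$q3)  # single observation
  expect_error(depth_profile(prof, meta[1:2, ]), "missing from the metadata")
})

test_that("relative abundance fractions sum to one and flag zero totals", {
  prof <- data.frame(sample_id = "s1", category = c("SAR11", "other"),
                     copies_per_genome = c(0.3, 0.1))
  ra <- relative_abundance(prof)
  expect_equal(ra$fraction, c(0.75, 0.25))
  # a SAR11-dominated community: 0.609 of the pool
  prof <- data.frame(sample_id = "s1",
                     category = c("SAR11", "rest"),
                     copies_per_genome = c(0.609, 0.391))
  expect_equal(relative_abundance(prof)$fraction[1], 0.609)
  prof <- data.frame(sample_id = c("s1", "s2"),
                     category = "x", copies_per_genome = c(1, 0))
  expect_warning(ra <- relative_abundance(prof), "zero total")
  expect_true(is.na(ra$fraction[2]))
})

test_that("gene-set profiles compose copy numbers with depth grouping", {
  shapes <- list(blh = c(0.5, 0.5, 0.02), crtI = rep(0.3, 3),
                 PR = c(0.7, 0.9, 0.15))
  cc <- make_community_coverage(3, c(25, 125, 1000), shapes, 200, "none",
                                seed = 9)
  dp <- gene_set_profile(cc$coverage,
                         sets = list(blh = "blh", crtI = "crtI", PR = "PR"),
                         metadata = cc$metadata)
  for (nm in names(shapes)) {
    got <- dp[dp$category == nm, ]
    got <- got[order(got$depth_m), ]
    want <- shapes[[nm]][order(c(25, 125, 1000))]
    expect_equal(got$mean, want, tolerance = 1e-12)
  }
  # singleton set equals the plain estimator; empty set is zero
  expect_equal(dp$mean[dp$category == "blh" & dp$depth_m == 25],
               copies_per_genome(cc$coverage, "S01", "blh"))
  expect_warning(
    dp2 <- gene_set_profile(cc$coverage, sets = list(ghost = "nope"),
                            metadata = cc$metadata),
    "skipped")
  expect_equal(dp2$mean, rep(0, 3))
  expect_error(gene_set_profile(cc$coverage,
                                sets = list(a = "blh", b = "blh"),
                                metadata = cc$metadata), "overlap")
})

test_that("transcript fractions are percentages with validated counts", {
  expect_equal(transcript_fraction(200, 1e6), 0.02)
  expect_equal(transcript_fraction(0, 123), 0)
  expect_equal(transcript_fraction(c(200, 40), c(1e6, 1e6)), c(0.02, 0.004))
  expect_error(transcript_fraction(5, 0), ">= 1")
  expect_error(transcript_fraction(-1, 10), ">= 0")
  expect_error(transcript_fraction(11, 10), "exceed")
})
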