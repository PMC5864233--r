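# One-call synthetic study bundle: a depth-stratified community whose
# composition echoes the North Pacific Subtropical Gyre survey design -
# SAR11-dominated proteorhodopsins (60.9% of copies), blue-absorbing DTE-Q
# near the surface giving way to DTT-T at depth, copy numbers per genome
# declining from ~0.7-0.9 above 125 m to 0.15 at 1000 m, transcript
# fractions from 0.02% (surface) to 0.001% (deep), and retinal-biosynthesis
# genes (blh/crtY shallow, crtB/crtI depth-flat, diox1 tracking the
# rhodopsins).

#' @noRd
bundle_taxon_table <- function() {
  data.frame(
    taxon = c("SAR11", "Bacteroidetes", "unassigned", "SAR324", "SUP05",
              "SAR116", "SAR86", "Actinobacteria", "Euryarchaeota",
              "Erythrobacter", "GiantVirus"),
    fraction = c(0.609, 0.07, 0.07, 0.05, 0.04, 0.04, 0.04, 0.03, 0.03,
                 0.008, 0.013),
    label = c("DTE-Q", "DTE-M", "DTT-Q", "DTE-L", "DTE-Q", "DTE-Q",
              "DTE-Q", "DTE-M", "DTE-Q", "NDQ-Q", "DTS-L"),
    stringsAsFactors = FALSE)
}

#' Depth design of the synthetic study
#'
#' Seven fixed depths with total proteorhodopsin copies per genome and
#' rhodopsin transcript fractions assigned per depth.
#'
#' @return data.frame `depth_m`, `pr_copies_per_genome`,
#'   `transcript_fraction_percent`.
#' @export
bundle_depth_design <- function() {
  data.frame(
    depth_m = c(25, 75, 125, 200, 500, 770, 1000),
    pr_copies_per_genome = c(0.7, 0.7, 0.9, 0.34, 0.34, 0.2, 0.15),
    transcript_fraction_percent = c(0.02, 0.02, 0.02, 0.004, 0.001, 0.001,
                                    0.001),
    stringsAsFactors = FALSE)
}

#' Simulate a complete study bundle on disk
#'
#' Generates opsins (planted motifs and taxa), decoys, a depth-stratified
#' coverage table, transcript counts and all truth ledgers, and writes them
#' as FASTA/TSV files ready for [run_pipeline()].
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; all randomness derives from it.
#' @param n_opsins,n_decoys record counts (decoys cycle the three classes).
#' @param noise coverage noise model, see [make_community_coverage()].
#' @param transcript_noise `"binomial"` or `"none"`.
#' @param uscg_mean_coverage mean single-copy marker coverage.
#' @param total_reads total non-rRNA reads per metatranscriptome sample.
#' @return invisibly, a list with the file `paths` and the in-memory
#'   `records`, `truth`, `coverage`, `metadata`, `transcripts` objects.
#' @export
simulate_bundle <- function(dir, seed = 1L, n_opsins = 100L,
                            n_decoys = 30L,
                            noise = c("poisson", "none", "lognormal"),
                            transcript_noise = c("binomial", "none"),
                            uscg_mean_coverage = 100,
                            total_reads = 2e6) {
  noise <- match.arg(noise)
  transcript_noise <- match.arg(transcript_noise)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scaffold <- pr_reference()
  design <- bundle_depth_design()
  taxa <- bundle_taxon_table()
  base <- as.integer(seed) * 1009L

  # --- sequence records -----------------------------------------------------
  counts <- pmax(1L, round(taxa$fraction * n_opsins))
  while (sum(counts) > n_opsins) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  while (sum(counts) < n_opsins) counts[which.max(taxa$fraction)] <-
    counts[which.max(taxa$fraction)] + 1L

  # SAR11 carries both the shallow DTE-Q/DTE-L types and the deep DTT-T /
  # DTQ-Q types; other taxa keep one label each
  sar11_labels <- c("DTE-Q", "DTE-L", "DTT-T", "DTQ-Q")
  sar11_weights <- c(0.55, 0.1, 0.3, 0.05)

  records <- list()
  truth_records <- list()
  gene_meta <- list()
  k <- 0L
  identities <- with_seed(base + 1L, runif(n_opsins, 0.72, 0.95))
  sar11_pick <- with_seed(base + 2L,
                          sample(sar11_labels, n_opsins, TRUE, sar11_weights))
  for (t in seq_len(nrow(taxa))) {
    for (j in seq_len(counts[t])) {
      k <- k + 1L
      label <- if (taxa$taxon[t] == "SAR11") sar11_pick[k] else taxa$label[t]
      out <- make_opsin(identities[k], motif_from_label(label),
                        seed = base + 10L + k, scaffold = scaffold,
                        id = sprintf("pr_%03d", k))
      out$record$taxon <- taxa$taxon[t]
      records[[length(records) + 1L]] <- out$record
      tr <- out$truth
      tr$taxon <- taxa$taxon[t]
      tr$combined_label <- label
      truth_records[[length(truth_records) + 1L]] <- tr
      gene_meta[[length(gene_meta) + 1L]] <- data.frame(
        gene_id = out$record$id, taxon = taxa$taxon[t],
        stringsAsFactors = FALSE)
    }
  }
  kinds <- rep(c("six_tm", "no_lysine", "soluble"), length.out = n_decoys)
  for (d in seq_len(n_decoys)) {
    out <- make_decoy(kinds[d], seed = base + 500L + d, scaffold = scaffold,
                      id = sprintf("decoy_%03d", d))
    records[[length(records) + 1L]] <- out$record
    tr <- out$truth
    tr$taxon <- NA_character_
    tr$combined_label <- NA_character_
    truth_records[[length(truth_records) + 1L]] <- tr
  }
  truth_records <- do.call(rbind, truth_records)
  gene_meta <- do.call(rbind, gene_meta)

  # --- planted copies per genome -------------------------------------------
  n_dep <- nrow(design)
  opsins <- truth_records[truth_records$is_opsin, , drop = FALSE]
  deep_share <- ifelse(design$depth_m >= 200, 0.75, 0.08)
  planted <- list()
  for (t in seq_len(nrow(taxa))) {
    tx <- taxa$taxon[t]
    ids <- opsins$record_id[opsins$taxon == tx]
    taxon_total <- design$pr_copies_per_genome * taxa$fraction[t]
    if (tx == "SAR11") {
      deep_ids <- opsins$record_id[opsins$taxon == tx &
                                     opsins$combined_label %in%
                                       c("DTT-T", "DTQ-Q")]
      surf_ids <- setdiff(ids, deep_ids)
      for (g in deep_ids) {
        planted[[g]] <- taxon_total * deep_share / max(1L, length(deep_ids))
      }
      for (g in surf_ids) {
        planted[[g]] <- taxon_total * (1 - deep_share) /
          max(1L, length(surf_ids))
      }
    } else {
      for (g in ids) planted[[g]] <- taxon_total / max(1L, length(ids))
    }
  }
  # decoys are present in the catalog at low, depth-flat abundance
  for (g in truth_records$record_id[!truth_records$is_opsin]) {
    planted[[g]] <- rep(0.02, n_dep)
  }
  # retinal biosynthesis context genes
  planted[["blh"]] <- c(0.5, 0.5, 0.45, 0.05, 0.02, 0.01, 0.01)
  planted[["crtY"]] <- c(0.4, 0.4, 0.35, 0.04, 0.02, 0.01, 0.01)
  planted[["crtB"]] <- rep(0.3, n_dep)
  planted[["crtI"]] <- rep(0.3, n_dep)
  planted[["diox1"]] <- design$pr_copies_per_genome / 3

  cc <- make_community_coverage(
    n_samples = n_dep, depths = design$depth_m, planted = planted,
    uscg_mean_coverage = uscg_mean_coverage, noise = noise,
    seed = base + 3L)

  tc <- make_transcript_counts(
    design$transcript_fraction_percent, total_reads,
    noise = transcript_noise, seed = base + 4L,
    sample_ids = cc$metadata$sample_id)

  # --- write ---------------------------------------------------------------
  paths <- list(
    fasta = file.path(dir, "sequences.fasta"),
    coverage = file.path(dir, "coverage.tsv"),
    sample_metadata = file.path(dir, "sample_metadata.tsv"),
    gene_metadata = file.path(dir, "gene_metadata.tsv"),
    transcripts = file.path(dir, "transcripts.tsv"),
    truth_records = file.path(dir, "truth_records.tsv"),
    truth_coverage = file.path(dir, "truth_coverage.tsv"),
    truth_transcripts = file.path(dir, "truth_transcripts.tsv"))
  write_fasta(records, paths$fasta)
  write_tsv(cc$coverage, paths$coverage)
  write_tsv(cc$metadata, paths$sample_metadata)
  write_tsv(gene_meta, paths$gene_metadata)
  write_tsv(tc$counts, paths$transcripts)
  write_tsv(truth_records, paths$truth_records)
  write_tsv(cc$truth, paths$truth_coverage)
  write_tsv(tc$truth, paths$truth_transcripts)

  invisible(list(paths = paths, records = records, truth = truth_records,
                 coverage = cc$coverage, metadata = cc$metadata,
                 coverage_truth = cc$truth, transcripts = tc$counts,
                 transcript_truth = tc$truth, design = design))
}
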