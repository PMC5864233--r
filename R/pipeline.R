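# Pipeline orchestration: screen -> annotate -> cluster -> abundance ->
# expression, with a config object, per-stage logging, fixed output schemas
# and a machine-readable manifest. Outputs carry no timestamps, so a rerun
# with the same config and inputs is byte-identical.

#' Build a pipeline run configuration
#'
#' @param fasta protein FASTA path (required).
#' @param outdir output directory (required).
#' @param coverage,sample_metadata,transcripts,gene_metadata,hmm_hits
#'   optional input TSV / HMMER tabular paths; stages lacking their inputs
#'   are skipped.
#' @param window,threshold,min_tm_length,merge_gap,tm7_tolerance screening
#'   parameters, see [screen_params()].
#' @param min_identity alignment-identity floor for motif annotation.
#' @param cluster_threshold,cluster_level dereplication settings, see
#'   [greedy_cluster()].
#' @param evalue_cutoff HMMER hit E-value cutoff, see [read_hmm_hits()].
#' @param uscg_stat `"mean"` or `"median"` marker normalization.
#' @param gene_sets named list of gene-id sets profiled per sample (e.g. the
#'   retinal-biosynthesis genes); the set of screened-in rhodopsins is always
#'   added as `"proteorhodopsin"`.
#' @return list of class `opsinscan_config`.
#' @export
opsinscan_config <- function(fasta, outdir, coverage = NULL,
                             sample_metadata = NULL, transcripts = NULL,
                             gene_metadata = NULL, hmm_hits = NULL,
                             window = 19L, threshold = 1.6,
                             min_tm_length = 15L, merge_gap = 5L,
                             tm7_tolerance = 2L, min_identity = 0.25,
                             cluster_threshold = 0.95,
                             cluster_level = "amino_acid",
                             evalue_cutoff = 1e-5, uscg_stat = "mean",
                             gene_sets = list()) {
  cfg <- list(fasta = fasta, outdir = outdir, coverage = coverage,
              sample_metadata = sample_metadata, transcripts = transcripts,
              gene_metadata = gene_metadata, hmm_hits = hmm_hits,
              window = as.integer(window), threshold = threshold,
              min_tm_length = as.integer(min_tm_length),
              merge_gap = as.integer(merge_gap),
              tm7_tolerance = as.integer(tm7_tolerance),
              min_identity = min_identity,
              cluster_threshold = cluster_threshold,
              cluster_level = cluster_level,
              evalue_cutoff = evalue_cutoff, uscg_stat = uscg_stat,
              gene_sets = gene_sets)
  class(cfg) <- "opsinscan_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unstated fields take the [opsinscan_config()] defaults.
#'
#' @param path YAML file with keys matching [opsinscan_config()] arguments.
#' @return list of class `opsinscan_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(opsinscan_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(opsinscan_config, y)
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full survey pipeline
#'
#' Stages: read FASTA (optionally restricted to HMMER hits), opsin screening,
#' motif annotation of the survivors, dereplication, coverage-based abundance
#' profiling (per gene, per motif label, per taxon, per gene set) and
#' transcript fractions. Writes `screen_results.tsv`, `motif_calls.tsv`,
#' `clusters.tsv`, `abundance.tsv`, `expression.tsv`, a `manifest.json`
#' (config echo, input checksums, package version) and a human-readable
#' `summary.txt` with the record funnel and motif frequency table. An
#' `INCOMPLETE` marker file is present while the run is in flight and
#' removed on success.
#'
#' @param config an [opsinscan_config()].
#' @param reference a [pr_reference()] frame.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the output paths and in-memory results.
#' @export
run_pipeline <- function(config, reference = pr_reference(), quiet = FALSE) {
  stopifnot(inherits(config, "opsinscan_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$outdir, "INCOMPLETE")
  file.create(marker)
  outputs <- list()

  # --- input ----------------------------------------------------------------
  records <- stage("read_fasta", {
    if (is.null(config$fasta) || !file.exists(config$fasta)) {
      stop("input FASTA not found: ", config$fasta, call. = FALSE)
    }
    read_fasta(config$fasta)
  })
  say("input: %d record(s) from %s", length(records), config$fasta)

  if (!is.null(config$hmm_hits)) {
    hits <- stage("hmm_hits",
                  read_hmm_hits(config$hmm_hits, config$evalue_cutoff))
    records <- records[names(records) %in% hits]
    say("hmm filter: %d candidate(s) retained", length(records))
    if (length(records) == 0L) {
      stop("pipeline stage 'hmm_hits' failed: no candidates remain after the E-value filter",
           call. = FALSE)
    }
  }

  # --- screen ---------------------------------------------------------------
  params <- screen_params(window = config$window,
                          threshold = config$threshold,
                          min_tm_length = config$min_tm_length,
                          merge_gap = config$merge_gap,
                          tm7_tolerance = config$tm7_tolerance,
                          min_identity = config$min_identity)
  screen <- stage("screen", screen_opsins(records, reference, params))
  outputs$screen_results <- file.path(config$outdir, "screen_results.tsv")
  write_tsv(screen, outputs$screen_results)
  passing <- records[screen$record_id[screen$passed]]
  say("screen: %d / %d record(s) pass the 7-TM + retinal-lysine filter",
      length(passing), nrow(screen))
  if (length(passing) == 0L) {
    stop("pipeline stage 'screen' failed: no records pass the opsin filter",
         call. = FALSE)
  }

  # --- annotate -------------------------------------------------------------
  motifs <- stage("annotate", suppressWarnings(
    annotate_motifs(passing, reference, config$min_identity)))
  outputs$motif_calls <- file.path(config$outdir, "motif_calls.tsv")
  write_tsv(motifs, outputs$motif_calls)
  say("annotate: %d / %d complete motif call(s)", sum(motifs$complete),
      nrow(motifs))

  # --- cluster --------------------------------------------------------------
  clusters <- stage("cluster", greedy_cluster(
    passing, config$cluster_threshold, config$cluster_level))
  cluster_df <- as.data.frame(clusters)
  outputs$clusters <- file.path(config$outdir, "clusters.tsv")
  write_tsv(cluster_df, outputs$clusters)
  say("cluster: %d non-redundant representative(s) at %.0f%% identity",
      length(clusters), 100 * config$cluster_threshold)

  # --- abundance ------------------------------------------------------------
  abundance_df <- NULL
  if (!is.null(config$coverage) && !is.null(config$sample_metadata)) {
    abundance_df <- stage("abundance", {
      cov <- coverage_table(read_tsv(config$coverage))
      meta <- read_tsv(config$sample_metadata)
      pr_ids <- intersect(unique(cov$gene_id[!cov$is_uscg]),
                          vapply(passing, `[[`, character(1), "id"))
      depth_of <- function(s) meta$depth_m[match(s, meta$sample_id)]
      rows <- list()

      gene_prof <- copy_number_profile(
        cov[cov$is_uscg | cov$gene_id %in% pr_ids, , drop = FALSE],
        uscg_stat = config$uscg_stat)
      rows$gene <- data.frame(
        sample_id = gene_prof$sample_id,
        depth_m = depth_of(gene_prof$sample_id), category_type = "gene",
        category = gene_prof$category,
        copies_per_genome = gene_prof$copies_per_genome,
        fraction = NA_real_, stringsAsFactors = FALSE)

      lab <- setNames(motifs$combined_label, motifs$record_id)
      lab <- lab[!is.na(lab)]
      if (length(lab) > 0) {
        mp <- relative_abundance(copy_number_profile(
          cov[cov$is_uscg | cov$gene_id %in% names(lab), , drop = FALSE],
          categories = lab, uscg_stat = config$uscg_stat))
        rows$motif <- data.frame(
          sample_id = mp$sample_id, depth_m = depth_of(mp$sample_id),
          category_type = "motif", category = mp$category,
          copies_per_genome = mp$copies_per_genome, fraction = mp$fraction,
          stringsAsFactors = FALSE)
      }

      if (!is.null(config$gene_metadata)) {
        gm <- read_tsv(config$gene_metadata)
        tax <- setNames(gm$taxon, gm$gene_id)
        tp <- relative_abundance(copy_number_profile(
          cov[cov$is_uscg | cov$gene_id %in% pr_ids, , drop = FALSE],
          categories = tax, uscg_stat = config$uscg_stat))
        rows$taxon <- data.frame(
          sample_id = tp$sample_id, depth_m = depth_of(tp$sample_id),
          category_type = "taxon", category = tp$category,
          copies_per_genome = tp$copies_per_genome, fraction = tp$fraction,
          stringsAsFactors = FALSE)
      }

      sets <- config$gene_sets
      sets$proteorhodopsin <- pr_ids
      set_rows <- do.call(rbind, lapply(names(sets), function(nm) {
        members <- intersect(sets[[nm]], unique(cov$gene_id[!cov$is_uscg]))
        vals <- vapply(unique(cov$sample_id), function(s) {
          if (length(members) == 0L) 0 else {
            copies_per_genome(cov, s, members, config$uscg_stat)
          }
        }, numeric(1))
        data.frame(sample_id = unique(cov$sample_id),
                   depth_m = depth_of(unique(cov$sample_id)),
                   category_type = "gene_set", category = nm,
                   copies_per_genome = vals, fraction = NA_real_,
                   stringsAsFactors = FALSE)
      }))
      rows$sets <- set_rows
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    })
    outputs$abundance <- file.path(config$outdir, "abundance.tsv")
    write_tsv(abundance_df, outputs$abundance)
    say("abundance: %d profile row(s) across %d sample(s)",
        nrow(abundance_df), length(unique(abundance_df$sample_id)))
  }

  # --- expression -----------------------------------------------------------
  expression_df <- NULL
  if (!is.null(config$transcripts)) {
    expression_df <- stage("expression", {
      tx <- read_tsv(config$transcripts)
      tx$fraction_percent <- transcript_fraction(tx$rhodopsin_reads,
                                                 tx$total_nonrrna_reads)
      tx
    })
    outputs$expression <- file.path(config$outdir, "expression.tsv")
    write_tsv(expression_df, outputs$expression)
    say("expression: transcript fractions for %d sample(s)",
        nrow(expression_df))
  }

  # --- manifest and summary -------------------------------------------------
  inputs <- Filter(Negate(is.null),
                   config[c("fasta", "coverage", "sample_metadata",
                            "transcripts", "gene_metadata", "hmm_hits")])
  manifest <- list(
    tool = "opsinscan",
    version = as.character(utils::packageVersion("opsinscan")),
    reference = list(name = reference$name,
                     synthetic = reference$synthetic),
    config = config[setdiff(names(config), "gene_sets")],
    gene_sets = lapply(config$gene_sets, as.character),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    outputs = lapply(outputs, basename))
  outputs$manifest <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, outputs$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  n_complete <- sum(motifs$complete)
  freq <- sort(table(motifs$combined_label[motifs$complete]),
               decreasing = TRUE)
  summary_lines <- c(
    "opsinscan run summary",
    "=====================",
    sprintf("input records:            %d", length(records)),
    sprintf("pass 7-TM+lysine screen:  %d", length(passing)),
    sprintf("complete motif calls:     %d", n_complete),
    sprintf("non-redundant clusters:   %d (threshold %.2f, %s)",
            length(clusters), config$cluster_threshold,
            config$cluster_level),
    "",
    "motif frequency (complete calls):",
    sprintf("  %-8s %d", names(freq), as.integer(freq)))
  outputs$summary <- file.path(config$outdir, "summary.txt")
  writeLines(summary_lines, outputs$summary)

  file.remove(marker)
  say("done: outputs in %s", config$outdir)
  invisible(list(outputs = outputs, screen = screen, motifs = motifs,
                 clusters = clusters, abundance = abundance_df,
                 expression = expression_df))
}
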