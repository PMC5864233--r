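# Synthetic-data generators with planted ground truth. The generators define
# the study conditions every downstream estimator is tested against: opsin
# and decoy sequences for the screen, planted motifs for the annotator,
# coverage tables with known copies-per-genome, and transcript counts with
# known fractions.

HYDROPHOBIC_SET <- c("A", "I", "L", "M", "F", "V", "W")

#' @noRd
empty_truth <- function() {
  data.frame(record_id = character(0), is_opsin = logical(0),
             decoy_kind = character(0), r97 = character(0),
             r101 = character(0), r105 = character(0), r108 = character(0),
             tm_segment_count = integer(0),
             retinal_lysine_present = logical(0),
             target_identity = numeric(0), realized_identity = numeric(0),
             rng_seed = integer(0), stringsAsFactors = FALSE)
}

#' Generate a synthetic opsin by mutating the reference scaffold
#'
#' Produces a mutated copy of the scaffold in which (i) the four motif
#' positions carry exactly the requested residues, (ii) the retinal-binding
#' lysine and a 3-residue flank around it are untouched, (iii) substitutions
#' inside the reference transmembrane segments are restricted to hydrophobic
#' residues (A/I/L/M/F/V/W) so the topology is preserved, and (iv) the
#' realized identity to the scaffold is within 0.03 of `target_identity`
#' (mutations are counted substitutions, so it is exact to within rounding).
#'
#' @param target_identity requested identity to the scaffold, in
#'   `[0.3, 1]`. The default 0.8 reflects typical within-clade
#'   proteorhodopsin amino-acid divergence.
#' @param motif named residues for positions 97/101/105/108, as from
#'   [motif_from_label()]; default is the scaffold's own DTE-L.
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param scaffold a [pr_reference()] frame.
#' @param id record id (default derived from the seed).
#' @return list with `record` (a [protein_record()]) and `truth` (one-row
#'   data.frame of planted values).
#' @examples
#' out <- make_opsin(0.9, motif_from_label("DTQ-Q"), seed = 7)
#' out$truth$realized_identity
#' @export
make_opsin <- function(target_identity = 0.8,
                       motif = c(r97 = "D", r101 = "T", r105 = "L",
                                 r108 = "E"),
                       seed = 1L, scaffold = pr_reference(), id = NULL) {
  if (!is.numeric(target_identity) || target_identity < 0.3 ||
      target_identity > 1) {
    stop("`target_identity` must be in [0.3, 1]", call. = FALSE)
  }
  motif <- toupper(unname(motif))
  if (length(motif) != 4L || !all(motif %in% AA_STANDARD)) {
    stop("`motif` must be 4 standard one-letter residues (97/101/105/108)",
         call. = FALSE)
  }
  if (is.null(id)) id <- sprintf("opsin_s%d", as.integer(seed))

  ch <- seq_chars(scaffold$aa_sequence)
  n <- length(ch)
  lys <- scaffold$retinal_lysine_pr
  motif_pos <- scaffold$motif_positions_pr
  protected <- c(motif_pos, (lys - 3L):(lys + 3L))
  tm_idx <- unlist(apply(scaffold$tm_segments, 1L,
                         function(s) s[1L]:s[2L], simplify = FALSE))

  with_seed(seed, {
    mut <- ch
    mut[motif_pos] <- motif
    d_target <- round((1 - target_identity) * n)
    d_planted <- sum(mut != ch)
    extra <- max(0L, d_target - d_planted)
    # only positions still matching the scaffold are candidates, so every
    # substitution adds exactly one mismatch and the identity is exact
    cand <- setdiff(seq_len(n), protected)
    pos <- if (extra > 0L) sample(cand, extra) else integer(0)
    for (p in pos) {
      pool <- if (p %in% tm_idx) HYDROPHOBIC_SET else AA_STANDARD
      mut[p] <- sample(setdiff(pool, mut[p]), 1L)
    }
    realized <- 1 - sum(mut != ch) / n
    rec <- protein_record(id, paste(mut, collapse = ""))
    truth <- data.frame(
      record_id = id, is_opsin = TRUE, decoy_kind = NA_character_,
      r97 = motif[1L], r101 = motif[2L], r105 = motif[3L], r108 = motif[4L],
      tm_segment_count = 7L, retinal_lysine_present = TRUE,
      target_identity = target_identity, realized_identity = realized,
      rng_seed = as.integer(seed), stringsAsFactors = FALSE)
    list(record = rec, truth = truth)
  })
}

#' Generate a synthetic non-opsin decoy
#'
#' Three decoy classes exercise the exclusion rule:
#' * `six_tm` - scaffold with the seventh transmembrane helix replaced by
#'   hydrophilic residues (the lysine itself is kept), so only six segments
#'   remain;
#' * `no_lysine` - scaffold with the retinal lysine substituted to alanine;
#' * `soluble` - random hydrophilic-biased sequence with no hydropathy
#'   window reaching the transmembrane threshold.
#'
#' @param kind one of `"six_tm"`, `"no_lysine"`, `"soluble"`.
#' @param seed integer seed.
#' @param scaffold a [pr_reference()] frame.
#' @param id record id (default derived from kind and seed).
#' @return list with `record` and `truth` as in [make_opsin()].
#' @export
make_decoy <- function(kind = c("six_tm", "no_lysine", "soluble"),
                       seed = 1L, scaffold = pr_reference(), id = NULL) {
  kind <- match.arg(kind)
  if (is.null(id)) id <- sprintf("decoy_%s_s%d", kind, as.integer(seed))
  ch <- seq_chars(scaffold$aa_sequence)
  lys <- scaffold$retinal_lysine_pr
  hydrophilic <- c("D", "E", "R", "N", "Q", "S")

  with_seed(seed, {
    if (kind == "six_tm") {
      tm7 <- scaffold$tm_segments[7L, ]
      idx <- setdiff(tm7[["start"]]:tm7[["end"]], lys)
      ch[idx] <- sample(hydrophilic, length(idx), replace = TRUE)
      tm_count <- 6L
      lys_present <- TRUE
    } else if (kind == "no_lysine") {
      ch[lys] <- "A"
      tm_count <- 7L
      lys_present <- FALSE
    } else {
      # hydrophilic-biased alphabet; windows stay far below the TM threshold
      alpha <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "A", "L")
      wts <- c(3, 3, 3, 3, 2, 2, 2, 2, 1, 1, 0.5, 0.5)
      repeat {
        ch <- sample(alpha, 250L, replace = TRUE, prob = wts / sum(wts))
        ch[1L] <- "M"
        if (max(hydropathy_profile(paste(ch, collapse = ""), 19L)) < 1.6) {
          break
        }
      }
      tm_count <- 0L
      lys_present <- FALSE
    }
    rec <- protein_record(id, paste(ch, collapse = ""))
    truth <- data.frame(
      record_id = id, is_opsin = FALSE, decoy_kind = kind,
      r97 = NA_character_, r101 = NA_character_, r105 = NA_character_,
      r108 = NA_character_, tm_segment_count = tm_count,
      retinal_lysine_present = lys_present, target_identity = NA_real_,
      realized_identity = NA_real_, rng_seed = as.integer(seed),
      stringsAsFactors = FALSE)
    list(record = rec, truth = truth)
  })
}

#' Generate a community coverage table with planted copies-per-genome
#'
#' Emits ten universal single-copy marker rows per sample (coverage around
#' `uscg_mean_coverage` under the chosen noise model) and one row per planted
#' gene with coverage `copies_per_genome x (sample's realized marker mean)`,
#' noised accordingly. Under `noise = "none"` every downstream
#' copies-per-genome estimate recovers the planted value exactly.
#'
#' @param n_samples number of samples (>= 1).
#' @param depths sample depths in meters, recycled to `n_samples`.
#' @param planted named list (or genes x samples matrix) of planted
#'   copies-per-genome; scalars are recycled across samples.
#' @param uscg_mean_coverage positive mean marker coverage.
#' @param noise `"none"`, `"poisson"` (counts), or `"lognormal"`
#'   (multiplicative, `sdlog = sigma`).
#' @param sigma lognormal sdlog (default 0.2).
#' @param seed integer seed.
#' @return list with `coverage` (a [coverage_table()]), `metadata`
#'   (`sample_id`, `depth_m`, `date`), and `truth` (`sample_id`, `gene_id`,
#'   `copies_per_genome`).
#' @examples
#' cc <- make_community_coverage(1, 25, list(g1 = 0.7), 100, "none", seed = 1)
#' copies_per_genome(cc$coverage, cc$coverage$sample_id[1], "g1")  # 0.7
#' @export
make_community_coverage <- function(n_samples, depths, planted,
                                    uscg_mean_coverage = 100,
                                    noise = c("none", "poisson", "lognormal"),
                                    sigma = 0.2, seed = 1L) {
  noise <- match.arg(noise)
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 1L)
  if (uscg_mean_coverage <= 0) {
    stop("`uscg_mean_coverage` must be positive", call. = FALSE)
  }
  if (is.matrix(planted)) {
    planted <- setNames(lapply(seq_len(nrow(planted)),
                               function(i) planted[i, ]),
                        rownames(planted))
  }
  if (length(planted) == 0L || is.null(names(planted))) {
    stop("`planted` must be a non-empty named list: gene_id -> copies per genome",
         call. = FALSE)
  }
  planted <- lapply(planted, function(v) {
    v <- rep_len(as.numeric(v), n_samples)
    if (any(v < 0)) stop("planted copies per genome must be >= 0",
                         call. = FALSE)
    v
  })
  depths <- rep_len(depths, n_samples)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  dates <- format(seq(as.Date("2010-08-15"), by = "month",
                      length.out = n_samples))

  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (s in seq_len(n_samples)) {
      ucov <- switch(noise,
        none = rep(uscg_mean_coverage, 10L),
        poisson = {
          v <- rpois(10L, uscg_mean_coverage)
          while (any(v == 0L)) v[v == 0L] <- rpois(sum(v == 0L),
                                                   uscg_mean_coverage)
          as.numeric(v)
        },
        lognormal = uscg_mean_coverage *
          rlnorm(10L, meanlog = -sigma^2 / 2, sdlog = sigma))
      realized <- mean(ucov)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids[s], gene_id = uscg_cogs(), coverage = ucov,
        is_uscg = TRUE, stringsAsFactors = FALSE)
      for (g in names(planted)) {
        cpg <- planted[[g]][s]
        lambda <- cpg * realized
        cov <- switch(noise,
          none = lambda,
          poisson = as.numeric(rpois(1L, lambda)),
          lognormal = if (lambda == 0) 0 else {
            lambda * rlnorm(1L, meanlog = -sigma^2 / 2, sdlog = sigma)
          })
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_ids[s], gene_id = g, coverage = cov,
          is_uscg = FALSE, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sample_ids[s], gene_id = g, copies_per_genome = cpg,
          stringsAsFactors = FALSE)
      }
    }
    list(
      coverage = coverage_table(do.call(rbind, rows)),
      metadata = data.frame(sample_id = sample_ids, depth_m = depths,
                            date = dates, stringsAsFactors = FALSE),
      truth = do.call(rbind, truth)
    )
  })
}

#' Generate transcript read counts with a planted rhodopsin fraction
#'
#' @param planted_fraction_percent per-sample rhodopsin fraction of total
#'   non-rRNA reads, in percent (`[0, 100]`).
#' @param total_reads total non-rRNA reads per sample (scalar or vector).
#' @param noise `"none"` (deterministic rounding) or `"binomial"` (counts
#'   drawn as `Binomial(total, fraction/100)`).
#' @param seed integer seed.
#' @param sample_ids optional sample identifiers.
#' @return list with `counts` (`sample_id`, `rhodopsin_reads`,
#'   `total_nonrrna_reads`) and `truth` (`sample_id`,
#'   `planted_fraction_percent`).
#' @examples
#' make_transcript_counts(0.02, 1e6, "none", seed = 1)$counts$rhodopsin_reads
#' @export
make_transcript_counts <- function(planted_fraction_percent, total_reads,
                                   noise = c("none", "binomial"), seed = 1L,
                                   sample_ids = NULL) {
  noise <- match.arg(noise)
  f <- as.numeric(planted_fraction_percent)
  if (any(f < 0 | f > 100)) {
    stop("`planted_fraction_percent` must be in [0, 100]", call. = FALSE)
  }
  total <- rep_len(as.numeric(total_reads), length(f))
  if (any(total < 1)) stop("`total_reads` must be >= 1", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_along(f))

  with_seed(seed, {
    reads <- switch(noise,
      none = round(total * f / 100),
      binomial = rbinom(length(f), size = as.integer(total), prob = f / 100))
    list(
      counts = data.frame(sample_id = sample_ids,
                          rhodopsin_reads = as.integer(reads),
                          total_nonrrna_reads = as.integer(total),
                          stringsAsFactors = FALSE),
      truth = data.frame(sample_id = sample_ids,
                         planted_fraction_percent = f,
                         stringsAsFactors = FALSE)
    )
  })
}
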