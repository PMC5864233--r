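# Copies-per-genome via universal single-copy gene (USCG) normalization,
# depth profiles, relative abundances, gene-set profiles and transcript
# fractions.

#' The ten universal single-copy marker genes used for normalization
#'
#' Mean coverage over these ten COGs estimates the genome equivalents in a
#' sample; dividing a gene's coverage by it yields copies per genome.
#'
#' @return character vector of ten COG identifiers.
#' @export
uscg_cogs <- function() {
  c("COG0012", "COG0016", "COG0018", "COG0172", "COG0215",
    "COG0495", "COG0525", "COG0533", "COG0541", "COG0552")
}

#' Validate a per-sample gene coverage table
#'
#' @param x data.frame with columns `sample_id`, `gene_id`, `coverage`
#'   (non-negative), `is_uscg` (logical marking the single-copy marker rows).
#' @return the validated data.frame, classed `coverage_table`.
#' @export
coverage_table <- function(x) {
  req <- c("sample_id", "gene_id", "coverage", "is_uscg")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("coverage table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$coverage < 0)) stop("coverage must be >= 0", call. = FALSE)
  x$is_uscg <- as.logical(x$is_uscg)
  class(x) <- unique(c("coverage_table", class(x)))
  x
}

#' @noRd
uscg_mean <- function(table, sample_id, uscg_stat = "mean") {
  rows <- table[table$sample_id == sample_id & table$is_uscg, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("sample '%s' has no single-copy marker rows", sample_id),
         call. = FALSE)
  }
  bad <- rows$gene_id[rows$coverage <= 0]
  if (length(bad) > 0) {
    stop(sprintf("sample '%s': marker '%s' has non-positive coverage",
                 sample_id, bad[1L]), call. = FALSE)
  }
  if (uscg_stat == "median") median(rows$coverage) else mean(rows$coverage)
}

#' Copies per genome of a gene set in one sample
#'
#' Sums the coverages of `gene_ids` in the sample and divides by the mean
#' coverage of the sample's single-copy marker genes. Genes absent from the
#' sample's rows contribute coverage 0 (absence from an assembled catalog is
#' evidence of absence at the coverage level).
#'
#' @param table a [coverage_table()].
#' @param sample_id one sample identifier.
#' @param gene_ids character vector of gene ids (a single gene or a set).
#' @param uscg_stat `"mean"` (the convention) or `"median"` (robust option).
#' @return non-negative scalar: copies per genome.
#' @examples
#' tab <- coverage_table(data.frame(
#'   sample_id = "s1", gene_id = c(uscg_cogs(), "pr1"),
#'   coverage = c(rep(100, 10), 70), is_uscg = c(rep(TRUE, 10), FALSE)))
#' copies_per_genome(tab, "s1", "pr1")  # 0.7
#' @export
copies_per_genome <- function(table, sample_id, gene_ids,
                              uscg_stat = c("mean", "median")) {
  uscg_stat <- match.arg(uscg_stat)
  table <- coverage_table(table)
  if (!sample_id %in% table$sample_id) {
    stop(sprintf("sample '%s' not present in the coverage table", sample_id),
         call. = FALSE)
  }
  norm <- uscg_mean(table, sample_id, uscg_stat)
  rows <- table[table$sample_id == sample_id &
                  table$gene_id %in% gene_ids & !table$is_uscg, ,
                drop = FALSE]
  sum(rows$coverage) / norm
}

#' Per-sample copy-number profile
#'
#' Copies per genome for every (sample, category) combination, where the
#' category is the gene itself or a supplied gene -> category mapping (taxon,
#' motif label, ...). Category values are coverage-weighted sums over member
#' genes.
#'
#' @param table a [coverage_table()].
#' @param categories optional named character vector mapping gene_id ->
#'   category; genes not named map to `"unassigned"`. When `NULL` each gene
#'   is its own category.
#' @param uscg_stat see [copies_per_genome()].
#' @return data.frame `sample_id`, `category`, `copies_per_genome`.
#' @export
copy_number_profile <- function(table, categories = NULL,
                                uscg_stat = c("mean", "median")) {
  uscg_stat <- match.arg(uscg_stat)
  table <- coverage_table(table)
  samples <- unique(table$sample_id)
  genes <- table[!table$is_uscg, , drop = FALSE]
  if (is.null(categories)) {
    genes$category <- genes$gene_id
  } else {
    genes$category <- unname(categories[genes$gene_id])
    genes$category[is.na(genes$category)] <- "unassigned"
  }
  out <- do.call(rbind, lapply(samples, function(s) {
    norm <- uscg_mean(table, s, uscg_stat)
    rows <- genes[genes$sample_id == s, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    agg <- tapply(rows$coverage, rows$category, sum)
    data.frame(sample_id = s, category = names(agg),
               copies_per_genome = as.numeric(agg) / norm,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-depth summary of a copy-number profile
#'
#' Joins sample depths onto the profile and summarizes each (depth, category)
#' group: n, mean, median, quartiles, min, max. Depth grouping is by exact
#' value (the study design samples fixed depths); no binning.
#'
#' @param profile data.frame from [copy_number_profile()] (columns
#'   `sample_id`, `category`, `copies_per_genome`).
#' @param metadata data.frame with `sample_id` and `depth_m`.
#' @return data.frame `depth_m`, `category`, `n`, `mean`, `median`, `q1`,
#'   `q3`, `min`, `max`, sorted by depth then category.
#' @export
depth_profile <- function(profile, metadata) {
  stopifnot(all(c("sample_id", "category", "copies_per_genome") %in%
                  names(profile)),
            all(c("sample_id", "depth_m") %in% names(metadata)))
  depth <- metadata$depth_m[match(profile$sample_id, metadata$sample_id)]
  if (anyNA(depth)) {
    stop("profile contains sample(s) missing from the metadata: ",
         paste(unique(profile$sample_id[is.na(depth)]), collapse = ", "),
         call. = FALSE)
  }
  profile$depth_m <- depth
  key <- interaction(profile$depth_m, profile$category, drop = TRUE)
  rows <- lapply(split(profile, key), function(g) {
    v <- g$copies_per_genome
    q <- unname(quantile(v, c(0.25, 0.75), type = 7))
    data.frame(depth_m = g$depth_m[1L], category = g$category[1L],
               n = length(v), mean = mean(v), median = median(v),
               q1 = q[1L], q3 = q[2L], min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$depth_m, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative abundance of categories within each sample
#'
#' Each category's copies-per-genome divided by the sample total; fractions
#' sum to 1 per sample. Samples with zero total get `NA` fractions (reported
#' with a warning) rather than dividing by zero.
#'
#' @param profile data.frame from [copy_number_profile()].
#' @return the profile with an added `fraction` column.
#' @export
relative_abundance <- function(profile) {
  stopifnot(all(c("sample_id", "category", "copies_per_genome") %in%
                  names(profile)))
  totals <- tapply(profile$copies_per_genome, profile$sample_id, sum)
  tot <- as.numeric(totals[profile$sample_id])
  frac <- ifelse(tot > 0, profile$copies_per_genome / tot, NA_real_)
  if (any(totals == 0)) {
    warning("sample(s) with zero total copies per genome: ",
            paste(names(totals)[totals == 0], collapse = ", "),
            "; fractions undefined", call. = FALSE)
  }
  profile$fraction <- frac
  profile
}

#' Per-depth copies-per-genome for named gene sets
#'
#' Composition of [copies_per_genome()] and [depth_profile()]: each named set
#' (e.g. the retinal-biosynthesis genes crtB/crtI/crtY/blh/diox1 alongside
#' the proteorhodopsins) becomes one category. Set members absent from the
#' whole table are skipped with a warning that counts them.
#'
#' @param table a [coverage_table()].
#' @param sets named list of gene-id character vectors.
#' @param metadata data.frame with `sample_id`, `depth_m`.
#' @param allow_overlap set to TRUE to permit a gene in several sets.
#' @param uscg_stat see [copies_per_genome()].
#' @return data.frame as [depth_profile()], with `category` = set name.
#' @export
gene_set_profile <- function(table, sets, metadata, allow_overlap = FALSE,
                             uscg_stat = c("mean", "median")) {
  uscg_stat <- match.arg(uscg_stat)
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  table <- coverage_table(table)
  all_members <- unlist(sets, use.names = FALSE)
  if (!allow_overlap && anyDuplicated(all_members)) {
    stop("gene sets overlap; pass allow_overlap = TRUE to permit this",
         call. = FALSE)
  }
  known <- unique(table$gene_id[!table$is_uscg])
  unknown <- setdiff(all_members, known)
  if (length(unknown) > 0) {
    warning(sprintf("%d gene id(s) in the sets are absent from the table and were skipped: %s",
                    length(unknown), paste(unknown, collapse = ", ")),
            call. = FALSE)
  }
  samples <- unique(table$sample_id)
  profile <- do.call(rbind, lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], known)
    vals <- vapply(samples, function(s) {
      if (length(members) == 0L) 0 else {
        copies_per_genome(table, s, members, uscg_stat)
      }
    }, numeric(1))
    data.frame(sample_id = samples, category = nm,
               copies_per_genome = vals, stringsAsFactors = FALSE)
  }))
  depth_profile(profile, metadata)
}

#' Transcript fraction of total non-rRNA reads
#'
#' @param rhodopsin_reads,total_nonrrna_reads integer read counts
#'   (vectorized); `0 <= rhodopsin_reads <= total_nonrrna_reads`,
#'   `total >= 1`.
#' @return percent of total reads: `100 * rhodopsin / total`.
#' @examples
#' transcript_fraction(200, 1e6)  # 0.02
#' @export
transcript_fraction <- function(rhodopsin_reads, total_nonrrna_reads) {
  if (any(total_nonrrna_reads < 1)) {
    stop("`total_nonrrna_reads` must be >= 1", call. = FALSE)
  }
  if (any(rhodopsin_reads < 0)) {
    stop("`rhodopsin_reads` must be >= 0", call. = FALSE)
  }
  if (any(rhodopsin_reads > total_nonrrna_reads)) {
    stop("`rhodopsin_reads` cannot exceed `total_nonrrna_reads`",
         call. = FALSE)
  }
  100 * rhodopsin_reads / total_nonrrna_reads
}
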