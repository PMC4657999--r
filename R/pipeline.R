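# Orchestration of the analysis stages plus small report utilities
# (read-length distribution, mappability percentages).

#' Run the full characterization pipeline
#'
#' Executes, in order: score-cutoff selection from the SNR table, candidate
#' retention filters, conservation tiering and naming, specificity / arm /
#' duplicate-mature / cluster / chromosome analyses, isomiR classification,
#' and no-replicate fold change between the two libraries. All thresholds
#' default to the study values (SNR 10:1, count floor 10, E-value tiers
#' 4e-09 / 9e-05 / 2e-04, repeat rule >5 hits at E < 2e-08, 10 kb cluster
#' gap).
#'
#' @param sim input bundle: a list with precursors, stacks, homology,
#'   chrom_lengths, snr, homologs (as from [simulate_mirnaome()], or
#'   assembled from the canonical files via the readers in this package).
#' @param libraries ordered library pair; defaults to the first two count
#'   columns of the precursor table.
#' @param min_snr,min_count,max_genome_hits,genome_evalue,broad_e,narrow_e,single_e,max_gap
#'   stage thresholds (study defaults).
#' @param out_dir optional directory; when given, per-stage TSVs and a JSON
#'   summary are written there.
#' @return list with cutoff, filter report, tiers, names, families,
#'   specificity, arm profiles, duplicate groups, clusters, chromosome
#'   summary, isomiR distribution, fold changes, and a `summary` list of
#'   headline totals.
#' @export
run_pipeline <- function(sim, libraries = NULL,
                         min_snr = 10, min_count = 10L,
                         max_genome_hits = 5L, genome_evalue = 2e-08,
                         broad_e = 4e-09, narrow_e = 9e-05,
                         single_e = 2e-04, max_gap = 10000L,
                         out_dir = NULL) {
  precursors <- sim$precursors
  if (is.null(libraries)) libraries <- library_cols(precursors)[1:2]

  cutoff <- select_score_cutoff(sim$snr, min_snr = min_snr)
  report <- apply_candidate_filters(precursors, sim$homology,
                                    score_cutoff = cutoff,
                                    min_count = min_count,
                                    max_genome_hits = max_genome_hits,
                                    genome_evalue = genome_evalue)
  kept <- precursors[precursors$id %in% report$kept, , drop = FALSE]
  kept_novel <- kept[!kept$is_known, , drop = FALSE]

  tiers <- assign_tiers(unique(kept_novel$id), sim$homology,
                        broad_e = broad_e, narrow_e = narrow_e,
                        single_e = single_e)
  names_df <- assign_names(kept_novel, tiers, sim$homologs)
  families <- group_families(names_df)

  spec_novel <- classify_specificity(kept_novel, libraries,
                                     min_count = min_count)
  arms <- arm_profile(kept_novel, libraries, min_count = min_count)
  dup_groups <- duplicate_mature_groups(kept_novel, min_count = min_count)
  clusters <- detect_clusters(kept, max_gap = max_gap, include_known = TRUE)
  clusters_novel <- detect_clusters(kept_novel, max_gap = max_gap)
  chrom <- chromosome_summary(kept, sim$chrom_lengths)

  classified <- classify_stacks(
    sim$stacks[sim$stacks$precursor_id %in% report$kept, , drop = FALSE],
    kept)
  isomirs <- summarize_isomirs(classified)

  counts <- mature_count_matrix(kept, libraries)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (nrow(counts) && any(pos)) {
    sf <- size_factors(counts)
    fc <- fold_change(counts, sf, libraries)
  } else {
    sf <- NULL
    fc <- data.frame(feature = character(), norm_A = numeric(),
                     norm_B = numeric(), fc = numeric())
  }

  tier_totals <- table(factor(tiers$tier,
                              levels = c("conserved_broad",
                                         "conserved_narrow",
                                         "conserved_single",
                                         "nonconserved")))
  summary <- list(
    score_cutoff = cutoff,
    candidates_in = length(report$kept) + length(report$dropped),
    kept = length(report$kept),
    dropped = as.list(table(report$dropped)),
    novel_precursors = length(unique(kept_novel$id)),
    novel_matures = nrow(kept_novel),
    specificity_totals = spec_novel$totals,
    tier_totals = as.list(tier_totals),
    duplicate_mature_groups =
      length(unique(dup_groups$mature_seq)),
    novel_clusters = nrow(clusters_novel),
    clustered_novel_precursors = sum(clusters_novel$n_members),
    isomir_fractions = isomirs$fractions)

  result <- list(cutoff = cutoff, filter_report = report, tiers = tiers,
                 names = names_df, families = families,
                 specificity = spec_novel, arms = arms,
                 duplicate_groups = dup_groups, clusters = clusters,
                 clusters_novel = clusters_novel, chrom_summary = chrom,
                 classified_reads = classified, isomirs = isomirs,
                 size_factors = sf, fold_changes = fc, summary = summary)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Per-mature count matrix from a precursor table
#'
#' @param precursors precursor table.
#' @param libraries libraries to keep as columns.
#' @return integer matrix, rownames "<id>-<arm>".
#' @export
mature_count_matrix <- function(precursors, libraries) {
  m <- as.matrix(precursors[, libraries, drop = FALSE])
  if (nrow(m)) rownames(m) <- paste0(precursors$id, "-", precursors$arm)
  m
}

#' Write per-stage pipeline outputs and a JSON summary
#'
#' @param result list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return out_dir, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_filter_report(result$filter_report,
                      file.path(out_dir, "filter_report.tsv"))
  w(result$tiers[, c("precursor_id", "tier", "n_species")], "tiers.tsv")
  w(result$names, "names.tsv")
  w(result$specificity$precursor_calls, "specificity_precursors.tsv")
  w(result$specificity$mature_calls, "specificity_matures.tsv")
  w(result$arms, "arm_profiles.tsv")
  w(result$duplicate_groups, "duplicate_matures.tsv")
  cl <- result$clusters
  if (nrow(cl)) {
    flat <- cl[, c("cluster_id", "chrom", "strand", "start", "end",
                   "n_members")]
    flat$members <- vapply(cl$members, paste, "", collapse = ",")
  } else flat <- cl[, 0]
  w(flat, "clusters.tsv")
  w(result$chrom_summary, "chromosome_summary.tsv")
  w(result$isomirs$fractions, "isomir_fractions.tsv")
  w(result$fold_changes, "fold_changes.tsv")
  jsonlite::write_json(result$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Count-weighted read-length distribution
#'
#' @param lengths integer vector of read lengths (one per read family), or a
#'   data.frame with columns length and count.
#' @param counts optional counts parallel to `lengths`.
#' @param range closed length interval of interest (default 18-24 nt).
#' @return list with `histogram` (data.frame length, count) and
#'   `fraction_in_range` (count-weighted fraction inside the interval).
#' @export
length_distribution <- function(lengths, counts = NULL,
                                range = c(18L, 24L)) {
  if (is.data.frame(lengths)) {
    counts <- lengths$count
    lengths <- lengths$length
  }
  if (is.null(counts)) counts <- rep(1L, length(lengths))
  .check(length(lengths) > 0, "no reads")
  .check(counts >= 1, "counts must be positive")
  tot <- tapply(counts, lengths, sum)
  hist <- data.frame(length = as.integer(names(tot)),
                     count = as.integer(tot), row.names = NULL)
  inr <- hist$length >= range[1L] & hist$length <= range[2L]
  list(histogram = hist,
       fraction_in_range = sum(hist$count[inr]) / sum(hist$count))
}

#' Mappability and mapping percentages from library read totals
#'
#' Given per-library totals (raw reads, mappable reads, reads mapped to
#' mature miRNAs, reads on novel and known candidates), computes the derived
#' percentages: mappable/raw, mature-mapped/mappable, novel/mappable and
#' known/mappable, rendered by truncation at 1 decimal for the first and 2
#' for the rest (the convention of the source accounting tables).
#'
#' @param stats data.frame with columns library, raw_reads, mappable_reads,
#'   mature_mapped_reads, novel_mapped_reads, known_mapped_reads.
#' @return the input with added percentage columns pct_mappable,
#'   pct_mature_mapped, pct_novel_of_mappable, pct_known_of_mappable.
#' @export
mappability_summary <- function(stats) {
  need <- c("library", "raw_reads", "mappable_reads", "mature_mapped_reads",
            "novel_mapped_reads", "known_mapped_reads")
  missing <- setdiff(need, names(stats))
  if (length(missing)) {
    .fail("read-stats table is missing column(s): ",
          paste(missing, collapse = ", "))
  }
  pt <- function(num, den, d) percent_of(num, den, d, method = "truncate")
  stats$pct_mappable <- pt(stats$mappable_reads, stats$raw_reads, 1)
  stats$pct_mature_mapped <-
    pt(stats$mature_mapped_reads, stats$mappable_reads, 2)
  stats$pct_novel_of_mappable <-
    pt(stats$novel_mapped_reads, stats$mappable_reads, 2)
  stats$pct_known_of_mappable <-
    pt(stats$known_mapped_reads, stats$mappable_reads, 2)
  stats
}
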