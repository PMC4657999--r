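# Candidate retention: score cutoff selected by signal-to-noise, mature
# read-count floor, repeat exclusion, other-small-RNA exclusion.

#' Select the detection-score cutoff from a signal-to-noise table
#'
#' Returns the smallest cutoff whose estimated signal-to-noise ratio is
#' strictly greater than `min_snr` (default 10, i.e. a 10:1 ratio).
#'
#' @param snr_table data.frame with columns cutoff, snr (distinct cutoffs).
#' @param min_snr minimum acceptable signal-to-noise ratio.
#' @return the selected cutoff (numeric scalar).
#' @export
select_score_cutoff <- function(snr_table, min_snr = 10) {
  .check(nrow(snr_table) > 0, "SNR table is empty")
  .check(!anyDuplicated(snr_table$cutoff), "SNR cutoffs must be distinct")
  ok <- snr_table$snr > min_snr
  if (!any(ok)) {
    .fail("no admissible cutoff: no score threshold reaches a ",
          "signal-to-noise ratio above ", min_snr, ":1")
  }
  min(snr_table$cutoff[ok])
}

# number of distinct genomic areas among genome self-hits: subject_ids of the
# form "chrom:start-end" are merged when they overlap; anything unparseable
# counts as its own area.
.distinct_hit_areas <- function(subject_ids) {
  m <- regmatches(subject_ids,
                  regexec("^(.+):([0-9]+)-([0-9]+)$", subject_ids))
  parsed <- lengths(m) == 4L
  n_areas <- sum(!parsed & !duplicated(subject_ids[!parsed]))
  if (any(parsed)) {
    iv <- data.frame(
      chrom = vapply(m[parsed], `[`, "", 2L),
      start = as.numeric(vapply(m[parsed], `[`, "", 3L)),
      end = as.numeric(vapply(m[parsed], `[`, "", 4L)))
    for (chr in unique(iv$chrom)) {
      sub <- iv[iv$chrom == chr, , drop = FALSE]
      sub <- sub[order(sub$start, sub$end), , drop = FALSE]
      cur_end <- -Inf
      for (k in seq_len(nrow(sub))) {
        if (sub$start[k] >= cur_end) n_areas <- n_areas + 1L
        cur_end <- max(cur_end, sub$end[k])
      }
    }
  }
  n_areas
}

#' Apply the candidate retention filters
#'
#' Drops candidates in a fixed order, recording the first matching reason:
#' 1. `low_score`: novel precursors (is_known FALSE) with score below the
#'    cutoff; known precursors are exempt from this rule only.
#' 2. `low_count`: precursors none of whose mature forms reaches `min_count`
#'    reads in total across libraries.
#' 3. `repeat`: precursors with more than `max_genome_hits` genome self-hits
#'    at E-value below `genome_evalue` landing on distinct genomic areas
#'    (likely repeated sequences).
#' 4. `other_ncrna`: precursors with any Rfam/RefSeq-RNA hit at E-value below
#'    `genome_evalue` (snRNA/snoRNA/tRNA look-alikes).
#'
#' @param precursors precursor table (one row per mature form).
#' @param hits homology-hit table (may be empty).
#' @param score_cutoff detection-score cutoff (e.g. from
#'   [select_score_cutoff()]).
#' @param min_count mature read-count floor (default 10).
#' @param max_genome_hits maximum tolerated distinct genome self-hit areas
#'   (default 5; "more than five" drops).
#' @param genome_evalue significance threshold for rules 3 and 4
#'   (default 2e-08).
#' @return list with `kept` (character ids) and `dropped` (named character
#'   vector id -> reason).
#' @export
apply_candidate_filters <- function(precursors, hits = NULL,
                                    score_cutoff,
                                    min_count = 10L,
                                    max_genome_hits = 5L,
                                    genome_evalue = 2e-08) {
  .check(min_count >= 0 && max_genome_hits >= 0 && genome_evalue > 0,
         "filter thresholds must be nonnegative (E-value positive)")
  if (is.null(hits)) {
    hits <- data.frame(query_id = character(), subject_id = character(),
                       subject_species = character(), evalue = numeric(),
                       db = character(), stringsAsFactors = FALSE)
  }
  libs <- library_cols(precursors)
  plev <- precursor_level(precursors)
  totals <- rowSums(precursors[, libs, drop = FALSE])
  # per precursor: does any mature form reach min_count in total?
  max_mature_total <- vapply(plev$id, function(id) {
    sel <- precursors$id == id
    if (!any(sel)) 0 else max(totals[sel])
  }, 0)

  dropped <- character(0)
  reason_of <- function(i) {
    id <- plev$id[i]
    if (!plev$is_known[i] && plev$score[i] < score_cutoff) return("low_score")
    if (max_mature_total[[id]] < min_count) return("low_count")
    h <- hits[hits$query_id == id, , drop = FALSE]
    g <- h[h$db == "genome_self" & h$evalue < genome_evalue, , drop = FALSE]
    if (nrow(g) && .distinct_hit_areas(g$subject_id) > max_genome_hits) {
      return("repeat")
    }
    if (any(h$db == "rfam_refseq" & h$evalue < genome_evalue)) {
      return("other_ncrna")
    }
    NA_character_
  }
  reasons <- vapply(seq_len(nrow(plev)), reason_of, "")
  dropped <- stats::setNames(reasons[!is.na(reasons)],
                             plev$id[!is.na(reasons)])
  list(kept = plev$id[is.na(reasons)], dropped = dropped)
}

#' Write a filter report TSV (id, status, reason)
#'
#' @param report list from [apply_candidate_filters()].
#' @param path output path.
#' @return path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  tbl <- rbind(
    data.frame(id = report$kept, status = "kept", reason = "",
               stringsAsFactors = FALSE),
    data.frame(id = names(report$dropped), status = "dropped",
               reason = unname(report$dropped), stringsAsFactors = FALSE))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
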