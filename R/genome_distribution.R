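# Library specificity, genomic cluster detection, per-chromosome counts and
# densities.

#' Classify precursors and matures by library specificity
#'
#' A precursor is present in a library when any of its mature forms reaches
#' `min_count` reads there; a mature form is present when its own count does.
#' Present items fall in exactly one of `<A>_only`, `<B>_only`, `both` for
#' the ordered library pair; items absent from both libraries are excluded
#' and reported.
#'
#' @param precursors precursor table.
#' @param libraries ordered pair of library labels.
#' @param min_count presence threshold (reads, default 10).
#' @return list with `precursor_calls` (precursor_id, class),
#'   `mature_calls` (precursor_id, arm, class), `totals` (data.frame with
#'   rows precursors/matures and the three class columns plus total) and
#'   `excluded` (ids absent from both libraries).
#' @export
classify_specificity <- function(precursors, libraries, min_count = 10L) {
  .check(length(libraries) == 2L, "libraries must be an ordered pair")
  missing <- setdiff(libraries, library_cols(precursors))
  if (length(missing)) {
    .fail("unknown library label(s): ", paste(missing, collapse = ", "))
  }
  a <- libraries[1L]; b <- libraries[2L]
  classes <- c(paste0(a, "_only"), paste0(b, "_only"), "both")
  in_a <- precursors[[a]] >= min_count
  in_b <- precursors[[b]] >= min_count
  mat_class <- ifelse(in_a & in_b, "both",
                      ifelse(in_a, classes[1L],
                             ifelse(in_b, classes[2L], NA_character_)))
  mature_calls <- data.frame(precursor_id = precursors$id,
                             arm = precursors$arm, class = mat_class,
                             stringsAsFactors = FALSE)
  ids <- unique(precursors$id)
  p_a <- vapply(ids, function(id) any(in_a[precursors$id == id]), TRUE)
  p_b <- vapply(ids, function(id) any(in_b[precursors$id == id]), TRUE)
  p_class <- ifelse(p_a & p_b, "both",
                    ifelse(p_a, classes[1L],
                           ifelse(p_b, classes[2L], NA_character_)))
  precursor_calls <- data.frame(precursor_id = ids, class = p_class,
                                stringsAsFactors = FALSE)
  excluded <- ids[is.na(p_class)]
  count_classes <- function(x) {
    n <- vapply(classes, function(cc) sum(x == cc, na.rm = TRUE), 0L)
    c(n, total = sum(n))
  }
  totals <- rbind(precursors = count_classes(p_class),
                  matures = count_classes(mat_class))
  list(precursor_calls = precursor_calls[!is.na(p_class), , drop = FALSE],
       mature_calls = mature_calls[!is.na(mat_class), , drop = FALSE],
       totals = as.data.frame(totals),
       excluded = excluded)
}

#' Detect genomic clusters of precursors
#'
#' Precursors are sorted by (chromosome, strand, start) and chained while the
#' gap between the next start and the running maximum end of the chain is
#' below `max_gap`. With non-overlapping precursors this is the inter-miRNA
#' boundary gap next.start - previous.end; measuring from the running
#' envelope additionally makes the chains equal to the transitive closure of
#' the pairwise gap relation when precursors overlap or nest. Maximal chains
#' of two or more members are clusters.
#'
#' @param precursors precursor table.
#' @param max_gap maximum inter-precursor gap in bp (default 10000; gaps must
#'   be strictly smaller).
#' @param include_known include known precursors alongside novel ones
#'   (default TRUE).
#' @return data.frame: cluster_id, chrom, strand, start, end, n_members and a
#'   `members` list-column (ids ordered by start).
#' @export
detect_clusters <- function(precursors, max_gap = 10000L,
                            include_known = TRUE) {
  if (anyDuplicated(paste(precursors$id, precursors$arm))) {
    .fail("duplicate precursor ids in input")
  }
  plev <- precursor_level(precursors)
  if (!include_known) plev <- plev[!plev$is_known, , drop = FALSE]
  plev <- plev[order(plev$chrom, plev$strand, plev$start, plev$end,
                     plev$id), , drop = FALSE]
  clusters <- list()
  open <- NULL  # current chain: list(ids, chrom, strand, start, env_end)
  flush <- function() {
    if (!is.null(open) && length(open$ids) >= 2L) {
      clusters[[length(clusters) + 1L]] <<- open
    }
    open <<- NULL
  }
  for (i in seq_len(nrow(plev))) {
    row <- plev[i, ]
    if (!is.null(open) &&
        open$chrom == row$chrom && open$strand == row$strand &&
        row$start - open$env_end < max_gap) {
      open$ids <- c(open$ids, row$id)
      open$env_end <- max(open$env_end, row$end)
    } else {
      flush()
      open <- list(ids = row$id, chrom = row$chrom, strand = row$strand,
                   start = row$start, env_end = row$end)
    }
  }
  flush()
  if (!length(clusters)) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      members = I(list())))
  }
  out <- data.frame(
    cluster_id = sprintf("cluster_%03d", seq_along(clusters)),
    chrom = vapply(clusters, `[[`, "", "chrom"),
    strand = vapply(clusters, `[[`, "", "strand"),
    start = vapply(clusters, function(x) as.integer(x$start), 0L),
    end = vapply(clusters, function(x) as.integer(x$env_end), 0L),
    n_members = vapply(clusters, function(x) length(x$ids), 0L),
    stringsAsFactors = FALSE)
  out$members <- lapply(clusters, `[[`, "ids")
  out
}

#' Per-chromosome miRNA counts and density
#'
#' Counts precursors per chromosome split by known/novel, and computes the
#' density as miRNAs per Mbp (total count divided by chromosome length in
#' Mbp). Densities are reported unrounded together with the conventional
#' 2-decimal rendering. Every chromosome of `chrom_lengths` appears (zero
#' counts where empty); a precursor on a chromosome missing from
#' `chrom_lengths` is an error.
#'
#' @param precursors precursor table.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @return data.frame: chrom, length_bp, known, novel, total, density,
#'   density_2dp.
#' @export
chromosome_summary <- function(precursors, chrom_lengths) {
  plev <- precursor_level(precursors)
  unknown <- setdiff(unique(plev$chrom), names(chrom_lengths))
  if (length(unknown)) {
    .fail("chromosome(s) missing from length table: ",
          paste(unknown, collapse = ", "))
  }
  chroms <- names(chrom_lengths)
  known <- vapply(chroms, function(c)
    sum(plev$chrom == c & plev$is_known), 0L)
  novel <- vapply(chroms, function(c)
    sum(plev$chrom == c & !plev$is_known), 0L)
  total <- known + novel
  density <- total / (as.numeric(chrom_lengths) / 1e6)
  data.frame(chrom = chroms, length_bp = as.numeric(chrom_lengths),
             known = known, novel = novel, total = total,
             density = density, density_2dp = round_half_up(density, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
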