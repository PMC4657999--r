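# Expressed arms, dominant arm per library, arm switches, and grouping of
# precursors encoding an identical mature sequence.

#' Arm expression profile per precursor and library
#'
#' An arm is expressed in a library when its mature read count reaches
#' `min_count` (default 10; set `strict = TRUE` for a strictly-greater rule).
#' The dominant arm is the one with the strictly greater count among the
#' expressed arms; an exact tie goes to 5p. The switch flag is set when both
#' libraries have a dominant arm and they differ.
#'
#' @param precursors precursor table.
#' @param libraries ordered pair of library labels.
#' @param min_count expression threshold (reads).
#' @param strict if TRUE, require count > min_count instead of >=.
#' @return data.frame with one row per precursor: precursor_id, then per
#'   library `expressed_<lib>` (comma-joined arms, "" if none) and
#'   `dominant_<lib>` (NA if no arm expressed), plus `switch_flag`.
#' @export
arm_profile <- function(precursors, libraries, min_count = 10L,
                        strict = FALSE) {
  .check(length(libraries) == 2L, "libraries must be an ordered pair")
  missing <- setdiff(libraries, library_cols(precursors))
  if (length(missing)) {
    .fail("unknown library label(s): ", paste(missing, collapse = ", "))
  }
  ids <- unique(precursors$id)
  count_of <- function(id, arm, lib) {
    sel <- precursors$id == id & precursors$arm == arm
    if (any(sel)) precursors[[lib]][which(sel)[1L]] else 0L
  }
  expressed <- function(cnt) if (strict) cnt > min_count else cnt >= min_count
  out <- data.frame(precursor_id = ids, stringsAsFactors = FALSE)
  dom <- matrix(NA_character_, nrow = length(ids), ncol = 2L)
  for (j in 1:2) {
    lib <- libraries[j]
    c5 <- vapply(ids, count_of, 0L, arm = "5p", lib = lib)
    c3 <- vapply(ids, count_of, 0L, arm = "3p", lib = lib)
    e5 <- expressed(c5); e3 <- expressed(c3)
    out[[paste0("expressed_", lib)]] <-
      ifelse(e5 & e3, "5p,3p", ifelse(e5, "5p", ifelse(e3, "3p", "")))
    dom[, j] <- ifelse(e5 & e3, ifelse(c3 > c5, "3p", "5p"),
                       ifelse(e5, "5p", ifelse(e3, "3p", NA_character_)))
    out[[paste0("dominant_", lib)]] <- dom[, j]
  }
  out$switch_flag <- !is.na(dom[, 1L]) & !is.na(dom[, 2L]) &
    dom[, 1L] != dom[, 2L]
  out
}

#' Group precursors encoding an identical mature sequence
#'
#' Exact-sequence grouping on canonicalized (uppercase U-form) mature
#' sequences: a partition of the distinct mature sequences, invariant under
#' input permutation. Precursors with two mature forms contribute to two
#' groups.
#'
#' @param precursors precursor table.
#' @return named list: mature sequence -> sorted character vector of
#'   precursor ids encoding it.
#' @export
group_same_mature <- function(precursors) {
  if (!nrow(precursors)) return(stats::setNames(list(), character(0)))
  seqs <- canonical_rna(precursors$mature_seq)
  groups <- lapply(split(precursors$id, seqs), function(x) sort(unique(x)))
  groups[order(names(groups))]
}

#' Duplicate-mature groups with per-library presence
#'
#' Restricts [group_same_mature()] to groups of two or more precursors and
#' reports, for each member, the libraries in which that mature is present
#' (count >= `min_count`).
#'
#' @param precursors precursor table.
#' @param min_count presence threshold (reads).
#' @return data.frame: mature_seq, precursor_id, libraries_present
#'   (comma-joined).
#' @export
duplicate_mature_groups <- function(precursors, min_count = 10L) {
  groups <- group_same_mature(precursors)
  groups <- groups[lengths(groups) >= 2L]
  libs <- library_cols(precursors)
  rows <- lapply(names(groups), function(s) {
    ids <- groups[[s]]
    pres <- vapply(ids, function(id) {
      sel <- precursors$id == id & canonical_rna(precursors$mature_seq) == s
      have <- libs[vapply(libs, function(l)
        any(precursors[[l]][sel] >= min_count), TRUE)]
      paste(have, collapse = ",")
    }, "")
    data.frame(mature_seq = s, precursor_id = ids,
               libraries_present = pres, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(mature_seq = character(), precursor_id = character(),
                      libraries_present = character()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
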