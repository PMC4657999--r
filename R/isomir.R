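# isomiR taxonomy: classify aligned reads against their reference mature,
# call dominant forms, summarize category distributions.

.ISOMIR_CATEGORIES <- c("reference", "templated_5p", "nontemplated_5p",
                        "templated_3p", "nontemplated_3p",
                        "both_ends_templated", "both_ends_nontemplated",
                        "polymorphic")

#' isomiR category levels
#'
#' @return character vector of the eight exclusive categories.
#' @export
isomir_categories <- function() .ISOMIR_CATEGORIES

#' Classify one aligned read against a reference mature
#'
#' End offsets are computed relative to the mature interval on the precursor
#' (five_prime_offset = read start - mature start, negative meaning a 5'
#' extension; three_prime_offset = read end - mature end, positive meaning a
#' 3' extension). An extension end is non-templated iff at least one of its
#' extending bases differs from the precursor sequence at the aligned
#' position (or falls off the precursor); truncations and shifts within the
#' precursor are always templated. Internal mismatches against the precursor
#' body (excluding non-templated extension bases) are substitutions.
#'
#' Category precedence (categories are exclusive):
#' 1. any substitution -> `polymorphic`;
#' 2. both ends variant -> `both_ends_nontemplated` if either end is
#'    non-templated, else `both_ends_templated`;
#' 3. one end variant -> `templated_5p` / `nontemplated_5p` /
#'    `templated_3p` / `nontemplated_3p`;
#' 4. otherwise `reference`.
#'
#' Reads that do not overlap the mature interval (loop/star-only reads) get
#' category `"unassigned"` and are excluded from distributions.
#'
#' Mismatches are derived by direct comparison of the read to the precursor
#' sequence, so a mismatch annotation in the read table is not required.
#'
#' @param read_start 0-based offset of read base 1 on the precursor (may be
#'   negative for an upstream overhang).
#' @param read_seq read sequence.
#' @param mature_offset 0-based start of the mature on the precursor.
#' @param mature_length mature reference length.
#' @param precursor_seq precursor hairpin sequence.
#' @return list with category, five_prime_offset, three_prime_offset,
#'   substitutions (integer, 1-based mature-relative positions) and
#'   seed_affected (TRUE iff the 5' end is shifted or a substitution falls in
#'   seed positions 2-8).
#' @export
classify_read <- function(read_start, read_seq, mature_offset, mature_length,
                          precursor_seq) {
  read_seq <- canonical_rna(read_seq)
  precursor_seq <- canonical_rna(precursor_seq)
  L <- nchar(read_seq)
  plen <- nchar(precursor_seq)
  m0 <- mature_offset
  m1 <- mature_offset + mature_length
  s0 <- read_start
  s1 <- read_start + L
  if (s0 >= m1 || s1 <= m0) {
    return(list(category = "unassigned", five_prime_offset = NA_integer_,
                three_prime_offset = NA_integer_,
                substitutions = integer(0), seed_affected = NA))
  }
  off5 <- s0 - m0
  off3 <- s1 - m1

  rb <- strsplit(read_seq, "")[[1]]
  ppos <- s0 + seq_len(L) - 1L                      # 0-based precursor pos
  on_prec <- ppos >= 0L & ppos < plen
  pb <- rep(NA_character_, L)
  if (any(on_prec)) {
    pb[on_prec] <- strsplit(substr(precursor_seq, min(ppos[on_prec]) + 1L,
                                   max(ppos[on_prec]) + 1L), "")[[1]]
  }
  mismatch <- !on_prec | (rb != pb)

  ext5 <- if (off5 < 0L) seq_len(-off5) else integer(0)
  ext3 <- if (off3 > 0L) seq.int(L - off3 + 1L, L) else integer(0)
  nt5 <- length(ext5) > 0L && any(mismatch[ext5])
  nt3 <- length(ext3) > 0L && any(mismatch[ext3])

  body <- setdiff(which(mismatch & on_prec), c(ext5, ext3))
  subs <- sort(ppos[body] - m0 + 1L)                # 1-based mature-relative

  category <- if (length(subs)) {
    "polymorphic"
  } else if (off5 != 0L && off3 != 0L) {
    if (nt5 || nt3) "both_ends_nontemplated" else "both_ends_templated"
  } else if (off5 != 0L) {
    if (nt5) "nontemplated_5p" else "templated_5p"
  } else if (off3 != 0L) {
    if (nt3) "nontemplated_3p" else "templated_3p"
  } else {
    "reference"
  }
  list(category = category,
       five_prime_offset = off5,
       three_prime_offset = off3,
       substitutions = subs,
       seed_affected = off5 != 0L || any(subs >= 2L & subs <= 8L))
}

# pick, per read, the mature form it overlaps most (ties to 5p);
# returns the precursor-table row index or NA
.match_mature <- function(read_start, read_len, matures) {
  ov <- pmin(read_start + read_len, matures$mature_offset +
               nchar(matures$mature_seq)) -
    pmax(read_start, matures$mature_offset)
  ov[ov < 0] <- 0
  if (all(ov <= 0)) return(NA_integer_)
  top <- which(ov == max(ov))
  if (length(top) > 1L) top <- top[matures$arm[top] == "5p"][1L]
  top[1L]
}

#' Classify every read of a stack table
#'
#' Each read is assigned to the mature form of its precursor that it overlaps
#' most (ties to 5p) and classified with [classify_read()]. Reads overlapping
#' no mature form (loop/star-only) are kept with category "unassigned".
#'
#' @param stacks read-stack data.frame (see [read_stack_table()]).
#' @param precursors precursor table.
#' @return the stack table with added columns arm, category,
#'   five_prime_offset, three_prime_offset, substitutions (canonical string
#'   form, ";"-joined), seed_affected.
#' @export
classify_stacks <- function(stacks, precursors) {
  n <- nrow(stacks)
  out <- stacks
  out$arm <- rep(NA_character_, n)
  out$category <- rep(NA_character_, n)
  out$five_prime_offset <- rep(NA_integer_, n)
  out$three_prime_offset <- rep(NA_integer_, n)
  out$substitutions <- rep("", n)
  out$seed_affected <- rep(NA, n)
  if (!n) return(out)
  prec_split <- split(seq_len(nrow(precursors)), precursors$id)
  seq_by_id <- vapply(prec_split, function(i) precursors$sequence[i[1L]], "")
  for (i in seq_len(n)) {
    rows <- prec_split[[stacks$precursor_id[i]]]
    if (is.null(rows)) .fail("read references unknown precursor: ",
                             stacks$precursor_id[i])
    mat <- precursors[rows, , drop = FALSE]
    j <- .match_mature(stacks$start[i], nchar(stacks$sequence[i]), mat)
    if (is.na(j)) {
      out$category[i] <- "unassigned"
      next
    }
    cl <- classify_read(stacks$start[i], stacks$sequence[i],
                        mat$mature_offset[j], nchar(mat$mature_seq[j]),
                        seq_by_id[[stacks$precursor_id[i]]])
    out$arm[i] <- mat$arm[j]
    out$category[i] <- cl$category
    out$five_prime_offset[i] <- cl$five_prime_offset
    out$three_prime_offset[i] <- cl$three_prime_offset
    out$substitutions[i] <- paste(cl$substitutions, collapse = ";")
    out$seed_affected[i] <- cl$seed_affected
  }
  out
}

#' Dominant mature form of one precursor arm
#'
#' Among the reads of a stack overlapping the given mature, variants (unique
#' read start + sequence) are ranked by summed count across libraries; the
#' top variant's classification and sequence are returned. Ties are broken in
#' favor of the reference form, then by lexicographically smallest sequence.
#'
#' @param stack read rows for one precursor.
#' @param mature_offset,mature_length,precursor_seq as in [classify_read()].
#' @return list with sequence, start, count, and the classification fields of
#'   [classify_read()].
#' @export
dominant_form <- function(stack, mature_offset, mature_length,
                          precursor_seq) {
  if (!nrow(stack)) .fail("empty read stack: no dominant form")
  calls <- lapply(seq_len(nrow(stack)), function(i)
    classify_read(stack$start[i], stack$sequence[i], mature_offset,
                  mature_length, precursor_seq))
  keep <- vapply(calls, function(x) x$category != "unassigned", TRUE)
  if (!any(keep)) .fail("no reads overlap the mature form")
  stack <- stack[keep, , drop = FALSE]
  calls <- calls[keep]
  key <- paste(stack$start, stack$sequence, sep = "/")
  tot <- tapply(stack$count, key, sum)
  first <- !duplicated(key)
  variants <- data.frame(key = key[first], start = stack$start[first],
                         sequence = stack$sequence[first],
                         stringsAsFactors = FALSE)
  variants$count <- as.integer(tot[variants$key])
  variants$is_ref <- vapply(which(first), function(i)
    calls[[i]]$category == "reference", TRUE)
  ord <- order(-variants$count, !variants$is_ref, variants$sequence)
  top <- variants[ord[1L], ]
  cl <- calls[[which(first)[ord[1L]]]]
  c(list(sequence = top$sequence, start = top$start, count = top$count), cl)
}

#' Summarize isomiR category distributions
#'
#' Count-weighted fractions per category, per library and pooled over
#' libraries. Unassigned reads are excluded (their count is reported).
#'
#' @param classified stack table from [classify_stacks()].
#' @return list with `fractions` (data.frame: library incl. "pooled",
#'   one column per category), `counts` (same shape, read counts) and
#'   `unassigned_reads` (total excluded count).
#' @export
summarize_isomirs <- function(classified) {
  cats <- .ISOMIR_CATEGORIES
  keep <- !is.na(classified$category) & classified$category != "unassigned"
  unass <- sum(classified$count[!keep])
  cl <- classified[keep, , drop = FALSE]
  if (!nrow(cl)) {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cats),
                                  dimnames = list(NULL, cats)))
    return(list(fractions = cbind(library = character(0), empty),
                counts = cbind(library = character(0), empty),
                unassigned_reads = unass))
  }
  libs <- sort(unique(cl$library))
  count_row <- function(sel) {
    vapply(cats, function(cc) sum(cl$count[sel & cl$category == cc]), 0)
  }
  counts <- t(vapply(libs, function(l) count_row(cl$library == l),
                     numeric(length(cats))))
  counts <- rbind(counts, pooled = count_row(rep(TRUE, nrow(cl))))
  fractions <- counts / rowSums(counts)
  list(
    fractions = data.frame(library = c(libs, "pooled"), fractions,
                           row.names = NULL, check.names = FALSE),
    counts = data.frame(library = c(libs, "pooled"), counts,
                        row.names = NULL, check.names = FALSE),
    unassigned_reads = unass)
}
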