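# Canonical file dialects and validated containers shared by all stages.
#
# Coordinates are 0-based half-open throughout ([start, end)); BED is emitted
# natively and any 1-based conversion happens only at the writer boundary.
#
# The precursor table is the central container: one row per mature form, with
# precursor-level fields repeated across the rows sharing an id.
# Canonical columns:
#   id chrom start end strand score is_known sequence arm mature_seq
#   mature_offset <one count column per library>

.PREC_FIXED_COLS <- c("id", "chrom", "start", "end", "strand", "score",
                      "is_known", "sequence", "arm", "mature_seq",
                      "mature_offset")

#' Library (count) columns of a precursor table
#'
#' @param tbl precursor table data.frame.
#' @return character vector of library labels (columns after the fixed ones).
#' @export
library_cols <- function(tbl) {
  setdiff(names(tbl), .PREC_FIXED_COLS)
}

#' Validate a precursor table
#'
#' Checks the canonical schema and all type invariants: coordinates 0-based
#' half-open with start < end, strand in {+,-}, hairpin length equal to the
#' interval length, mature length in [15, 32], mature contained in the
#' precursor, nonnegative integer counts, and per-id consistency of the
#' precursor-level fields. Sequences are canonicalized to uppercase U-form.
#'
#' @param tbl data.frame in the canonical layout.
#' @return the validated table (sequences canonicalized), invisibly classed.
#' @export
validate_precursor_table <- function(tbl) {
  missing <- setdiff(.PREC_FIXED_COLS, names(tbl))
  if (length(missing)) {
    .fail("precursor table is missing column(s): ",
          paste(missing, collapse = ", "))
  }
  libs <- library_cols(tbl)
  if (!length(libs)) .fail("precursor table has no library count columns")
  if (nrow(tbl) == 0L) return(tbl)

  tbl$start <- as.integer(tbl$start)
  tbl$end <- as.integer(tbl$end)
  tbl$mature_offset <- as.integer(tbl$mature_offset)
  tbl$score <- as.numeric(tbl$score)
  tbl$is_known <- as.logical(tbl$is_known)
  tbl$sequence <- canonical_rna(tbl$sequence)
  tbl$mature_seq <- canonical_rna(tbl$mature_seq)

  row_fail <- function(cond, what) {
    if (any(cond)) {
      .fail("invalid precursor row(s) [", what, "]: id ",
            paste(unique(tbl$id[cond]), collapse = ", "))
    }
  }
  row_fail(!(tbl$start >= 0L & tbl$start < tbl$end), "need 0 <= start < end")
  row_fail(!tbl$strand %in% c("+", "-"), "strand must be + or -")
  row_fail(nchar(tbl$sequence) != tbl$end - tbl$start,
           "sequence length != interval length")
  ml <- nchar(tbl$mature_seq)
  row_fail(!(ml >= 15L & ml <= 32L), "mature length outside [15, 32]")
  row_fail(!tbl$arm %in% c("5p", "3p"), "arm must be 5p or 3p")
  row_fail(tbl$mature_offset < 0L |
             tbl$mature_offset + ml > nchar(tbl$sequence),
           "mature form not contained in precursor")
  for (lib in libs) {
    tbl[[lib]] <- as.integer(tbl[[lib]])
    row_fail(is.na(tbl[[lib]]) | tbl[[lib]] < 0L,
             paste0("negative/missing count in library ", lib))
  }
  # per-id consistency of precursor-level fields; distinct arms per id
  for (id in unique(tbl$id)) {
    sub <- tbl[tbl$id == id, , drop = FALSE]
    for (col in c("chrom", "start", "end", "strand", "score", "is_known",
                  "sequence")) {
      if (length(unique(sub[[col]])) != 1L) {
        .fail("inconsistent precursor-level field '", col, "' for id ", id)
      }
    }
    if (anyDuplicated(sub$arm)) .fail("duplicated arm for id ", id)
  }
  tbl
}

#' Read a canonical precursor TSV
#'
#' @param path file path.
#' @return validated precursor table (one row per mature form).
#' @export
read_precursor_table <- function(path) {
  if (!file.exists(path)) .fail("no such file: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_precursor_table(tbl)
}

#' Write a canonical precursor TSV
#'
#' @param tbl precursor table.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_precursor_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a precursor table to one row per precursor
#'
#' Keeps the precursor-level fields and adds `n_mature`.
#'
#' @param tbl precursor table.
#' @return data.frame with one row per id, in first-appearance order.
#' @export
precursor_level <- function(tbl) {
  first <- !duplicated(tbl$id)
  out <- tbl[first, c("id", "chrom", "start", "end", "strand", "score",
                      "is_known", "sequence"), drop = FALSE]
  out$n_mature <- as.integer(table(tbl$id)[out$id])
  rownames(out) <- NULL
  out
}

# ---- read stacks ----------------------------------------------------------

#' Parse a semicolon-joined mismatch annotation ("pos:base;pos:base")
#'
#' @param x character vector of annotations ("" or NA for none).
#' @return list of data.frames with columns pos (1-based read position) and
#'   base (read base).
#' @export
parse_mismatches <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(pos = integer(), base = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    .check(lengths(parts) == 2L, "malformed mismatch annotation: ", s)
    data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
               base = canonical_rna(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  })
}

#' Format mismatch annotations back to the canonical string form
#'
#' @param mm list of data.frames as returned by [parse_mismatches()].
#' @return character vector.
#' @export
format_mismatches <- function(mm) {
  vapply(mm, function(d) {
    if (!nrow(d)) return("")
    paste(paste0(d$pos, ":", d$base), collapse = ";")
  }, "")
}

#' Read a canonical read-stack TSV
#'
#' Columns: precursor_id, library, start, sequence, count, mismatches
#' (semicolon-joined pos:base, empty for none). `start` is the 0-based offset
#' of read base 1 on the precursor and may be negative (upstream overhang).
#'
#' @param path file path.
#' @return data.frame of aligned reads.
#' @export
read_stack_table <- function(path) {
  if (!file.exists(path)) .fail("no such file: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(mismatches = "character"))
  need <- c("precursor_id", "library", "start", "sequence", "count",
            "mismatches")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    .fail("read-stack table is missing column(s): ",
          paste(missing, collapse = ", "))
  }
  tbl$start <- as.integer(tbl$start)
  tbl$count <- as.integer(tbl$count)
  tbl$sequence <- canonical_rna(tbl$sequence)
  tbl$mismatches[is.na(tbl$mismatches)] <- ""
  .check(tbl$count >= 1L, "read counts must be >= 1")
  mm <- parse_mismatches(tbl$mismatches)
  bad <- mapply(function(d, L) any(d$pos < 1L | d$pos > L),
                mm, nchar(tbl$sequence))
  .check(!bad, "mismatch position outside read length")
  tbl
}

#' Write a canonical read-stack TSV
#'
#' @param stacks read-stack data.frame.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_stack_table <- function(stacks, path) {
  utils::write.table(stacks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- homology hits, chrom lengths, SNR ------------------------------------

#' Read a homology-hit TSV (query_id, subject_id, subject_species, evalue, db)
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_homology_table <- function(path) {
  if (!file.exists(path)) .fail("no such file: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_homology_table(tbl)
}

#' Validate a homology-hit table
#'
#' @param tbl data.frame with columns query_id, subject_id, subject_species,
#'   evalue, db.
#' @return the validated table.
#' @export
validate_homology_table <- function(tbl) {
  need <- c("query_id", "subject_id", "subject_species", "evalue", "db")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    .fail("homology table is missing column(s): ",
          paste(missing, collapse = ", "))
  }
  tbl$evalue <- as.numeric(tbl$evalue)
  .check(tbl$evalue > 0, "E-values must be positive")
  .check(tbl$db %in% c("mirbase", "genome_self", "rfam_refseq"),
         "db must be one of mirbase, genome_self, rfam_refseq")
  tbl
}

#' Read a chromosome-length TSV (chrom, length_bp)
#'
#' @param path file path.
#' @return named integer-ish numeric vector of lengths in bp.
#' @export
read_chrom_lengths <- function(path) {
  if (!file.exists(path)) .fail("no such file: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("chrom", "length_bp"), names(tbl))
  if (length(missing)) {
    .fail("chromosome-length table is missing column(s): ",
          paste(missing, collapse = ", "))
  }
  len <- as.numeric(tbl$length_bp)
  .check(len > 0, "chromosome lengths must be positive")
  stats::setNames(len, as.character(tbl$chrom))
}

#' Read a signal-to-noise TSV (cutoff, snr)
#'
#' @param path file path.
#' @return data.frame with numeric cutoff and snr.
#' @export
read_snr_table <- function(path) {
  if (!file.exists(path)) .fail("no such file: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("cutoff", "snr"), names(tbl))
  if (length(missing)) {
    .fail("SNR table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tbl$cutoff <- as.numeric(tbl$cutoff)
  tbl$snr <- as.numeric(tbl$snr)
  .check(tbl$snr > 0, "SNR values must be positive")
  tbl
}

# ---- FASTA ----------------------------------------------------------------

#' Read a FASTA file as a named character vector (U-form)
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(canonical_rna(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# ---- BED ------------------------------------------------------------------

#' Write precursors or clusters as BED6
#'
#' Coordinates pass through unchanged (internal representation is already
#' 0-based half-open). The BED score column is `min(1000, round(score))`,
#' floored at 0; clusters (which carry no score) get 0. The name column is
#' the assigned name when present, else the id.
#'
#' @param items precursor table (one row per precursor used), a
#'   `precursor_level()` data.frame, or a cluster data.frame from
#'   [detect_clusters()].
#' @param path output path.
#' @return path, invisibly.
#' @export
write_bed <- function(items, path) {
  if (nrow(items) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!is.null(items$members)) {  # cluster table
    name <- vapply(items$members, paste, "", collapse = ",")
    if (!is.null(items$name)) name <- items$name
    score <- rep(0L, nrow(items))
  } else {
    items <- items[!duplicated(items$id), , drop = FALSE]
    name <- if (!is.null(items$name)) items$name else items$id
    score <- pmin(1000, pmax(0, round(items$score)))
  }
  bed <- data.frame(chrom = items$chrom, start = items$start,
                    end = items$end, name = name, score = score,
                    strand = items$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
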