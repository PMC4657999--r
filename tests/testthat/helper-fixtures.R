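# Fixture builders and independent brute-force oracles used across tests.

# one precursor-table row; counts given as c(LV = ..., GL = ...)
prec_row <- function(id, arm = "5p", counts = c(LV = 100L, GL = 100L),
                     chrom = "1", start = 1000L, seq_len = 70L,
                     strand = "+", score = 50, is_known = FALSE,
                     sequence = NULL, mature_seq = NULL,
                     mature_offset = 5L, mature_len = 21L) {
  if (is.null(sequence)) {
    ui <- utf8ToInt(id)
    set.seed(sum(ui * seq_along(ui)) + seq_len)  # stable per id
    sequence <- paste(sample(c("A", "C", "G", "U"), seq_len, TRUE),
                      collapse = "")
  }
  if (is.null(mature_seq)) {
    mature_seq <- substr(sequence, mature_offset + 1L,
                         mature_offset + mature_len)
  }
  out <- data.frame(id = id, chrom = chrom, start = start,
                    end = start + nchar(sequence), strand = strand,
                    score = score, is_known = is_known, sequence = sequence,
                    arm = arm, mature_seq = mature_seq,
                    mature_offset = mature_offset, stringsAsFactors = FALSE)
  for (lib in names(counts)) out[[lib]] <- as.integer(counts[[lib]])
  out
}

prec_table <- function(...) {
  tbl <- do.call(rbind, list(...))
  validate_precursor_table(tbl)
}

# a small, fast simulation scenario for unit/property tests
small_config <- function(seed = 11L, ...) {
  sim_config(
    seed = seed,
    class_quotas = c(A_only = 2L, B_only = 3L, both = 4L),
    two_mature_quotas = c(A_only = 1L, B_only = 1L, both = 2L),
    tier_quotas = c(conserved_broad = 3L, conserved_narrow = 2L,
                    conserved_single = 2L, nonconserved = 2L),
    duplicate_pairs = 1L,
    cluster_sizes = c(2L),
    n_chrom = 5L,
    n_known = 4L, known_both = 3L, known_two_mature = 2L,
    decoys = c(low_score = 1L, low_count = 1L, "repeat" = 1L,
               other_ncrna = 1L),
    length_reads_n = 500L,
    ...)
}

# ---- independent oracles --------------------------------------------------

# isomiR oracle: per-base walk over the alignment, written independently of
# classify_read (explicit per-position loop, separate branching).
oracle_classify <- function(read_start, read_seq, mature_offset,
                            mature_length, precursor_seq) {
  L <- nchar(read_seq)
  plen <- nchar(precursor_seq)
  r0 <- read_start                      # 0-based read interval [r0, r1)
  r1 <- read_start + L
  m0 <- mature_offset
  m1 <- mature_offset + mature_length
  if (r1 <= m0 || r0 >= m1) return(list(category = "unassigned"))
  off5 <- r0 - m0
  off3 <- r1 - m1
  base_at <- function(p0) {
    if (p0 < 0 || p0 >= plen) NA_character_
    else substr(precursor_seq, p0 + 1, p0 + 1)
  }
  nt5 <- FALSE; nt3 <- FALSE; subs <- integer(0)
  for (i in seq_len(L)) {
    p <- r0 + i - 1                     # aligned 0-based precursor position
    rb <- substr(read_seq, i, i)
    pb <- base_at(p)
    is_match <- !is.na(pb) && rb == pb
    if (p < m0 && off5 < 0) {           # 5' extension base
      if (!is_match) nt5 <- TRUE
    } else if (p >= m1 && off3 > 0) {   # 3' extension base
      if (!is_match) nt3 <- TRUE
    } else if (!is_match && !is.na(pb)) {
      subs <- c(subs, p - m0 + 1)
    }
  }
  cat <- if (length(subs) > 0) "polymorphic"
  else if (off5 != 0 && off3 != 0) {
    if (nt5 || nt3) "both_ends_nontemplated" else "both_ends_templated"
  } else if (off5 != 0) {
    if (nt5) "nontemplated_5p" else "templated_5p"
  } else if (off3 != 0) {
    if (nt3) "nontemplated_3p" else "templated_3p"
  } else "reference"
  list(category = cat, five_prime_offset = off5, three_prime_offset = off3,
       substitutions = subs,
       seed_affected = off5 != 0 || any(subs >= 2 & subs <= 8))
}

# cluster oracle: transitive closure over all precursor pairs whose boundary
# gap on the same chromosome and strand is below the threshold
oracle_clusters <- function(plev, max_gap) {
  n <- nrow(plev)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (plev$chrom[i] != plev$chrom[j]) next
    if (plev$strand[i] != plev$strand[j]) next
    gap <- max(plev$start[i], plev$start[j]) -
      min(plev$end[i], plev$end[j])
    if (gap < max_gap) adj[i, j] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(plev$id, comp)
  groups <- groups[lengths(groups) >= 2]
  lapply(unname(groups), sort)
}

# naive filter oracle: re-checks every retention rule per candidate
oracle_filter <- function(precursors, hits, cutoff, min_count = 10,
                          max_hits = 5, evalue = 2e-08) {
  libs <- library_cols(precursors)
  plev <- precursor_level(precursors)
  out <- character(0)
  for (i in seq_len(nrow(plev))) {
    id <- plev$id[i]
    reason <- NA
    if (!plev$is_known[i] && plev$score[i] < cutoff) reason <- "low_score"
    if (is.na(reason)) {
      rows <- precursors[precursors$id == id, libs, drop = FALSE]
      if (max(rowSums(rows)) < min_count) reason <- "low_count"
    }
    if (is.na(reason) && !is.null(hits) && nrow(hits)) {
      h <- hits[hits$query_id == id, , drop = FALSE]
      g <- h[h$db == "genome_self" & h$evalue < evalue, , drop = FALSE]
      if (nrow(g) > 0) {
        # count merged areas by parsing chrom:start-end subject ids
        areas <- 0
        parts <- regmatches(g$subject_id,
                            regexec("^(.+):([0-9]+)-([0-9]+)$",
                                    g$subject_id))
        unparsed <- g$subject_id[lengths(parts) != 4]
        areas <- areas + length(unique(unparsed))
        ok <- parts[lengths(parts) == 4]
        if (length(ok)) {
          df <- data.frame(chrom = sapply(ok, `[`, 2),
                           s = as.numeric(sapply(ok, `[`, 3)),
                           e = as.numeric(sapply(ok, `[`, 4)))
          for (ch in unique(df$chrom)) {
            d <- df[df$chrom == ch, ]
            d <- d[order(d$s), ]
            hi <- -Inf
            for (k in seq_len(nrow(d))) {
              if (d$s[k] >= hi) areas <- areas + 1
              hi <- max(hi, d$e[k])
            }
          }
        }
        if (areas > max_hits) reason <- "repeat"
      }
      if (is.na(reason) &&
          any(h$db == "rfam_refseq" & h$evalue < evalue)) {
        reason <- "other_ncrna"
      }
    }
    out[id] <- reason
  }
  out
}

# direct median-of-ratios formula evaluation
oracle_size_factors <- function(mat) {
  mat <- as.matrix(mat)
  keep <- apply(mat, 1, function(r) all(r > 0))
  gm <- apply(mat[keep, , drop = FALSE], 1,
              function(r) prod(r)^(1 / length(r)))
  sapply(seq_len(ncol(mat)), function(j)
    median(mat[keep, j] / gm))
}
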