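# Conservation tiering from homology hit tables and deterministic
# miRBase-style nomenclature.

.TIERS <- c("conserved_broad", "conserved_narrow", "conserved_single",
            "nonconserved")

#' Assign a conservation tier to one candidate
#'
#' Tiers, evaluated in order against miRBase homology hits:
#' * `conserved_broad`: hits from at least 5 distinct species at
#'   E-value < `broad_e`;
#' * `conserved_narrow`: 2-4 distinct species at E-value < `narrow_e`;
#' * `conserved_single`: exactly one species at E-value < `single_e`
#'   (this bucket holds single-species matches such as distant homologs and
#'   the Bos taurus miR-2284/2285 family);
#' * `nonconserved`: otherwise (an empty hit list is valid).
#'
#' @param precursor_id candidate id.
#' @param hits homology-hit table; only `db == "mirbase"` rows are used.
#' @param broad_e,narrow_e,single_e E-value thresholds
#'   (defaults 4e-09, 9e-05, 2e-04).
#' @return list with precursor_id, tier, supporting_species (character).
#' @export
assign_tier <- function(precursor_id, hits,
                        broad_e = 4e-09, narrow_e = 9e-05,
                        single_e = 2e-04) {
  h <- hits[hits$db == "mirbase" & hits$query_id == precursor_id, ,
            drop = FALSE]
  sp_broad <- unique(h$subject_species[h$evalue < broad_e])
  if (length(sp_broad) >= 5L) {
    return(list(precursor_id = precursor_id, tier = "conserved_broad",
                supporting_species = sort(sp_broad)))
  }
  sp_narrow <- unique(h$subject_species[h$evalue < narrow_e])
  if (length(sp_narrow) >= 2L && length(sp_narrow) <= 4L) {
    return(list(precursor_id = precursor_id, tier = "conserved_narrow",
                supporting_species = sort(sp_narrow)))
  }
  sp_single <- unique(h$subject_species[h$evalue < single_e])
  if (length(sp_single) == 1L) {
    return(list(precursor_id = precursor_id, tier = "conserved_single",
                supporting_species = sp_single))
  }
  list(precursor_id = precursor_id, tier = "nonconserved",
       supporting_species = character(0))
}

#' Assign conservation tiers to many candidates
#'
#' @param ids character vector of candidate ids.
#' @inheritParams assign_tier
#' @return data.frame with columns precursor_id, tier, n_species, and a
#'   `supporting_species` list-column.
#' @export
assign_tiers <- function(ids, hits, broad_e = 4e-09, narrow_e = 9e-05,
                         single_e = 2e-04) {
  calls <- lapply(ids, assign_tier, hits = hits, broad_e = broad_e,
                  narrow_e = narrow_e, single_e = single_e)
  out <- data.frame(
    precursor_id = ids,
    tier = vapply(calls, `[[`, "", "tier"),
    n_species = vapply(calls, function(x) length(x$supporting_species), 0L),
    stringsAsFactors = FALSE)
  out$supporting_species <- lapply(calls, `[[`, "supporting_species")
  out
}

#' Seed-weighted ungapped similarity between two mature sequences
#'
#' Best-offset ungapped comparison; at the best offset the score is
#' 2 x (matching bases at query positions 2-8, the seed) + matching bases
#' elsewhere. Used to pick the closest homolog mature for naming; isolated
#' here so it can be swapped for an alignment-based score.
#'
#' @param query,subject mature sequences (U-form).
#' @return integer similarity score (0 if no overlap).
#' @export
seed_similarity <- function(query, subject) {
  q <- strsplit(canonical_rna(query), "")[[1]]
  s <- strsplit(canonical_rna(subject), "")[[1]]
  nq <- length(q); ns <- length(s)
  best <- 0L
  for (off in seq(-ns + 1L, nq - 1L)) {  # subject position 1 at query off+1
    qpos <- seq_len(nq)
    spos <- qpos - off
    keep <- spos >= 1L & spos <= ns
    if (!any(keep)) next
    match <- q[qpos[keep]] == s[spos[keep]]
    seed <- qpos[keep] >= 2L & qpos[keep] <= 8L
    score <- 2L * sum(match & seed) + sum(match & !seed)
    if (score > best) best <- score
  }
  best
}

# strip species prefix and arm suffix from a miRBase-style name
.base_name <- function(name) {
  x <- sub("^[a-z]{3,4}-", "", name)
  sub("-(5p|3p)$", "", x)
}

# representative mature per precursor: highest total count, ties to 5p
.representative_matures <- function(precursors) {
  libs <- library_cols(precursors)
  tot <- rowSums(precursors[, libs, drop = FALSE])
  ord <- order(precursors$id, -tot, precursors$arm != "5p")
  p <- precursors[ord, , drop = FALSE]
  p[!duplicated(p$id), c("id", "chrom", "start", "mature_seq"),
    drop = FALSE]
}

# coordinate order for deterministic tie-breaks
.coord_order <- function(df) order(df$chrom, df$start, df$id)

#' Assign deterministic names to kept candidates
#'
#' Conserved candidates are named "oar-" + the base name of their closest
#' homolog mature (closest under [seed_similarity()] on the candidate's most
#' abundant mature). Collisions are resolved deterministically:
#' * precursors proposing the same name with *different* mature sequences get
#'   a progressive letter (a, b, ...) in genomic-coordinate order
#'   (e.g. oar-miR-2285la, oar-miR-2285lb);
#' * distinct precursors encoding an *identical* mature sequence share the
#'   name with suffixes -1, -2 in coordinate order.
#'
#' Nonconserved candidates receive provisional names oar-miR-N1 ... oar-miR-Nk
#' in coordinate order, with identical-mature groups sharing one number plus
#' -1/-2 suffixes (oar-miR-N14-1, oar-miR-N14-2).
#'
#' @param precursors precursor table restricted to kept candidates.
#' @param tiers tier data.frame from [assign_tiers()].
#' @param homologs homolog mature catalog: named character vector of mature
#'   sequences with miRBase-style names (e.g. "bta-miR-2285l"), as read from
#'   FASTA by [read_fasta_seqs()].
#' @param existing character vector of names already in use (never reused).
#' @return data.frame precursor_id, name.
#' @export
assign_names <- function(precursors, tiers, homologs,
                         existing = character(0)) {
  rep_mat <- .representative_matures(precursors)
  rep_mat <- merge(rep_mat, tiers[, c("precursor_id", "tier")],
                   by.x = "id", by.y = "precursor_id", sort = FALSE)
  conserved <- rep_mat[rep_mat$tier != "nonconserved", , drop = FALSE]
  noncons <- rep_mat[rep_mat$tier == "nonconserved", , drop = FALSE]
  if (nrow(conserved) && !length(homologs)) {
    .fail("homolog catalog is empty but conserved candidates are present")
  }
  used <- existing
  result <- character(0)

  claim <- function(name) {
    # letter-suffix fallback if a finalized name is somehow taken
    cand <- name
    letters_i <- 1L
    while (cand %in% used) {
      cand <- paste0(name, letters[letters_i])
      letters_i <- letters_i + 1L
    }
    used <<- c(used, cand)
    cand
  }

  if (nrow(conserved)) {
    hseq <- canonical_rna(homologs)
    hnames <- names(homologs)
    best_for <- vapply(conserved$mature_seq, function(m) {
      sc <- vapply(hseq, function(s) seed_similarity(m, s), 0L)
      top <- which(sc == max(sc))
      hnames[top[order(hnames[top])[1L]]]
    }, "")
    conserved$proposed <- paste0("oar-", .base_name(best_for))
    for (nm in unique(conserved$proposed)) {
      grp <- conserved[conserved$proposed == nm, , drop = FALSE]
      grp <- grp[.coord_order(grp), , drop = FALSE]
      parts <- split(seq_len(nrow(grp)), factor(grp$mature_seq,
                                                levels = unique(grp$mature_seq)))
      if (length(parts) == 1L) {
        idx <- parts[[1L]]
        nms <- if (length(idx) == 1L) claim(nm) else
          vapply(seq_along(idx), function(k) claim(paste0(nm, "-", k)), "")
        result[grp$id[idx]] <- nms
      } else {
        # near-duplicates: letter per mature-sequence partition, coord order
        for (p in seq_along(parts)) {
          idx <- parts[[p]]
          lettered <- paste0(nm, letters[p])
          nms <- if (length(idx) == 1L) claim(lettered) else
            vapply(seq_along(idx), function(k)
              claim(paste0(lettered, "-", k)), "")
          result[grp$id[idx]] <- nms
        }
      }
    }
  }

  if (nrow(noncons)) {
    noncons <- noncons[.coord_order(noncons), , drop = FALSE]
    grp_key <- factor(noncons$mature_seq, levels = unique(noncons$mature_seq))
    for (g in seq_along(levels(grp_key))) {
      idx <- which(as.integer(grp_key) == g)
      base <- paste0("oar-miR-N", g)
      nms <- if (length(idx) == 1L) claim(base) else
        vapply(seq_along(idx), function(k) claim(paste0(base, "-", k)), "")
      result[noncons$id[idx]] <- nms
    }
  }

  out <- data.frame(precursor_id = names(result), name = unname(result),
                    stringsAsFactors = FALSE)
  out[match(rep_mat$id[rep_mat$id %in% out$precursor_id], out$precursor_id), ,
      drop = FALSE]
}

#' Group assigned names into miRNA families
#'
#' The family label is the name stripped of the species prefix, the arm
#' suffix, any -1/-2 duplicate suffix, and trailing paralog letters after the
#' family number (oar-miR-2285la -> miR-2285; oar-miR-N7 -> miR-N7).
#'
#' @param assignment data.frame precursor_id, name (from [assign_names()]).
#' @return named list: family label -> character vector of precursor ids.
#' @export
group_families <- function(assignment) {
  if (!nrow(assignment)) return(stats::setNames(list(), character(0)))
  fam <- sub("^[a-z]{3,4}-", "", assignment$name)
  fam <- sub("-(5p|3p)$", "", fam)
  fam <- sub("^(.*[0-9][a-z]*)-[0-9]+$", "\\1", fam)  # -1/-2 duplicate suffix
  fam <- sub("^(.*[0-9])[a-z]+$", "\\1", fam)         # trailing paralog letters
  split(assignment$precursor_id, fam)
}
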