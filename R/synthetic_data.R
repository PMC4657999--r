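# Ground-truthed synthetic inputs: two-library read stacks on hairpin
# precursors with planted specificity classes, conservation tiers, duplicate
# mature pairs, genomic clusters, isomiR category proportions and decoy
# candidates for every filtering rule.

.BASES <- c("A", "C", "G", "U")
.COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

#' Default simulation configuration
#'
#' The defaults are the study conditions of the sheep left-ventricle /
#' global-library design: 172 novel precursors partitioned 12/76/84 across
#' LV-only / GL-only / both (19/115/130 matures via the two-mature quotas),
#' conservation tiers 112/10/29/21, 13 duplicate-mature precursor pairs,
#' 7 planted clusters holding 17 precursors, 100 known precursors (85 shared
#' with LV), 27 chromosomes, isomiR category proportions near the pooled
#' observed distribution (57.5% reference, 18% templated 3', 10.5%
#' non-templated 3', 8.5% polymorphic, 5% templated 5', rare remaining
#' forms), 90.93% of mappable reads between 18 and 24 nt, 5p-dominance
#' weights 0.6421 (LV) / 0.5398 (GL) with an arm-switch rate of 5/84, and
#' decoy candidates exercising each retention rule (3 low-score, 3
#' low-count, 4 repeat-like, 6 other-ncRNA, the last two mirroring the ten
#' candidates removed by the conservation screens).
#'
#' @param seed integer RNG seed; a fixed seed makes [simulate_mirnaome()]
#'   byte-identical across runs.
#' @param ... named overrides of any default listed above (see the returned
#'   list for field names).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    libraries = c("LV", "GL"),
    class_quotas = c(A_only = 12L, B_only = 76L, both = 84L),
    two_mature_quotas = c(A_only = 7L, B_only = 39L, both = 46L),
    tier_quotas = c(conserved_broad = 112L, conserved_narrow = 10L,
                    conserved_single = 29L, nonconserved = 21L),
    duplicate_pairs = 13L,
    cluster_sizes = c(3L, 3L, 2L, 2L, 2L, 2L, 3L),
    n_chrom = 27L,
    n_known = 100L,
    known_both = 85L,
    known_two_mature = 59L,
    isomir_props = c(reference = 0.575, templated_5p = 0.05,
                     nontemplated_5p = 0.002, templated_3p = 0.18,
                     nontemplated_3p = 0.105, both_ends_templated = 0.0015,
                     both_ends_nontemplated = 0.0015, polymorphic = 0.085),
    addition_weights = c(A = 0.5, U = 0.3, C = 0.1, G = 0.1),
    substitution_rate = NULL,  # kept for clarity; edits are category-driven
    depth_meanlog = log(150), depth_sdlog = 1,
    min_present = 10L,
    p5_dominant = c(0.6421, 0.5398),
    switch_rate = 5 / 84,
    decoys = c(low_score = 3L, low_count = 3L, "repeat" = 4L,
               other_ncrna = 6L),
    snr_table = data.frame(
      cutoff = 0:10,
      snr = c(1.1, 1.6, 2.4, 3.8, 6.1, 37.2, 41.5, 44.0, 47.3, 49.9, 51.2)),
    length_reads_n = 10000L,
    frac_18_24 = 0.9093,
    species_pool = c("bta", "hsa", "mmu", "ssc", "eca", "cfa", "chi",
                     "ptr", "oan", "gga", "rno", "dps"))
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    .fail("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg list from [sim_config()].
#' @return the config, invisibly checked.
#' @export
validate_sim_config <- function(cfg) {
  .check(length(cfg$libraries) == 2L, "exactly two libraries are supported")
  .check(abs(sum(cfg$isomir_props) - 1) < 1e-9,
         "isomiR category proportions must sum to 1")
  .check(setequal(names(cfg$isomir_props), isomir_categories()),
         "isomir_props must cover exactly the eight categories")
  .check(all(cfg$two_mature_quotas <= cfg$class_quotas),
         "two-mature quotas cannot exceed class quotas")
  .check(sum(cfg$cluster_sizes) <= sum(cfg$class_quotas),
         "planted clusters exceed the novel precursor count")
  .check(all(cfg$cluster_sizes >= 2L), "cluster sizes must be >= 2")
  n_single <- sum(cfg$class_quotas) - sum(cfg$two_mature_quotas)
  .check(2L * cfg$duplicate_pairs <= n_single,
         "not enough single-mature precursors for the duplicate pairs")
  .check(cfg$known_both <= cfg$n_known,
         "known_both cannot exceed n_known")
  .check(cfg$frac_18_24 >= 0 && cfg$frac_18_24 <= 1,
         "frac_18_24 must be a probability")
  cfg
}

# hairpin with a reverse-complement-biased 3p arm so it looks stem-loop-like
.make_hairpin <- function(L, off5, len5, off3, len3) {
  s <- strsplit(.rand_seq(L), "")[[1]]
  for (k in seq_len(min(len5, len3))) {
    if (stats::runif(1) < 0.85) {
      s[off3 + len3 + 1L - k] <- .COMPLEMENT[[s[off5 + k]]]
    }
  }
  paste(s, collapse = "")
}

# draw a base from the addition alphabet, never equal to `not`
.nt_base <- function(weights, not) {
  w <- weights[setdiff(names(weights), not)]
  sample(names(w), 1L, prob = w)
}

# build one read row implementing an isomiR category on a mature
.make_read <- function(category, prec_seq, offset, mature, weights) {
  len <- nchar(mature)
  at <- function(p0) substr(prec_seq, p0 + 1L, p0 + 1L)  # 0-based access
  start <- offset; seqr <- mature; mm <- character(0)
  if (category %in% c("templated_5p", "both_ends_templated")) {
    if (category == "templated_5p" && stats::runif(1) < 0.5) {
      start <- offset + 1L; seqr <- substr(seqr, 2L, nchar(seqr))
    } else {
      start <- offset - 1L; seqr <- paste0(at(offset - 1L), seqr)
    }
  }
  if (category == "nontemplated_5p" ||
      category == "both_ends_nontemplated") {
    b <- .nt_base(weights, at(offset - 1L))
    start <- offset - 1L; seqr <- paste0(b, seqr)
    mm <- c(mm, paste0("1:", b))
  }
  if (category %in% c("templated_3p", "both_ends_templated")) {
    if (category == "templated_3p" && stats::runif(1) < 0.5) {
      seqr <- substr(seqr, 1L, nchar(seqr) - 1L)
    } else {
      seqr <- paste0(seqr, at(offset + len))
    }
  }
  if (category == "nontemplated_3p" ||
      category == "both_ends_nontemplated") {
    b <- .nt_base(weights, at(offset + len))
    seqr <- paste0(seqr, b)
    mm <- c(mm, paste0(nchar(seqr), ":", b))
  }
  if (category == "polymorphic") {
    pos <- sample(3:(len - 2L), 1L)
    old <- substr(mature, pos, pos)
    b <- sample(setdiff(.BASES, old), 1L)
    substr(seqr, pos, pos) <- b
    mm <- paste0(pos, ":", b)
  }
  list(start = start, sequence = seqr, mismatches = paste(mm, collapse = ";"))
}

#' Simulate a ground-truthed two-library miRNAome
#'
#' Generates, under the configured quotas: hairpin precursors placed on
#' synthetic chromosomes honoring planted clusters (intra-cluster gaps drawn
#' below 10 kb on one strand, everything else isolated by wider gaps);
#' per-library mature counts honoring the specificity classes and
#' arm-dominance weights; per-read isomiR categories drawn from the
#' configured multinomial, with read sequences forward-edited from the
#' reference mature (templated edits copy precursor bases, non-templated
#' additions draw from the addition alphabet, polymorphic reads substitute
#' one internal base) so the mismatch annotations are exact by construction;
#' homology hit tables matching the conservation tier quotas plus decoy
#' repeat/other-ncRNA hits; a homolog mature catalog for naming; an SNR
#' table; and an iid mappable-read length sample.
#'
#' @param config a `sim_config` list.
#' @return list with precursors (canonical table), stacks, homology,
#'   chrom_lengths (named vector), snr, homologs (named character vector),
#'   read_lengths (data.frame length, count), truth (ground-truth manifest)
#'   and config.
#' @export
simulate_mirnaome <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  libs <- cfg$libraries
  n_novel <- sum(cfg$class_quotas)

  chrom_names <- c(as.character(seq_len(cfg$n_chrom - 1L)), "X")
  chrom_lengths <- stats::setNames(
    round(seq(275e6, 40e6, length.out = cfg$n_chrom)), chrom_names)

  # --- plan novel precursors -----------------------------------------------
  classes <- sample(rep(names(cfg$class_quotas), cfg$class_quotas))
  two_mature <- logical(n_novel)
  for (cl in names(cfg$class_quotas)) {
    idx <- which(classes == cl)
    two_mature[sample(idx, cfg$two_mature_quotas[[cl]])] <- TRUE
  }
  tiers <- sample(rep(names(cfg$tier_quotas), cfg$tier_quotas))
  single_arm <- ifelse(stats::runif(n_novel) < cfg$p5_dominant[1L],
                       "5p", "3p")

  # duplicate-mature pairs among single-mature precursors
  singles <- which(!two_mature)
  dup_members <- sample(singles, 2L * cfg$duplicate_pairs)
  dup_pairs <- matrix(dup_members, ncol = 2L)

  # decoys
  n_dec <- sum(cfg$decoys)
  decoy_reason <- rep(names(cfg$decoys), cfg$decoys)

  # known precursors
  n_known <- cfg$n_known
  known_class <- c(rep("both", cfg$known_both),
                   rep("B_only", n_known - cfg$known_both))
  known_two <- logical(n_known)
  if (cfg$known_two_mature > 0L) {
    known_two[sample.int(n_known, cfg$known_two_mature)] <- TRUE
  }

  # --- sequences -----------------------------------------------------------
  n_all <- n_novel + n_dec + n_known
  role <- c(rep("novel", n_novel), decoy_reason, rep("known", n_known))
  ids <- sprintf("cand_%04d", seq_len(n_all))
  ids[role == "known"] <- sprintf("known_%03d", seq_len(n_known))

  plan <- vector("list", n_all)
  mature_pool <- character(0)
  for (i in seq_len(n_all)) {
    repeat {
      L <- sample(70:90, 1L)
      len5 <- sample(20:22, 1L)
      len3 <- sample(20:22, 1L)
      off5 <- sample(3:6, 1L)
      off3 <- L - sample(3:6, 1L) - len3   # 0-based start of 3p mature
      seqp <- .make_hairpin(L, off5, len5, off3, len3)
      m5 <- substr(seqp, off5 + 1L, off5 + len5)
      m3 <- substr(seqp, off3 + 1L, off3 + len3)
      if (!(m5 %in% mature_pool) && !(m3 %in% mature_pool) && m5 != m3) break
    }
    mature_pool <- c(mature_pool, m5, m3)
    plan[[i]] <- list(L = L, seq = seqp, off5 = off5, len5 = len5,
                      off3 = off3, len3 = len3, m5 = m5, m3 = m3)
  }

  # overwrite duplicate partners' mature region with the first member's
  for (k in seq_len(nrow(dup_pairs))) {
    a <- dup_pairs[k, 1L]; b <- dup_pairs[k, 2L]
    arm <- single_arm[a]; single_arm[b] <- arm
    pa <- plan[[a]]; pb <- plan[[b]]
    if (arm == "5p") {
      mseq <- pa$m5
      pb$len5 <- nchar(mseq)
      substr(pb$seq, pb$off5 + 1L, pb$off5 + pb$len5) <- mseq
      pb$m5 <- mseq
    } else {
      mseq <- pa$m3
      pb$off3 <- pb$off3 + pb$len3 - nchar(mseq)
      pb$len3 <- nchar(mseq)
      substr(pb$seq, pb$off3 + 1L, pb$off3 + pb$len3) <- mseq
      pb$m3 <- mseq
    }
    plan[[b]] <- pb
  }

  # --- genomic placement ---------------------------------------------------
  cluster_members <- list()
  pool <- sample(seq_len(n_novel))
  taken <- 0L
  for (s in cfg$cluster_sizes) {
    cluster_members[[length(cluster_members) + 1L]] <-
      pool[(taken + 1L):(taken + s)]
    taken <- taken + s
  }
  clustered <- unlist(cluster_members)
  entities <- c(lapply(cluster_members, identity),
                as.list(setdiff(seq_len(n_all), clustered)))
  entities <- sample(entities)
  cursor <- stats::setNames(round(stats::runif(cfg$n_chrom, 1e5, 5e5)),
                            chrom_names)
  chrom <- character(n_all); strand <- character(n_all)
  start <- integer(n_all); end <- integer(n_all)
  cluster_of <- rep(NA_integer_, n_all)
  for (e in seq_along(entities)) {
    members <- entities[[e]]
    chr <- sample(chrom_names, 1L)
    str <- sample(c("+", "-"), 1L)
    pos <- cursor[[chr]] + round(stats::runif(1, 15000, 120000))
    if (length(members) > 1L) {
      members <- sample(members)  # genomic order independent of planning
      ci <- which(vapply(cluster_members, function(m)
        all(members %in% m), TRUE))
      for (m in members) {
        chrom[m] <- chr; strand[m] <- str
        start[m] <- pos; end[m] <- pos + plan[[m]]$L
        cluster_of[m] <- ci
        pos <- end[m] + round(stats::runif(1, 1000, 9000))
      }
    } else {
      m <- members
      chrom[m] <- chr; strand[m] <- sample(c("+", "-"), 1L)
      start[m] <- pos; end[m] <- pos + plan[[m]]$L
      pos <- end[m]
    }
    cursor[[chr]] <- pos
  }

  # --- counts and dominance ------------------------------------------------
  draw_depth <- function(lo) {
    max(lo, round(stats::rlnorm(1, cfg$depth_meanlog, cfg$depth_sdlog)))
  }
  present_libs <- function(cl) switch(cl,
    A_only = libs[1L], B_only = libs[2L], both = libs)

  counts <- matrix(0L, nrow = n_all, ncol = 2L,
                   dimnames = list(ids, libs))      # 5p counts
  counts3 <- counts                                 # 3p counts
  has5 <- logical(n_all); has3 <- logical(n_all)
  dom <- matrix(NA_character_, n_all, 2L, dimnames = list(ids, libs))

  all_class <- c(classes, rep("both", n_dec), known_class)
  all_two <- c(two_mature, rep(FALSE, n_dec), known_two)
  is_decoy_lc <- role == "low_count"

  for (i in seq_len(n_all)) {
    pls <- present_libs(all_class[i])
    if (all_two[i]) {
      has5[i] <- TRUE; has3[i] <- TRUE
      dom_a <- if (stats::runif(1) < cfg$p5_dominant[1L]) "5p" else "3p"
      for (lib in pls) {
        j <- match(lib, libs)
        d <- if (lib == libs[1L] || all_class[i] != "both") {
          if (lib == libs[2L]) {
            if (stats::runif(1) < cfg$p5_dominant[2L]) "5p" else "3p"
          } else dom_a
        } else {
          if (stats::runif(1) < cfg$switch_rate) setdiff(c("5p", "3p"), dom_a)
          else dom_a
        }
        td <- draw_depth(cfg$min_present + 5L)
        to <- max(cfg$min_present,
                  min(td - 1L, round(td * stats::runif(1, 0.15, 0.6))))
        if (d == "5p") { counts[i, j] <- td; counts3[i, j] <- to }
        else { counts[i, j] <- to; counts3[i, j] <- td }
        dom[i, j] <- d
      }
    } else {
      arm <- if (role[i] == "known" || role[i] == "novel") {
        if (role[i] == "known") sample(c("5p", "3p"), 1L) else single_arm[i]
      } else sample(c("5p", "3p"), 1L)
      if (arm == "5p") has5[i] <- TRUE else has3[i] <- TRUE
      for (lib in pls) {
        j <- match(lib, libs)
        n <- if (is_decoy_lc[i]) sample(2:4, 1L) else
          draw_depth(cfg$min_present)
        if (arm == "5p") counts[i, j] <- n else counts3[i, j] <- n
        dom[i, j] <- arm
      }
    }
  }
  # low-count decoys: force every mature's pooled total below the floor
  for (i in which(is_decoy_lc)) {
    while (sum(counts[i, ]) + sum(counts3[i, ]) >= cfg$min_present) {
      counts[i, ] <- pmax(0L, counts[i, ] - 1L)
      counts3[i, ] <- pmax(0L, counts3[i, ] - 1L)
    }
  }

  # --- scores --------------------------------------------------------------
  score <- round(10^stats::runif(n_all, 0.75, 4.5), 1)
  score[role == "low_score"] <- round(stats::runif(sum(role == "low_score"),
                                                   0.5, 4.4), 1)
  is_known <- role == "known"

  # --- precursor table -----------------------------------------------------
  rows <- list()
  for (i in seq_len(n_all)) {
    p <- plan[[i]]
    base <- data.frame(id = ids[i], chrom = chrom[i], start = start[i],
                       end = end[i], strand = strand[i], score = score[i],
                       is_known = is_known[i], sequence = p$seq,
                       stringsAsFactors = FALSE)
    if (has5[i]) {
      r <- cbind(base, data.frame(arm = "5p", mature_seq = p$m5,
                                  mature_offset = p$off5))
      r[[libs[1L]]] <- counts[i, 1L]; r[[libs[2L]]] <- counts[i, 2L]
      rows[[length(rows) + 1L]] <- r
    }
    if (has3[i]) {
      r <- cbind(base, data.frame(arm = "3p", mature_seq = p$m3,
                                  mature_offset = p$off3))
      r[[libs[1L]]] <- counts3[i, 1L]; r[[libs[2L]]] <- counts3[i, 2L]
      rows[[length(rows) + 1L]] <- r
    }
  }
  precursors <- do.call(rbind, rows)
  precursors <- validate_precursor_table(precursors)

  # --- read stacks ---------------------------------------------------------
  cats <- isomir_categories()
  stack_rows <- list()
  truth_cat <- list()
  for (i in seq_len(n_all)) {
    p <- plan[[i]]
    arms <- c(if (has5[i]) "5p", if (has3[i]) "3p")
    for (arm in arms) {
      off <- if (arm == "5p") p$off5 else p$off3
      mat <- if (arm == "5p") p$m5 else p$m3
      cmat <- if (arm == "5p") counts[i, ] else counts3[i, ]
      for (j in seq_along(libs)) {
        n <- cmat[[j]]
        if (n == 0L) next
        ncat <- stats::rmultinom(1L, n, cfg$isomir_props[cats])[, 1L]
        for (k in seq_along(cats)) {
          if (ncat[k] == 0L) next
          rd <- .make_read(cats[k], p$seq, off, mat, cfg$addition_weights)
          stack_rows[[length(stack_rows) + 1L]] <- data.frame(
            precursor_id = ids[i], library = libs[j], start = rd$start,
            sequence = rd$sequence, count = ncat[k],
            mismatches = rd$mismatches, stringsAsFactors = FALSE)
          truth_cat[[length(truth_cat) + 1L]] <- data.frame(
            precursor_id = ids[i], library = libs[j], arm = arm,
            category = cats[k], count = ncat[k], stringsAsFactors = FALSE)
        }
      }
    }
  }
  stacks <- do.call(rbind, stack_rows)
  rownames(stacks) <- NULL
  truth_reads <- do.call(rbind, truth_cat)
  rownames(truth_reads) <- NULL

  # --- homology hits and homolog catalog -----------------------------------
  hit_rows <- list()
  homolog_names <- character(0)
  homolog_seqs <- character(0)
  expected_name <- rep(NA_character_, n_all)
  single_letters <- paste0(rep(c("2285", "2284"), c(26L, 10L)),
                           c(letters, letters[1:10]))
  n_broadnames <- 0L; n_single <- 0L
  mutate_outside_seed <- function(s) {
    pos <- sample(9:nchar(s), 1L)
    old <- substr(s, pos, pos)
    substr(s, pos, pos) <- sample(setdiff(.BASES, old), 1L)
    s
  }
  for (i in seq_len(n_novel)) {
    p <- plan[[i]]
    mat <- if (has5[i]) p$m5 else p$m3
    if (has5[i] && has3[i]) {
      mat <- if (sum(counts[i, ]) >= sum(counts3[i, ])) p$m5 else p$m3
    }
    tier <- tiers[i]
    if (tier == "nonconserved") next
    if (tier == "conserved_broad") {
      nsp <- sample(5:8, 1L)
      sp <- sample(cfg$species_pool, nsp)
      ev <- 10^stats::runif(nsp, -25, -9.6)
      n_broadnames <- n_broadnames + 1L
      hname <- paste0("miR-", 100L + n_broadnames)
    } else if (tier == "conserved_narrow") {
      nsp <- sample(2:4, 1L)
      sp <- sample(cfg$species_pool, nsp)
      ev <- 10^stats::runif(nsp, -4.9, -4.06)
      n_broadnames <- n_broadnames + 1L
      hname <- paste0("miR-", 100L + n_broadnames)
    } else {
      nsp <- 1L
      sp <- "bta"
      ev <- 10^stats::runif(1L, -5, -3.8)
      n_single <- n_single + 1L
      hname <- paste0("miR-", single_letters[n_single])
    }
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = ids[i], subject_id = paste0(sp, "-", hname),
      subject_species = sp, evalue = ev, db = "mirbase",
      stringsAsFactors = FALSE)
    homolog_names <- c(homolog_names, paste0(sp[1L], "-", hname))
    homolog_seqs <- c(homolog_seqs, mutate_outside_seed(mat))
    expected_name[i] <- paste0("oar-", hname)
  }
  # decoy hits: repeats and other ncRNAs
  for (i in which(role == "repeat")) {
    k <- sample(6:8, 1L)
    pos <- round(stats::runif(k, 1e6, 2e8))
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = ids[i],
      subject_id = paste0(sample(chrom_names, k, replace = TRUE), ":",
                          pos, "-", pos + 200L),
      subject_species = "oar", evalue = 10^stats::runif(k, -20, -10),
      db = "genome_self", stringsAsFactors = FALSE)
  }
  for (i in which(role == "other_ncrna")) {
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = ids[i], subject_id = sample(c("U6-snRNA", "SNORD27",
                                               "tRNA-Gly"), 1L),
      subject_species = "oar", evalue = 10^stats::runif(1L, -15, -9),
      db = "rfam_refseq", stringsAsFactors = FALSE)
  }
  homology <- do.call(rbind, hit_rows)
  rownames(homology) <- NULL
  homologs <- stats::setNames(homolog_seqs, homolog_names)

  # --- mappable read length sample (iid) -----------------------------------
  n_len <- cfg$length_reads_n
  in_range <- stats::runif(n_len) < cfg$frac_18_24
  len <- integer(n_len)
  len[in_range] <- sample(18:24, sum(in_range), replace = TRUE,
                          prob = c(2, 5, 12, 30, 25, 15, 11))
  len[!in_range] <- sample(c(15:17, 25:32), sum(!in_range), replace = TRUE)
  length_tab <- as.data.frame(table(length = len), stringsAsFactors = FALSE)
  read_lengths <- data.frame(length = as.integer(length_tab$length),
                             count = as.integer(length_tab$Freq))

  # --- ground truth manifest -----------------------------------------------
  novel_ids <- ids[seq_len(n_novel)]
  class_label <- function(cl) switch(cl,
    A_only = paste0(libs[1L], "_only"),
    B_only = paste0(libs[2L], "_only"), "both")
  truth <- list(
    classes = data.frame(
      precursor_id = novel_ids,
      class = vapply(classes, class_label, ""),
      stringsAsFactors = FALSE),
    tiers = data.frame(precursor_id = novel_ids, tier = tiers,
                       stringsAsFactors = FALSE),
    dominant_arm = data.frame(
      precursor_id = rep(ids, 2L),
      library = rep(libs, each = n_all),
      arm = c(dom[, 1L], dom[, 2L]),
      stringsAsFactors = FALSE),
    clusters = data.frame(
      precursor_id = ids[clustered],
      cluster_id = cluster_of[clustered],
      stringsAsFactors = FALSE),
    duplicate_pairs = lapply(seq_len(nrow(dup_pairs)), function(k)
      sort(ids[dup_pairs[k, ]])),
    expected_drops = stats::setNames(
      decoy_reason, ids[role %in% names(cfg$decoys)]),
    expected_name = stats::setNames(expected_name[seq_len(n_novel)],
                                    novel_ids),
    reads = truth_reads,
    quotas = list(classes = cfg$class_quotas, tiers = cfg$tier_quotas,
                  matures = cfg$class_quotas + cfg$two_mature_quotas))
  truth$dominant_arm <- truth$dominant_arm[!is.na(truth$dominant_arm$arm), ]

  list(precursors = precursors, stacks = stacks, homology = homology,
       chrom_lengths = chrom_lengths, snr = cfg$snr_table,
       homologs = homologs, read_lengths = read_lengths,
       truth = truth, config = cfg)
}

#' Write a simulation to canonical files
#'
#' Emits the canonical precursor, read-stack, homology, chromosome-length and
#' SNR TSVs, hairpin and homolog-catalog FASTA files, the read-length table
#' and the ground-truth manifest as JSON.
#'
#' @param sim list from [simulate_mirnaome()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    precursors = file.path(dir, "precursors.tsv"),
    stacks = file.path(dir, "read_stacks.tsv"),
    homology = file.path(dir, "homology_hits.tsv"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
    snr = file.path(dir, "snr.tsv"),
    hairpins = file.path(dir, "hairpins.fa"),
    homologs = file.path(dir, "homolog_matures.fa"),
    read_lengths = file.path(dir, "read_lengths.tsv"),
    truth = file.path(dir, "truth.json"))
  write_precursor_table(sim$precursors, paths[["precursors"]])
  write_stack_table(sim$stacks, paths[["stacks"]])
  utils::write.table(sim$homology, paths[["homology"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(sim$chrom_lengths),
               length_bp = as.numeric(sim$chrom_lengths)),
    paths[["chrom_lengths"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$snr, paths[["snr"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  plev <- precursor_level(sim$precursors)
  write_fasta_seqs(stats::setNames(plev$sequence, plev$id),
                   paths[["hairpins"]])
  write_fasta_seqs(sim$homologs, paths[["homologs"]])
  utils::write.table(sim$read_lengths, paths[["read_lengths"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
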