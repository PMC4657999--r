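mk_hits <- function(id, species, evalue) {
  data.frame(query_id = id, subject_id = paste0(species, "-miR-x"),
             subject_species = species, evalue = evalue, db = "mirbase",
             stringsAsFactors = FALSE)
}

test_that("conservation tiers follow the E-value ladder", {
  h <- mk_hits("p", c("bta", "hsa", "mmu", "ssc", "eca", "cfa"), 1e-20)
  expect_equal(assign_tier("p", h)$tier, "conserved_broad")

  h <- mk_hits("p", "bta", 1e-05)
  call <- assign_tier("p", h)
  expect_equal(call$tier, "conserved_single")
  expect_equal(call$supporting_species, "bta")

  h <- mk_hits("p", c("bta", "hsa", "mmu"), 5e-06)
  expect_equal(assign_tier("p", h)$tier, "conserved_narrow")

  expect_equal(assign_tier("p", mk_hits("q", "bta", 1e-30))$tier,
               "nonconserved")  # hits for another query don't count
  expect_equal(assign_tier("p", mk_hits("p", "bta", 1e-3))$tier,
               "nonconserved")  # too weak for any tier
})

test_that("tiers partition candidates and broad count is monotone in broad_e", {
  set.seed(5)
  for (rep_i in 1:5) {
    ids <- sprintf("p%02d", 1:25)
    hits <- do.call(rbind, lapply(ids, function(id) {
      k <- sample(0:7, 1)
      if (k == 0) return(NULL)
      mk_hits(id, sample(c("bta", "hsa", "mmu", "ssc", "eca", "cfa", "chi"),
                         k), 10^runif(k, -22, -3))
    }))
    if (is.null(hits)) hits <- mk_hits("none", "bta", 1)
    tiers <- assign_tiers(ids, hits)
    expect_equal(nrow(tiers), length(ids))
    expect_true(all(tiers$tier %in% c("conserved_broad", "conserved_narrow",
                                      "conserved_single", "nonconserved")))
    strict <- assign_tiers(ids, hits, broad_e = 4e-12)
    expect_lte(sum(strict$tier == "conserved_broad"),
               sum(tiers$tier == "conserved_broad"))
  }
})

test_that("seed similarity weights positions 2-8 double and finds best offset", {
  s <- "ACGUACGUACGUACGUACGUA"
  expect_equal(seed_similarity(s, s), 2L * 7L + (nchar(s) - 7L))
  # identical except position 5 (seed): loses 2 relative to identity
  s2 <- s
  substr(s2, 5, 5) <- "C"  # was A
  expect_equal(seed_similarity(s, s2), seed_similarity(s, s) - 2L)
  # a shifted copy still aligns at the best offset
  expect_gt(seed_similarity(s, paste0("GG", s)), nchar(s))
  expect_equal(seed_similarity("ACGUACGUACGUACGUACG", ""), 0L)
})

test_that("nonconserved precursors get provisional N-names; shared matures -1/-2", {
  shared <- paste(rep("ACGU", 6), collapse = "")  # 24-nt mature
  tbl <- prec_table(
    prec_row("pA", chrom = "2", start = 5000L, mature_seq = shared,
             mature_len = 24L),
    prec_row("pB", chrom = "1", start = 1000L),
    prec_row("pC", chrom = "9", start = 100L, mature_seq = shared,
             mature_len = 24L))
  tiers <- data.frame(precursor_id = c("pA", "pB", "pC"),
                      tier = "nonconserved")
  nm <- assign_names(tbl, tiers, character(0))
  got <- setNames(nm$name, nm$precursor_id)
  # coordinate order: pB (chr1) first -> N1; shared pair numbered together
  expect_equal(unname(got["pB"]), "oar-miR-N1")
  expect_equal(unname(got["pA"]), "oar-miR-N2-1")
  expect_equal(unname(got["pC"]), "oar-miR-N2-2")
})

test_that("conserved homolog naming resolves collisions with letters", {
  m1 <- "ACGUACGUACGUACGUACGUA"
  m2 <- "ACGUACGUACGUACGUACCCA"  # same seed, different tail
  tbl <- prec_table(
    prec_row("c1", chrom = "3", start = 100L, mature_seq = m1,
             mature_len = 21L),
    prec_row("c2", chrom = "3", start = 90000L, mature_seq = m2,
             mature_len = 21L),
    prec_row("u1", chrom = "7", start = 100L))
  tiers <- data.frame(precursor_id = c("c1", "c2", "u1"),
                      tier = c("conserved_single", "conserved_single",
                               "conserved_broad"))
  u1_mat <- tbl$mature_seq[tbl$id == "u1"]
  homologs <- c("bta-miR-2285l" = m1, "hsa-miR-208b" = u1_mat)
  nm <- assign_names(tbl, tiers, homologs)
  got <- setNames(nm$name, nm$precursor_id)
  expect_equal(unname(got["c1"]), "oar-miR-2285la")
  expect_equal(unname(got["c2"]), "oar-miR-2285lb")
  expect_equal(unname(got["u1"]), "oar-miR-208b")
  expect_error(assign_names(tbl, tiers, character(0)), "homolog catalog")
})

test_that("identical matures under one homolog get -1/-2 in coordinate order", {
  m <- "ACGUACGUACGUACGUACGUA"
  tbl <- prec_table(
    prec_row("d2", chrom = "5", start = 9000L, mature_seq = m,
             mature_len = 21L),
    prec_row("d1", chrom = "5", start = 100L, mature_seq = m,
             mature_len = 21L))
  tiers <- data.frame(precursor_id = c("d2", "d1"), tier = "conserved_broad")
  nm <- assign_names(tbl, tiers, c("bta-miR-450" = m))
  got <- setNames(nm$name, nm$precursor_id)
  expect_equal(unname(got["d1"]), "oar-miR-450-1")
  expect_equal(unname(got["d2"]), "oar-miR-450-2")
})

test_that("naming is injective and invariant under input permutation", {
  sim <- simulate_mirnaome(small_config(seed = 21))
  novel <- sim$precursors[!sim$precursors$is_known &
                            !(sim$precursors$id %in%
                                names(sim$truth$expected_drops)), ]
  tiers <- assign_tiers(unique(novel$id), sim$homology)
  nm1 <- assign_names(novel, tiers, sim$homologs)
  set.seed(1)
  shuffled <- novel[sample(nrow(novel)), ]
  nm2 <- assign_names(shuffled, tiers[sample(nrow(tiers)), ], sim$homologs)
  expect_false(anyDuplicated(nm1$name) > 0)
  expect_mapequal(setNames(as.list(nm1$name), nm1$precursor_id),
                  setNames(as.list(nm2$name), nm2$precursor_id))
})

test_that("family grouping strips prefixes, arms, letters and -1/-2 suffixes", {
  asg <- data.frame(
    precursor_id = c("a", "b", "c", "d", "e"),
    name = c("oar-miR-2285la", "oar-miR-2285lb", "oar-miR-2284x",
             "oar-miR-N7", "oar-miR-N14-1"))
  fams <- group_families(asg)
  expect_equal(sort(fams[["miR-2285"]]), c("a", "b"))
  expect_equal(fams[["miR-2284"]], "c")
  expect_equal(fams[["miR-N7"]], "d")
  expect_equal(fams[["miR-N14"]], "e")
  expect_equal(length(group_families(asg[0, ])), 0L)
  # grouping is a partition
  expect_setequal(unlist(fams), asg$precursor_id)
})
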