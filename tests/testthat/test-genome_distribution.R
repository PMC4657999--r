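test_that("specificity classes partition present precursors with exact totals", {
  tbl <- prec_table(
    prec_row("a", counts = c(LV = 10L, GL = 0L)),
    prec_row("b", counts = c(LV = 0L, GL = 10L)),
    prec_row("c", counts = c(LV = 15L, GL = 25L)),
    prec_row("d", counts = c(LV = 3L, GL = 2L)))  # absent from both
  sp <- classify_specificity(tbl, c("LV", "GL"))
  calls <- setNames(sp$precursor_calls$class, sp$precursor_calls$precursor_id)
  expect_equal(unname(calls["a"]), "LV_only")  # boundary: exactly 10
  expect_equal(unname(calls["b"]), "GL_only")
  expect_equal(unname(calls["c"]), "both")
  expect_equal(sp$excluded, "d")
  tot <- sp$totals["precursors", ]
  expect_equal(tot$total, tot$LV_only + tot$GL_only + tot$both)
})

test_that("precursor presence means any mature form present", {
  tbl <- validate_precursor_table(rbind(
    prec_row("p", arm = "5p", counts = c(LV = 50L, GL = 2L),
             mature_offset = 4L),
    prec_row("p", arm = "3p", counts = c(LV = 2L, GL = 50L),
             mature_offset = 40L)))
  sp <- classify_specificity(tbl, c("LV", "GL"))
  expect_equal(sp$precursor_calls$class, "both")
  # but each mature on its own is library-specific
  expect_setequal(sp$mature_calls$class, c("LV_only", "GL_only"))
})

test_that("cluster chaining matches the chained-gap examples", {
  mk <- function(id, start, strand = "+", chrom = "1")
    prec_row(id, chrom = chrom, start = start, strand = strand,
             seq_len = 70L)
  # gaps of 4 kb and 6 kb chain into one cluster of 3
  tbl <- prec_table(mk("x1", 10000L), mk("x2", 14070L), mk("x3", 20140L))
  cl <- detect_clusters(tbl)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 3L)
  expect_equal(cl$members[[1]], c("x1", "x2", "x3"))
  expect_equal(cl$start, 10000L)
  expect_equal(cl$end, 20210L)
  # 9,999 bases apart but opposite strands: no cluster
  tbl2 <- prec_table(mk("y1", 10000L, "+"), mk("y2", 20069L, "-"))
  expect_equal(nrow(detect_clusters(tbl2)), 0L)
  # equal gap on the same strand: 9,999 < 10,000 clusters
  tbl3 <- prec_table(mk("z1", 10000L, "-"), mk("z2", 20069L, "-"))
  expect_equal(nrow(detect_clusters(tbl3)), 1L)
  # exactly 10,000 does not
  tbl4 <- prec_table(mk("w1", 10000L), mk("w2", 20070L))
  expect_equal(nrow(detect_clusters(tbl4)), 0L)
})

test_that("clusters equal the brute-force transitive closure on random layouts", {
  set.seed(23)
  for (rep_i in 1:8) {
    n <- 50L
    rows <- lapply(seq_len(n), function(i)
      prec_row(sprintf("p%02d", i),
               chrom = sample(c("1", "2"), 1),
               strand = sample(c("+", "-"), 1),
               start = sample.int(200000L, 1), seq_len = 70L))
    tbl <- do.call(prec_table, rows)
    got <- detect_clusters(tbl, max_gap = 10000L)
    got_sets <- lapply(got$members, sort)
    want_sets <- oracle_clusters(precursor_level(tbl), 10000L)
    expect_setequal(got_sets, want_sets)
    # order invariance
    got2 <- detect_clusters(tbl[sample(nrow(tbl)), ], max_gap = 10000L)
    expect_setequal(lapply(got2$members, sort), want_sets)
  }
})

test_that("clusters are maximal and members ordered by start", {
  sim <- simulate_mirnaome(small_config(seed = 6))
  cl <- detect_clusters(sim$precursors)
  plev <- precursor_level(sim$precursors)
  for (k in seq_len(nrow(cl))) {
    members <- cl$members[[k]]
    starts <- plev$start[match(members, plev$id)]
    expect_true(all(diff(starts) >= 0))
    # no outside precursor on the same chrom/strand is within the gap
    outside <- plev[plev$chrom == cl$chrom[k] &
                      plev$strand == cl$strand[k] &
                      !(plev$id %in% members), ]
    if (nrow(outside)) {
      gap <- pmax(outside$start, cl$start[k]) -
        pmin(outside$end, cl$end[k])
      expect_true(all(gap >= 10000L))
    }
  }
  expect_error(
    detect_clusters(rbind(sim$precursors, sim$precursors[1, ])),
    "duplicated arm|duplicate")
})

test_that("chromosome summary computes counts and density per Mbp", {
  rows <- lapply(sprintf("c%02d", 1:60), function(id)
    prec_row(id, chrom = "18", start = sample.int(6e7, 1),
             is_known = id < "c56"))  # 55 known, 5 novel
  tbl <- do.call(prec_table, rows)
  lens <- c("18" = 68965517, "22" = 51000000)
  cs <- chromosome_summary(tbl, lens)
  r18 <- cs[cs$chrom == "18", ]
  expect_equal(r18$total, 60L)
  expect_equal(r18$density_2dp, 0.87)
  r22 <- cs[cs$chrom == "22", ]
  expect_equal(r22$total, 0L)
  expect_equal(r22$density, 0)
  # halving the length doubles the density
  cs2 <- chromosome_summary(tbl, lens / 2)
  expect_equal(cs2$density, cs$density * 2)
  expect_error(chromosome_summary(tbl, c("1" = 1e6)), "18")
})
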