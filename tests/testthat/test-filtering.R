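test_that("score cutoff is the smallest threshold clearing the SNR bar", {
  tab <- data.frame(cutoff = c(4, 5, 6), snr = c(8.2, 37.0, 41.0))
  expect_equal(select_score_cutoff(tab), 5)
  expect_equal(select_score_cutoff(data.frame(cutoff = 1, snr = 100)), 1)
  # strictly greater than 10:1 is required
  expect_error(select_score_cutoff(data.frame(cutoff = 3, snr = 10)),
               "no admissible cutoff")
  expect_error(select_score_cutoff(data.frame(cutoff = c(1, 1),
                                              snr = c(20, 30))),
               "distinct")
})

test_that("retention rules drop the right candidates for the right reasons", {
  tbl <- prec_table(
    prec_row("known_low", score = 0.1, is_known = TRUE,
             counts = c(LV = 500L, GL = 0L)),
    prec_row("novel_low_score", score = 3, counts = c(LV = 500L, GL = 0L)),
    prec_row("novel_low_count", score = 9, counts = c(LV = 4L, GL = 5L)),
    prec_row("novel_repeat", score = 9, counts = c(LV = 50L, GL = 50L)),
    prec_row("novel_ncrna", score = 9, counts = c(LV = 50L, GL = 50L)),
    prec_row("novel_ok", score = 9, counts = c(LV = 50L, GL = 50L)))
  hits <- rbind(
    data.frame(query_id = "novel_repeat",
               subject_id = paste0("chr", 1:6, ":1000-1200"),
               subject_species = "oar", evalue = 1e-12, db = "genome_self"),
    data.frame(query_id = "novel_ncrna", subject_id = "U6-snRNA",
               subject_species = "oar", evalue = 1e-10, db = "rfam_refseq"))
  rep <- apply_candidate_filters(tbl, hits, score_cutoff = 5)
  expect_setequal(rep$kept, c("known_low", "novel_ok"))
  expect_equal(rep$dropped[["novel_low_score"]], "low_score")
  expect_equal(rep$dropped[["novel_low_count"]], "low_count")
  expect_equal(rep$dropped[["novel_repeat"]], "repeat")
  expect_equal(rep$dropped[["novel_ncrna"]], "other_ncrna")
})

test_that("rule order is fixed: low_score outranks low_count", {
  tbl <- prec_table(prec_row("both_bad", score = 1,
                             counts = c(LV = 2L, GL = 2L)))
  rep <- apply_candidate_filters(tbl, NULL, score_cutoff = 5)
  expect_equal(unname(rep$dropped[["both_bad"]]), "low_score")
})

test_that("repeat rule counts distinct genomic areas, not raw hits", {
  tbl <- prec_table(prec_row("r1", score = 9, counts = c(LV = 50L, GL = 0L)))
  # 8 hits but all overlapping the same region -> one area -> kept
  hits <- data.frame(query_id = "r1",
                     subject_id = paste0("chr1:", 1000 + 1:8, "-",
                                         1300 + 1:8),
                     subject_species = "oar", evalue = 1e-12,
                     db = "genome_self")
  rep <- apply_candidate_filters(tbl, hits, score_cutoff = 5)
  expect_equal(rep$kept, "r1")
})

test_that("filter report partitions input and is monotone in the count floor", {
  set.seed(42)
  for (rep_i in 1:5) {
    n <- 30L
    rows <- lapply(seq_len(n), function(i)
      prec_row(sprintf("c%02d", i), score = runif(1, 0, 12),
               is_known = runif(1) < 0.2,
               counts = c(LV = rpois(1, 12), GL = rpois(1, 12))))
    tbl <- do.call(prec_table, rows)
    rep5 <- apply_candidate_filters(tbl, NULL, score_cutoff = 5,
                                    min_count = 5)
    rep20 <- apply_candidate_filters(tbl, NULL, score_cutoff = 5,
                                     min_count = 20)
    ids <- unique(tbl$id)
    expect_setequal(c(rep5$kept, names(rep5$dropped)), ids)
    expect_length(intersect(rep5$kept, names(rep5$dropped)), 0)
    # raising the floor never rescues a dropped candidate
    expect_true(all(rep20$kept %in% rep5$kept))
  }
})

test_that("filters agree with a naive per-candidate re-check on random inputs", {
  set.seed(7)
  n <- 200L
  rows <- lapply(seq_len(n), function(i)
    prec_row(sprintf("c%03d", i), score = runif(1, 0, 12),
             is_known = runif(1) < 0.25,
             counts = c(LV = rpois(1, 10), GL = rpois(1, 10))))
  tbl <- do.call(prec_table, rows)
  hit_ids <- sample(unique(tbl$id), 60)
  hits <- do.call(rbind, lapply(hit_ids, function(id) {
    k <- sample(1:8, 1)
    db <- sample(c("genome_self", "rfam_refseq", "mirbase"), 1)
    data.frame(query_id = id,
               subject_id = paste0("chr", sample(1:9, k, TRUE), ":",
                                   s <- round(runif(k, 1e3, 1e6)), "-",
                                   s + 300),
               subject_species = "oar",
               evalue = 10^runif(k, -15, -5), db = db)
  }))
  rep <- apply_candidate_filters(tbl, hits, score_cutoff = 5)
  oracle <- oracle_filter(tbl, hits, cutoff = 5)
  expect_setequal(rep$kept, names(oracle)[is.na(oracle)])
  dropped <- oracle[!is.na(oracle)]
  expect_mapequal(as.list(rep$dropped), as.list(dropped))
})

test_that("negative thresholds are rejected", {
  tbl <- prec_table(prec_row("x"))
  expect_error(apply_candidate_filters(tbl, NULL, score_cutoff = 5,
                                       min_count = -1),
               "nonnegative")
})
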