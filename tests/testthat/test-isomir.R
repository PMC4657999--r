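# a fixed 60-nt hairpin with a 22-nt mature at offset 10 for hand-built cases
HAIRPIN <- paste0("AACCGGUUAC", "GUACGGAUCCUAGCAUGCAAGU",
                  "GACUGACUGACUGACUGACUGACUGACU")
MAT_OFF <- 10L
MAT_LEN <- 22L
MATURE <- substr(HAIRPIN, MAT_OFF + 1, MAT_OFF + MAT_LEN)

test_that("the identical read is the reference form", {
  cl <- classify_read(MAT_OFF, MATURE, MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl$category, "reference")
  expect_equal(cl$five_prime_offset, 0L)
  expect_equal(cl$three_prime_offset, 0L)
  expect_length(cl$substitutions, 0)
  expect_false(cl$seed_affected)
})

test_that("a read lacking the first nucleotide is a seed-affecting templated 5' isomiR", {
  # the miR-1a-3p pattern: dominant form equals the conserved mature minus
  # its first base
  read <- substr(MATURE, 2, MAT_LEN)
  cl <- classify_read(MAT_OFF + 1L, read, MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl$category, "templated_5p")
  expect_equal(cl$five_prime_offset, 1L)
  expect_true(cl$seed_affected)
})

test_that("templating of extensions follows the precursor sequence", {
  # templated 3' extension: copy the next precursor base
  nextb <- substr(HAIRPIN, MAT_OFF + MAT_LEN + 1, MAT_OFF + MAT_LEN + 1)
  cl <- classify_read(MAT_OFF, paste0(MATURE, nextb), MAT_OFF, MAT_LEN,
                      HAIRPIN)
  expect_equal(cl$category, "templated_3p")
  expect_equal(cl$three_prime_offset, 1L)
  expect_false(cl$seed_affected)
  # non-templated 3' addition: any base that mismatches the precursor
  ntb <- setdiff(c("A", "C", "G", "U"), nextb)[1]
  cl <- classify_read(MAT_OFF, paste0(MATURE, ntb), MAT_OFF, MAT_LEN,
                      HAIRPIN)
  expect_equal(cl$category, "nontemplated_3p")
  # 5' templated extension
  prevb <- substr(HAIRPIN, MAT_OFF, MAT_OFF)
  cl <- classify_read(MAT_OFF - 1L, paste0(prevb, MATURE), MAT_OFF, MAT_LEN,
                      HAIRPIN)
  expect_equal(cl$category, "templated_5p")
  expect_equal(cl$five_prime_offset, -1L)
  expect_true(cl$seed_affected)
})

test_that("internal substitutions make a read polymorphic regardless of ends", {
  read <- MATURE
  substr(read, 12, 12) <- setdiff(c("A", "C", "G", "U"),
                                  substr(MATURE, 12, 12))[1]
  cl <- classify_read(MAT_OFF, read, MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl$category, "polymorphic")
  expect_equal(cl$substitutions, 12L)
  expect_false(cl$seed_affected)
  # substitution in the seed flags seed_affected
  read2 <- MATURE
  substr(read2, 4, 4) <- setdiff(c("A", "C", "G", "U"),
                                 substr(MATURE, 4, 4))[1]
  cl2 <- classify_read(MAT_OFF, read2, MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl2$category, "polymorphic")
  expect_true(cl2$seed_affected)
  # polymorphic wins over end variation
  read3 <- paste0(substr(read, 2, MAT_LEN), "A")
  cl3 <- classify_read(MAT_OFF + 1L, read3, MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl3$category, "polymorphic")
})

test_that("variation at both ends is a both-ends category", {
  prevb <- substr(HAIRPIN, MAT_OFF, MAT_OFF)
  nextb <- substr(HAIRPIN, MAT_OFF + MAT_LEN + 1, MAT_OFF + MAT_LEN + 1)
  cl <- classify_read(MAT_OFF - 1L, paste0(prevb, MATURE, nextb),
                      MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl$category, "both_ends_templated")
  ntb <- setdiff(c("A", "C", "G", "U"), nextb)[1]
  cl <- classify_read(MAT_OFF - 1L, paste0(prevb, MATURE, ntb),
                      MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl$category, "both_ends_nontemplated")
  # truncations at both ends stay templated
  cl <- classify_read(MAT_OFF + 1L, substr(MATURE, 2, MAT_LEN - 1),
                      MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl$category, "both_ends_templated")
})

test_that("reads outside the mature interval are unassigned, not classified", {
  loop_read <- substr(HAIRPIN, 41, 58)
  cl <- classify_read(40L, loop_read, MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(cl$category, "unassigned")
  stacks <- data.frame(precursor_id = "p", library = "LV",
                       start = c(MAT_OFF, 40L),
                       sequence = c(MATURE, loop_read),
                       count = c(10L, 5L), mismatches = "")
  prec <- prec_table(prec_row("p", sequence = HAIRPIN,
                              mature_offset = MAT_OFF,
                              mature_len = MAT_LEN))
  cls <- classify_stacks(stacks, prec)
  expect_equal(cls$category, c("reference", "unassigned"))
  smry <- summarize_isomirs(cls)
  expect_equal(smry$unassigned_reads, 5)
  expect_equal(smry$fractions$reference, c(1, 1))
})

test_that("classification matches the per-base oracle on random small stacks", {
  set.seed(13)
  for (rep_i in 1:40) {
    plen <- sample(55:80, 1)
    prec <- paste(sample(c("A", "C", "G", "U"), plen, TRUE), collapse = "")
    m_off <- sample(4:8, 1)
    m_len <- sample(18:24, 1)
    n_reads <- sample(1:30, 1)
    for (r in seq_len(n_reads)) {
      start <- m_off + sample(-3:3, 1)
      L <- m_len + sample(-3:3, 1)
      start <- max(0L, start)
      L <- min(L, plen - start)
      read <- substr(prec, start + 1, start + L)
      # random edits
      if (runif(1) < 0.5) {
        p <- sample(seq_len(L), 1)
        substr(read, p, p) <- sample(c("A", "C", "G", "U"), 1)
      }
      got <- classify_read(start, read, m_off, m_len, prec)
      want <- oracle_classify(start, read, m_off, m_len, prec)
      expect_equal(got$category, want$category)
      if (got$category != "unassigned") {
        expect_equal(got$five_prime_offset, want$five_prime_offset)
        expect_equal(got$three_prime_offset, want$three_prime_offset)
        expect_equal(got$substitutions, want$substitutions)
        expect_equal(got$seed_affected, want$seed_affected)
      }
    }
  }
})

test_that("every 5'-variant call is seed-affecting and categories partition reads", {
  sim <- simulate_mirnaome(small_config(seed = 8))
  cls <- classify_stacks(sim$stacks, sim$precursors)
  assigned <- cls[cls$category != "unassigned", ]
  expect_true(all(assigned$category %in% isomir_categories()))
  v5 <- assigned$five_prime_offset != 0
  expect_true(all(assigned$seed_affected[v5]))
  smry <- summarize_isomirs(cls)
  frac_cols <- isomir_categories()
  expect_equal(unname(rowSums(smry$fractions[, frac_cols])),
               rep(1, nrow(smry$fractions)), tolerance = 1e-9)
  expect_equal(sum(smry$counts[smry$counts$library == "pooled", frac_cols]),
               sum(assigned$count))
})

test_that("generator-labelled categories are recovered for every read", {
  sim <- simulate_mirnaome(small_config(seed = 17))
  cls <- classify_stacks(sim$stacks, sim$precursors)
  expect_equal(cls$category, sim$truth$reads$category)
  expect_equal(cls$arm, sim$truth$reads$arm)
})

test_that("the dominant form is the top-count variant with reference-first ties", {
  stack <- data.frame(
    precursor_id = "p", library = c("LV", "GL", "LV"),
    start = c(MAT_OFF, MAT_OFF + 1L, MAT_OFF + 1L),
    sequence = c(MATURE, substr(MATURE, 2, MAT_LEN),
                 substr(MATURE, 2, MAT_LEN)),
    count = c(500L, 600L, 300L), mismatches = "")
  top <- dominant_form(stack, MAT_OFF, MAT_LEN, HAIRPIN)
  expect_equal(top$category, "templated_5p")  # 900 beats 500
  expect_equal(top$count, 900L)

  tie <- data.frame(precursor_id = "p", library = "LV",
                    start = c(MAT_OFF, MAT_OFF + 1L),
                    sequence = c(MATURE, substr(MATURE, 2, MAT_LEN)),
                    count = c(400L, 400L), mismatches = "")
  expect_equal(dominant_form(tie, MAT_OFF, MAT_LEN, HAIRPIN)$category,
               "reference")
  single <- tie[2, ]
  expect_equal(dominant_form(single, MAT_OFF, MAT_LEN, HAIRPIN)$sequence,
               single$sequence)
  expect_error(dominant_form(tie[0, ], MAT_OFF, MAT_LEN, HAIRPIN), "empty")
})

test_that("distribution arithmetic is count-weighted", {
  prec <- prec_table(prec_row("p", sequence = HAIRPIN,
                              mature_offset = MAT_OFF,
                              mature_len = MAT_LEN))
  nextb <- substr(HAIRPIN, MAT_OFF + MAT_LEN + 1, MAT_OFF + MAT_LEN + 1)
  stacks <- data.frame(precursor_id = "p", library = "LV",
                       start = MAT_OFF,
                       sequence = c(MATURE, paste0(MATURE, nextb)),
                       count = c(60L, 40L), mismatches = "")
  smry <- summarize_isomirs(classify_stacks(stacks, prec))
  lv <- smry$fractions[smry$fractions$library == "LV", ]
  expect_equal(lv$reference, 0.6)
  expect_equal(lv$templated_3p, 0.4)
})
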