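test_that("tract location matches the first/last-occurrence definition", {
  expect_equal(locate_tract("AAGGGGCCTT"), tibble::tibble(start = 2L, end = 8L))
  expect_equal(locate_tract("GGGGCCTTTTTTGGGGCC"),
               tibble::tibble(start = 0L, end = 18L))
  expect_true(is.na(locate_tract("ACGTACGT")$start))
})

test_that("repeat counts are span-based so interrupted units still count", {
  expect_equal(count_repeats(strrep("GGGGCC", 14))$repeat_count, 14L)
  seq3 <- paste0("GGGGCC", "GGGTCC", "GGGGCC")
  got <- count_repeats(seq3)
  expect_equal(got$repeat_count, 3L)       # span 18 / 6
  expect_equal(got$exact_motif_count, 2L)  # the interrupted unit is no match
  expect_equal(got$tract_span, 18L)
})

test_that("purity metrics match hand counts", {
  pure <- repeat_purity(strrep("GGGGCC", 10))
  expect_equal(pure$gc_fraction, 1)
  expect_equal(pure$motif_fraction, 1)
  got <- repeat_purity(paste0("GGGGCC", "GGGTCC", "GGGGCC"))
  expect_equal(got$gc_fraction, 17 / 18)
  expect_equal(got$motif_fraction, 12 / 18)
})

test_that("location, counting and purity agree with a sliding-window oracle", {
  set.seed(12)
  for (i in 1:400) {
    n_units <- sample(1:20, 1)
    units <- rep("GGGGCC", n_units)
    # random interruptions: substitution or deletion inside random units
    n_int <- rbinom(1, n_units, 0.15)
    for (p in sample(n_units, n_int)) {
      j <- sample(6, 1)
      if (runif(1) < 0.5) substr(units[p], j, j) <- sample(c("A", "T"), 1)
      else units[p] <- paste0(substr(units[p], 1, j - 1), substr(units[p], j + 1, 6))
    }
    seq <- paste0(
      paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), TRUE), collapse = ""),
      paste(units, collapse = ""),
      paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), TRUE), collapse = "")
    )
    tr <- bf_tract(seq, "GGGGCC")
    got_tr <- locate_tract(seq)
    expect_equal(c(got_tr$start, got_tr$end), tr)
    if (!is.na(tr[1])) {
      expect_equal(count_repeats(seq)$repeat_count,
                   as.integer((tr[2] - tr[1]) %/% 6))
      pur <- bf_purity(seq, "GGGGCC")
      got_pur <- repeat_purity(seq)
      expect_equal(c(got_pur$gc_fraction, got_pur$motif_fraction), pur)
    }
  }
})

test_that("with interruptions off, per-read counts recover the truth exactly", {
  co <- simulate_cohort(small_config(seed = 61, interruption_rate = 0))
  meas <- measure_repeats(co$reads)
  truth <- co$truth$true_repeat_count[match(meas$read_id, co$truth$read_id)]
  expect_identical(meas$repeat_count, truth)
  expect_true(all(meas$motif_fraction == 1))
  expect_true(all(meas$gc_fraction == 1))
})

test_that("interruptions perturb counts by a bounded amount and lower purity", {
  co <- simulate_cohort(small_config(seed = 62, interruption_rate = 0.02))
  meas <- measure_repeats(co$reads)
  idx <- match(meas$read_id, co$truth$read_id)
  truth <- co$truth$true_repeat_count[idx]
  n_int <- lengths(co$truth$true_interruption_positions)[idx]
  expect_true(all(meas$repeat_count <= truth))
  expect_true(all(meas$repeat_count >= truth - n_int - 2L))
  expect_true(all(meas$motif_fraction[n_int == 0] == 1))
  # most interrupted tracts lose purity (a few interruptions regenerate a
  # junction-spanning motif copy or sit in a terminal unit outside the tract)
  expect_lt(mean(meas$motif_fraction[n_int > 0]), 1)
})

test_that("longer expanded reads tend to be less pure", {
  co <- default_cohort() # interruption rate 1e-3 per unit
  meas <- measure_repeats(co$reads)
  exp_ids <- co$truth$read_id[co$truth$true_allele == "expanded"]
  sub <- meas[meas$read_id %in% exp_ids, ]
  res <- spearman_assoc(sub$repeat_count, sub$motif_fraction)
  expect_lt(res$estimate, 0)
})

test_that("sample summaries use max/median/range over per-read counts", {
  meas <- tibble::tibble(
    read_id = sprintf("r%d", 1:4), sample_id = c("S1", "S2", "S2", "S2"),
    allele = "expanded",
    repeat_count = c(100L, 327L, 1000L, 4088L),
    gc_fraction = c(1, 1, 0.99, 0.98),
    motif_fraction = c(1, 0.9, 0.95, 0.85)
  )
  s <- summarize_sample_repeats(meas)
  s1 <- s[s$sample_id == "S1", ]; s2 <- s[s$sample_id == "S2", ]
  expect_equal(s1$max_repeats, 100L)
  expect_equal(s1$range_repeats, 0L)
  expect_equal(s2$max_repeats, 4088L)
  expect_equal(s2$range_repeats, 4088L - 327L)
  expect_equal(s2$median_repeats, 1000)
  expect_equal(s2$median_motif_fraction, 0.9)
})
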