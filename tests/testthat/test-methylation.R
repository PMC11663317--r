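test_that("per-read summaries follow the score and threshold definitions", {
  cpg <- tibble::tibble(read_id = "r1", read_pos = c(0L, 5L, 9L, 12L),
                        score = c(0L, 255L, 255L, 255L))
  got <- summarize_read_methylation(cpg, threshold = 128)
  expect_equal(got$median_score, 255)
  expect_equal(got$prop_methylated, 0.75)

  # the boundary score is methylated under the inclusive main rule
  one <- tibble::tibble(read_id = "r1", read_pos = 0L, score = 128L)
  expect_equal(summarize_read_methylation(one, 128)$prop_methylated, 1.0)
  # ... but not under the strict alternate comparator
  expect_equal(summarize_read_methylation(one, 128, strict = TRUE)$prop_methylated, 0)

  # even CpG count: median is the mean of the two middle scores
  even <- tibble::tibble(read_id = "r1", read_pos = c(0L, 3L), score = c(10L, 20L))
  expect_equal(summarize_read_methylation(even, 128)$median_score, 15)

  expect_error(summarize_read_methylation(one, 300), "\\[0, 255\\]")
})

test_that("read and sample summaries match a naive re-count oracle", {
  set.seed(21)
  n_reads <- 2000
  cpg <- tibble::tibble(
    read_id = rep(sprintf("r%04d", seq_len(n_reads)), times = sample(1:30, n_reads, TRUE))
  )
  cpg$read_pos <- as.integer(unlist(lapply(table(cpg$read_id)[unique(cpg$read_id)],
                                           function(k) seq_len(k) * 2L)))
  cpg$score <- sample(0:255, nrow(cpg), replace = TRUE)
  got <- summarize_read_methylation(cpg, threshold = 128)

  by_read <- split(cpg$score, cpg$read_id)
  expect_equal(got$median_score,
               vapply(by_read[got$read_id], bf_median, numeric(1)), ignore_attr = TRUE)
  oracle_prop <- vapply(by_read[got$read_id],
                        function(s) sum(s >= 128) / length(s), numeric(1))
  expect_equal(got$prop_methylated, oracle_prop, ignore_attr = TRUE)

  # sample-level aggregation vs a sorting-based oracle
  got$sample_id <- rep(c("A", "B"), length.out = nrow(got))
  got$allele <- "expanded"
  samp <- summarize_sample_methylation(got)
  for (s in c("A", "B")) {
    sub <- got[got$sample_id == s, ]
    row <- samp[samp$sample_id == s, ]
    expect_equal(row$median_of_median_scores, bf_median(sub$median_score))
    expect_equal(row$median_prop_methylated, bf_median(sub$prop_methylated))
    expect_equal(row$range_prop, max(sub$prop_methylated) - min(sub$prop_methylated))
  }
})

test_that("single-read samples summarise to that read with zero range", {
  rm <- tibble::tibble(read_id = "r1", sample_id = "S", allele = "expanded",
                       n_cpgs = 5L, median_score = 100, prop_methylated = 0.4)
  s <- summarize_sample_methylation(rm)
  expect_equal(s$median_prop_methylated, 0.4)
  expect_equal(s$range_prop, 0)
  rm3 <- tibble::tibble(read_id = c("a", "b", "c"), sample_id = "S",
                        allele = "expanded", n_cpgs = 3L, median_score = 1,
                        prop_methylated = c(0.2, 0.4, 0.6))
  s3 <- summarize_sample_methylation(rm3)
  expect_equal(s3$median_prop_methylated, 0.4)
  expect_equal(s3$range_prop, 0.4)
})

test_that("proportion methylated is non-increasing in the threshold", {
  set.seed(5)
  cpg <- tibble::tibble(
    read_id = rep(sprintf("r%02d", 1:50), each = 20),
    read_pos = rep(seq_len(20) * 2L, 50),
    score = sample(0:255, 1000, replace = TRUE)
  )
  props <- vapply(c(0, 64, 128, 192, 255),
                  function(t) summarize_read_methylation(cpg, t)$prop_methylated,
                  numeric(50))
  expect_true(all(diff(t(props)) <= 0))
})

test_that("threshold comparison pairs the two rules and correlates them", {
  cmp <- default_pipeline()$thresholds
  expect_true(all(cmp$samples$prop_alt <= cmp$samples$prop_main))
  r_exp <- cmp$correlation[cmp$correlation$allele == "expanded", ]
  expect_gt(r_exp$estimate, 0.9)

  # constant proportions: correlation flagged, not crashed
  co <- small_cohort()
  keep <- filter_reads(co$reads, filter_profile("methylation_purity"))
  cpg <- co$cpg[co$cpg$read_id %in% keep$read_id, ]
  info <- tibble::tibble(
    read_id = keep$read_id, sample_id = keep$sample_id,
    allele = co$truth$true_allele[match(keep$read_id, co$truth$read_id)]
  )
  allhi <- cpg; allhi$score <- 255L
  cmp2 <- compare_thresholds(allhi, info)
  expect_true(all(cmp2$samples$prop_main == 1))
  expect_true(all(is.na(cmp2$correlation$estimate)))
  expect_match(cmp2$correlation$note, "constant")
})

test_that("waterfall matrices sort by CpG count and keep missing distinct from zero", {
  cpg <- tibble::tibble(
    read_id = rep(c("a", "b", "c"), times = c(2, 3, 5)),
    read_pos = c(0L, 2L, 0L, 2L, 4L, 0L, 2L, 4L, 6L, 8L),
    score = c(0L, 10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L)
  )
  m <- waterfall_matrix(cpg)
  expect_equal(dim(m), c(3L, 5L))
  expect_equal(rownames(m), c("c", "b", "a"))
  expect_equal(m["a", ], c(0, 10, NA, NA, NA))
  expect_equal(m["c", ], c(50, 60, 70, 80, 90))
  expect_equal(sum(is.na(m["b", ])), 2L)
  # row count conservation
  expect_equal(nrow(m), dplyr::n_distinct(cpg$read_id))
  p <- plot_waterfall(m)
  expect_s3_class(p, "ggplot")
})

test_that("tract-only CpG restriction drops exactly the flank calls", {
  co <- small_cohort()
  tc <- tract_cpgs(co$reads, co$cpg)
  tract <- locate_tract(co$reads$sequence)
  idx <- match(co$cpg$read_id, co$reads$read_id)
  expected <- sum(co$cpg$read_pos >= tract$start[idx] &
                    co$cpg$read_pos < tract$end[idx], na.rm = TRUE)
  expect_equal(nrow(tc), expected)
  expect_lt(nrow(tc), nrow(co$cpg))
})

test_that("a simulated allele contrast of 0.2+ is detected by the paired test", {
  set.seed(99)
  n_ind <- 27; n_reads <- 20
  read_meth <- purrr::map_dfr(seq_len(n_ind), function(i) {
    wt_mean <- runif(1, 0.1, 0.3)
    tibble::tibble(
      read_id = sprintf("i%02d_r%02d_%s", i, rep(1:n_reads, 2),
                        rep(c("w", "e"), each = n_reads)),
      sample_id = sprintf("S%02d", i),
      allele = rep(c("wild_type", "expanded"), each = n_reads),
      n_cpgs = 50L, median_score = 0,
      prop_methylated = pmin(1, pmax(0, rnorm(2 * n_reads,
        mean = rep(c(wt_mean, wt_mean + 0.25), each = n_reads), sd = 0.08)))
    )
  })
  samp <- summarize_sample_methylation(read_meth)
  wide <- tidyr::pivot_wider(samp[, c("sample_id", "allele", "median_prop_methylated")],
                             names_from = "allele",
                             values_from = "median_prop_methylated")
  res <- wilcoxon_paired(wide$expanded, wide$wild_type)
  expect_lt(res$p_value, 0.01)
})
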