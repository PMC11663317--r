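test_that("noise-free limit produces exact repeat tracts", {
  cfg <- sim_config(
    n_individuals = 3, expanded_modal_length = 100,
    mosaicism_dispersion = 0, interruption_rate = 0, truncation_rate = 0,
    reads_per_allele_range = c(4L, 6L), seed = 5
  )
  co <- simulate_cohort(cfg)
  exp_idx <- co$truth$true_allele == "expanded"
  expect_true(all(co$truth$true_repeat_count[exp_idx] == 100))
  expect_true(all(lengths(co$truth$true_interruption_positions) == 0))

  # the emitted tract is 100 perfect motif copies
  meas <- count_repeats(co$reads$sequence[match(co$truth$read_id[exp_idx],
                                                co$reads$read_id)])
  expect_true(all(meas$repeat_count == 100))
  expect_true(all(meas$exact_motif_count == 100))
  pur <- repeat_purity(co$reads$sequence[match(co$truth$read_id[exp_idx],
                                               co$reads$read_id)])
  expect_true(all(pur$motif_fraction == 1))
})

test_that("noise-free scores follow the mean model exactly", {
  cfg <- sim_config(
    n_individuals = 2, expanded_modal_length = 80, mosaicism_dispersion = 0,
    interruption_rate = 0, truncation_rate = 0, score_noise_sd = 0,
    expansion_meth_intercept = 0.2, expansion_meth_slope = 0,
    flank_cpg_meth_level = 0.9, reads_per_allele_range = c(3L, 4L), seed = 9
  )
  co <- simulate_cohort(cfg)
  fl_len <- cfg$flank_length
  joined <- dplyr::left_join(co$cpg, co$reads, by = "read_id")
  tract <- locate_tract(joined$sequence)
  in_tract <- joined$read_pos >= tract$start & joined$read_pos < tract$end
  near_end <- joined$read_pos < cfg$end_window |
    joined$read_pos >= nchar(joined$sequence) - cfg$end_window

  expect_true(all(joined$score[in_tract] == round(0.2 * 255)))       # 51
  expect_true(all(joined$score[!in_tract & near_end] == round(0.9 * 255))) # 230
  expect_true(all(joined$score[!in_tract & !near_end] == 51))
  expect_true(all(nchar(joined$sequence) > 2 * fl_len)) # sanity: full span
})

test_that("every CG dinucleotide gets exactly one CpG call", {
  co <- small_cohort()
  n_cg <- stringr::str_count(co$reads$sequence, stringr::fixed("CG"))
  calls <- dplyr::count(co$cpg, read_id)
  got <- calls$n[match(co$reads$read_id, calls$read_id)]
  got[is.na(got)] <- 0L
  expect_equal(got, n_cg)
  # and every call sits on a C followed by G
  expect_silent(c9methyl:::validate_cpg_positions(co$reads, co$cpg))
})

test_that("identical configs give byte-identical fixtures", {
  a <- simulate_cohort(small_config(seed = 77))
  b <- simulate_cohort(small_config(seed = 77))
  expect_identical(a$reads, b$reads)
  expect_identical(a$cpg, b$cpg)
  expect_identical(a$meta, b$meta)

  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(a, d1); write_fixture(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("expanded per-read lengths are right-skewed under mosaicism", {
  co <- default_cohort()
  x <- co$truth$true_repeat_count[co$truth$true_allele == "expanded"]
  expect_gt(mean(x), median(x))
  # skew also holds within individuals (direct computation on the truth table)
  by_ind <- split(x, co$truth$individual_id[co$truth$true_allele == "expanded"])
  frac_skewed <- mean(vapply(by_ind, function(v) mean(v) > median(v), logical(1)))
  expect_gt(frac_skewed, 0.7)
})

test_that("with positive slope and no noise, mean expansion score increases with repeat count", {
  cfg <- sim_config(
    n_individuals = 4, expanded_modal_length = c(100, 300, 900, 2000),
    interruption_rate = 0, truncation_rate = 0, score_noise_sd = 0,
    reads_per_allele_range = c(3L, 5L), seed = 13
  )
  co <- simulate_cohort(cfg)
  exp_truth <- co$truth[co$truth$true_allele == "expanded", ]
  # tract-CpG probability per read (flank probs differ; take the modal value)
  tract_prob <- vapply(exp_truth$true_per_cpg_meth_prob, function(p) {
    tb <- table(p); as.numeric(names(tb)[which.max(tb)])
  }, numeric(1))
  ord <- order(exp_truth$true_repeat_count)
  distinct <- !duplicated(exp_truth$true_repeat_count[ord])
  expect_true(all(diff(tract_prob[ord][distinct]) > 0))
  expect_equal(tract_prob,
               pmin(1, 0.21 + cfg$expansion_meth_slope * exp_truth$true_repeat_count),
               tolerance = 1e-12)
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(wt_repeat_range = c(1, 30), seed = 1), "2, 30")
  expect_error(sim_config(expanded_modal_length = 40, seed = 1), ">= 64")
  expect_error(sim_config(interruption_rate = 1.5, seed = 1), "\\[0, 1\\]")
  expect_error(sim_config(n_individuals = 0, seed = 1), "positive")
  expect_error(sim_config(reads_per_allele_range = c(5, 2), seed = 1), "increasing")
  expect_error(simulate_cohort(sim_config(n_individuals = 2)), "seed")
})

test_that("truncated reads are marked as not spanning", {
  cfg <- small_config(seed = 3, truncation_rate = 0.4)
  co <- simulate_cohort(cfg)
  expect_gt(sum(!co$truth$true_spans_left | !co$truth$true_spans_right), 0)
  expect_identical(co$reads$spans_left_flank, co$truth$true_spans_left)
  expect_identical(co$reads$spans_right_flank, co$truth$true_spans_right)
})
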