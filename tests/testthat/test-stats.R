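test_that("spearman correlation is monotone-invariant and handles ties", {
  expect_equal(spearman_assoc(1:10, 2 * (1:10))$estimate, 1)
  expect_equal(spearman_assoc(1:10, rev(1:10))$estimate, -1)
  # invariant under strictly monotone transforms
  set.seed(7)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_assoc(x, y)$estimate,
               spearman_assoc(exp(x), y^3 + 5 * y)$estimate)
  # ties: matches the tie-averaged rank formula computed by hand
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6, 7, 9)
  expect_equal(spearman_assoc(xt, yt)$estimate, bf_spearman_rho(xt, yt))
  # degenerate inputs
  expect_match(spearman_assoc(rep(1, 5), 1:5)$note, "constant")
  expect_match(spearman_assoc(1:2, 2:1)$note, "fewer than 3")
})

test_that("the paired signed-rank test matches exact enumeration", {
  a <- c(1, 2, 3)
  expect_warning(res <- wilcoxon_paired(a, a), "zero")
  expect_equal(res$p_value, 1)

  set.seed(11)
  b <- rnorm(27)
  res_shift <- wilcoxon_paired(b + 1, b)
  expect_lt(res_shift$p_value, 0.001)

  cache <- new.env()
  for (i in 1:25) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_paired(x, y)
    expect_equal(got$p_value, bf_signrank_p(x - y, cache), tolerance = 1e-12)
  }
})

test_that("the rank-sum test matches exact enumeration", {
  expect_gt(wilcoxon_unpaired(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  # fully separated groups of 5: exact two-sided p = 2 / choose(10, 5)
  expect_equal(wilcoxon_unpaired(1:5, 11:15)$p_value, 2 / 252, tolerance = 1e-12)
  cache <- new.env()
  for (i in 1:25) {
    n <- sample(3:7, 1); m <- sample(3:7, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(wilcoxon_unpaired(x, y)$p_value, bf_ranksum_p(x, y, cache),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_unpaired(numeric(0), 1:3), "non-empty")
})

test_that("age-adjusted regression recovers exact and closed-form coefficients", {
  set.seed(3)
  df <- tibble::tibble(
    age = runif(30, 40, 70),
    group = sample(c(TRUE, FALSE), 30, replace = TRUE)
  )
  df$y <- 2 * df$age
  got <- suppressWarnings(adjusted_group_test(df, "y", "group", "age")) # perfect fit

  expect_equal(got$estimate[got$statistic_name == "y~age"], 2, tolerance = 1e-10)
  expect_equal(got$estimate[got$statistic_name == "y~groupTRUE"], 0, tolerance = 1e-10)

  df$y <- 0.5 * df$age + 2 * df$group + rnorm(30)
  got2 <- adjusted_group_test(df, "y", "group", "age")
  X <- cbind(1, as.numeric(df$group), df$age)
  expect_equal(got2$estimate, bf_ols(X, df$y), tolerance = 1e-10)

  df$age2 <- df$age # collinear copy
  expect_error(adjusted_group_test(
    dplyr::mutate(df, group = age), "y", "group", "age"
  ), "[Ss]ingular|collinear")
})

test_that("longitudinal series classify by total change against the 10% rule", {
  data <- tibble::tibble(
    individual_id = c("a", "a", "b", "b", "c"),
    timepoint_years = c(0, 2, 0, 2, 0),
    prop = c(0.40, 0.45, 0.40, 0.55, 0.5)
  )
  got <- classify_longitudinal(data, "prop")
  expect_equal(got$classification[got$individual_id == "a"], "stable")
  expect_equal(got$classification[got$individual_id == "b"], "variable")
  expect_equal(got$classification[got$individual_id == "c"], "not_classified")
  # relative variant
  rel <- classify_longitudinal(data, "prop", threshold = 0.2, relative = TRUE)
  expect_equal(rel$classification[rel$individual_id == "a"], "stable")
  expect_equal(rel$classification[rel$individual_id == "b"], "variable")
})

test_that("transmissions classify by the signed 10% change", {
  expect_equal(classify_transmission(0.50, 0.35), "decrease")
  expect_equal(classify_transmission(0.50, 0.45), "stable")
  expect_equal(classify_transmission(0.30, 0.45), "increase")
  expect_equal(classify_transmission(0.50, 0.40), "decrease") # boundary >= 0.10
  # constructed drops are all recovered
  set.seed(2)
  parent <- runif(7, 0.4, 0.6)
  child <- parent - runif(7, 0.12, 0.3)
  expect_equal(classify_transmission(parent, child), rep("decrease", 7))
})

test_that("the promoter hypermethylation contrast reports medians and guards small groups", {
  set.seed(8)
  y <- runif(27, 0.1, 0.5)
  flag <- rep(c(TRUE, FALSE), c(9, 18))
  shifted <- y + 0.2 * flag
  res <- hypermethylation_contrast(shifted, flag)
  expect_lt(res$test$p_value, 0.05)
  expect_equal(nrow(res$groups), 2)

  single <- hypermethylation_contrast(y, c(TRUE, rep(FALSE, 26)))
  expect_true(is.na(single$test$p_value))
  expect_match(single$test$note, "not testable")
  expect_equal(nrow(single$groups), 2)
})
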