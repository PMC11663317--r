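# tidy one-row association result
assoc_row <- function(name, method, estimate = NA_real_, statistic = NA_real_,
                      p_value = NA_real_, n = NA_integer_, note = NA_character_) {
  tibble(statistic_name = name, method = method, estimate = estimate,
         statistic = statistic, p_value = p_value, n = as.integer(n), note = note)
}

#' Spearman rank correlation
#'
#' Two-sided Spearman correlation with average ranks for ties. Constant
#' vectors or fewer than 3 complete pairs yield an `NA` result with an
#' explanatory note instead of an error, so that batteries of associations
#' run to completion.
#'
#' @param x,y Paired numeric vectors.
#' @param name Label stored in `statistic_name`.
#' @return A one-row tibble (`statistic_name`, `method`, `estimate` = rho,
#'   `statistic` = S, `p_value`, `n`, `note`).
#' @examples
#' spearman_assoc(1:10, (1:10)^3)$estimate # 1
#' @export
spearman_assoc <- function(x, y, name = "spearman") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(assoc_row(name, "spearman", n = n, note = "fewer than 3 complete pairs"))
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(assoc_row(name, "spearman", n = n, note = "constant input: correlation undefined"))
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", alternative = "two.sided"))
  assoc_row(name, "spearman", estimate = unname(ht$estimate),
            statistic = unname(ht$statistic), p_value = ht$p.value, n = n)
}

#' Paired Wilcoxon (signed-rank) test
#'
#' Two-sided signed-rank test on within-individual differences, dropping
#' zero differences. Exact p-values are used for up to `exact_max`
#' non-zero differences without ties in their absolute values; otherwise
#' the normal approximation with continuity correction.
#'
#' @param a,b Paired per-individual values (same individuals, same order).
#' @param name Label for the result row.
#' @param exact_max Largest n for which the exact null distribution is used.
#' @return A one-row tibble; `statistic` is the signed-rank statistic V.
#' @export
wilcoxon_paired <- function(a, b, name = "wilcoxon_paired", exact_max = 25L) {
  if (length(a) != length(b)) abort("Paired vectors must have equal length.")
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  d <- a - b
  nz <- d != 0
  if (!any(nz)) {
    warn("All paired differences are zero; p = 1.")
    return(assoc_row(name, "wilcoxon_paired", estimate = 0, statistic = NA_real_,
                     p_value = 1, n = length(d), note = "all differences zero"))
  }
  n_eff <- sum(nz)
  ties <- anyDuplicated(abs(d[nz])) > 0
  exact <- n_eff <= exact_max && !ties
  ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                     correct = TRUE, alternative = "two.sided"))
  assoc_row(name, "wilcoxon_paired", estimate = median(d),
            statistic = unname(ht$statistic), p_value = ht$p.value,
            n = length(d))
}

#' Unpaired Wilcoxon rank-sum test
#'
#' @param a,b Values of the two independent groups.
#' @param name Label for the result row.
#' @param exact Passed to [stats::wilcox.test()]; default lets R choose
#'   (exact for small samples without ties).
#' @return A one-row tibble; `estimate` is the difference of group medians.
#' @export
wilcoxon_unpaired <- function(a, b, name = "wilcoxon_unpaired", exact = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  assoc_row(name, "wilcoxon_unpaired", estimate = median(a) - median(b),
            statistic = unname(ht$statistic), p_value = ht$p.value,
            n = length(a) + length(b))
}

#' Age-adjusted group comparison by linear regression
#'
#' Ordinary least squares of `response ~ group + age` with two-sided
#' coefficient t-tests, used to ask whether a symptomatic-versus-
#' presymptomatic difference survives adjustment for age at collection.
#'
#' @param data A data frame.
#' @param response,group,age Column names (strings).
#' @return A tibble with one row per model coefficient (method
#'   `linear_regression`), carrying `estimate`, `statistic` (t), `p_value`.
#' @export
adjusted_group_test <- function(data, response, group, age) {
  if (nrow(data) <= 3L) abort("Need more than 3 observations for the adjusted model.")
  f <- stats::reformulate(c(group, age), response = response)
  fit <- lm(f, data = data)
  if (anyNA(coef(fit))) {
    abort("Singular design in adjusted group test (collinear group and age?).")
  }
  broom::tidy(fit) |>
    transmute(
      statistic_name = paste0(response, "~", .data$term),
      method = "linear_regression",
      estimate = .data$estimate,
      statistic = .data$statistic,
      p_value = .data$p.value,
      n = nrow(data),
      note = NA_character_
    )
}

#' Classify longitudinal stability of a per-individual series
#'
#' An individual's series over time is `stable` when its total change
#' (maximum minus minimum) is below `threshold` (default 0.10, i.e. a 10%
#' change in absolute proportion units). With `relative = TRUE` the change
#' is taken relative to the earliest value instead. Individuals with a
#' single timepoint are `not_classified`.
#'
#' @param data Long tibble of per-sample values.
#' @param value Column holding the measured value (string).
#' @param individual,time Column names of individual id and timepoint.
#' @param threshold Change threshold.
#' @param relative Interpret `threshold` relative to the earliest value.
#' @return A tibble per individual: `n_timepoints`, `change`,
#'   `classification` (`stable` / `variable` / `not_classified`).
#' @export
classify_longitudinal <- function(data, value, individual = "individual_id",
                                  time = "timepoint_years",
                                  threshold = 0.10, relative = FALSE) {
  data |>
    group_by(.data[[individual]]) |>
    arrange(.data[[time]], .by_group = TRUE) |>
    summarise(
      n_timepoints = dplyr::n(),
      change = {
        v <- .data[[value]]
        ch <- max(v) - min(v)
        if (relative) ch / v[1] else ch
      },
      .groups = "drop"
    ) |>
    mutate(classification = dplyr::case_when(
      .data$n_timepoints < 2L ~ "not_classified",
      .data$change < threshold - 1e-9 ~ "stable", # tolerance: 0.15 - 0.05 must not miss the boundary
      TRUE ~ "variable"
    ))
}

#' Classify a parent-to-offspring transmission
#'
#' `decrease` when the offspring's value is lower than the parent's by at
#' least `threshold` (default a 10% change in absolute proportion units),
#' `increase` for the symmetric rise, otherwise `stable`.
#'
#' @param parent_value,child_value Numeric vectors (pairs).
#' @param threshold Change threshold.
#' @param relative Interpret the change relative to the parent value.
#' @return Character vector in `{decrease, stable, increase}`.
#' @examples
#' classify_transmission(0.50, 0.35) # "decrease"
#' @export
classify_transmission <- function(parent_value, child_value,
                                  threshold = 0.10, relative = FALSE) {
  d <- parent_value - child_value
  if (relative) d <- d / parent_value
  # numeric tolerance so that e.g. 0.50 - 0.40 lands on the 0.10 boundary
  dplyr::case_when(
    d >= threshold - 1e-9 ~ "decrease",
    -d >= threshold - 1e-9 ~ "increase",
    TRUE ~ "stable"
  )
}

#' Expansion methylation by promoter hypermethylation status
#'
#' Unpaired Wilcoxon test of expansion methylation proportions between
#' individuals with and without promoter hypermethylation, with group
#' medians and ranges. With fewer than 2 individuals in a group the medians
#' are still reported but the test is skipped.
#'
#' @param values Expansion methylation proportions (one per individual).
#' @param hypermethylated Logical flag per individual.
#' @return A list with `test` (one-row tibble) and `groups` (medians and
#'   ranges per flag level).
#' @export
hypermethylation_contrast <- function(values, hypermethylated) {
  ok <- complete.cases(values, hypermethylated)
  values <- values[ok]; hypermethylated <- hypermethylated[ok]
  groups <- tibble(hypermethylated = hypermethylated, value = values) |>
    group_by(.data$hypermethylated) |>
    summarise(n = dplyr::n(), median = median(.data$value),
              min = min(.data$value), max = max(.data$value), .groups = "drop")
  n_hi <- sum(hypermethylated); n_lo <- sum(!hypermethylated)
  test <- if (n_hi >= 2L && n_lo >= 2L) {
    wilcoxon_unpaired(values[hypermethylated], values[!hypermethylated],
                      name = "meth_by_promoter_hypermethylation")
  } else {
    assoc_row("meth_by_promoter_hypermethylation", "wilcoxon_unpaired",
              n = n_hi + n_lo, note = "a group has fewer than 2 individuals: not testable")
  }
  list(test = test, groups = groups)
}
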