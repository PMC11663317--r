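#' Run the cohort association battery
#'
#' Assembles the full set of cohort-level analyses from per-sample
#' methylation and repeat summaries plus sample metadata: paired
#' expanded-versus-wild-type contrasts, methylation/length/age/onset/
#' promoter Spearman correlations, the unadjusted and age-adjusted
#' symptomatic-versus-presymptomatic comparisons, somatic-variability
#' correlations (range versus maximum, range versus Southern smear),
#' Southern-blot concordance, purity-versus-length, the promoter
#' hypermethylation contrast, wild-type genotype concordance, longitudinal
#' stability classification, familial transmission classification, and --
#' when the metadata contains more than one tissue -- blood-versus-tissue
#' contrasts. Cross-sectional rows use each individual's earliest blood
#' sample.
#'
#' @param sample_meth Output of [summarize_sample_methylation()].
#' @param sample_repeats Output of [summarize_sample_repeats()] from the
#'   length-profile branch.
#' @param meta Sample metadata (see [simulate_cohort()]).
#' @param sample_purity Optional [summarize_sample_repeats()] output from
#'   the stricter methylation/purity branch; defaults to `sample_repeats`.
#' @param extra_rows Optional pre-computed association rows (e.g. the
#'   threshold-comparison correlations) appended to the battery table.
#' @param threshold Change threshold for the longitudinal and familial
#'   classifications (absolute proportion units).
#' @param relative Interpret `threshold` as relative change instead.
#' @return A list of tibbles: `associations`, `longitudinal`,
#'   `transmissions`, `hypermethylation_groups`.
#' @export
run_associations <- function(sample_meth, sample_repeats, meta,
                             sample_purity = NULL, extra_rows = NULL,
                             threshold = 0.10, relative = FALSE) {
  sample_purity <- sample_purity %||% sample_repeats
  ref_tissue <- if ("tissue" %in% names(meta)) {
    if ("blood" %in% meta$tissue) "blood" else meta$tissue[1]
  } else "blood"
  meta <- meta |> mutate(
    tissue = if ("tissue" %in% names(meta)) .data$tissue else ref_tissue,
    symptomatic = .data$group != "presymptomatic"
  )

  baseline <- meta |>
    filter(.data$tissue == ref_tissue) |>
    group_by(.data$individual_id) |>
    slice_min(.data$timepoint_years, n = 1, with_ties = FALSE) |>
    ungroup()

  wide <- baseline |>
    left_join(meth_wide(sample_meth), by = "sample_id") |>
    left_join(repeats_wide(sample_repeats), by = "sample_id") |>
    left_join(purity_wide(sample_purity), by = "sample_id")

  rows <- list()
  add <- function(x) rows[[length(rows) + 1L]] <<- x

  add(wilcoxon_paired(wide$exp_median_score, wide$wt_median_score,
                      name = "meth_score_expanded_vs_wt"))
  add(wilcoxon_paired(wide$exp_prop, wide$wt_prop,
                      name = "meth_prop_expanded_vs_wt"))
  add(spearman_assoc(wide$exp_prop, wide$exp_max_repeats, "meth_prop_vs_max_repeats"))
  add(spearman_assoc(wide$exp_median_score, wide$exp_max_repeats, "meth_score_vs_max_repeats"))
  add(spearman_assoc(wide$exp_prop, wide$age_at_collection, "meth_prop_vs_age"))
  sym <- wide |> filter(.data$symptomatic)
  add(spearman_assoc(sym$exp_prop, sym$age_at_onset, "meth_prop_vs_onset"))
  if ("promoter_methylation" %in% names(wide)) {
    add(spearman_assoc(wide$exp_prop, wide$promoter_methylation, "meth_prop_vs_promoter"))
  }

  hyper <- if ("promoter_hypermethylated" %in% names(wide)) {
    hypermethylation_contrast(wide$exp_prop, wide$promoter_hypermethylated)
  } else {
    list(test = NULL, groups = tibble())
  }
  if (!is.null(hyper$test)) add(hyper$test)

  add(wilcoxon_unpaired(wide$exp_prop[wide$symptomatic],
                        wide$exp_prop[!wide$symptomatic],
                        name = "meth_prop_group_unadjusted"))
  add(adjusted_group_test(wide, "exp_prop", "symptomatic", "age_at_collection"))

  add(spearman_assoc(wide$exp_max_repeats, wide$age_at_collection, "length_vs_age"))
  add(wilcoxon_unpaired(wide$exp_max_repeats[wide$symptomatic],
                        wide$exp_max_repeats[!wide$symptomatic],
                        name = "length_group_unadjusted"))
  add(adjusted_group_test(wide, "exp_max_repeats", "symptomatic", "age_at_collection"))

  add(spearman_assoc(wide$exp_range_repeats, wide$exp_max_repeats, "repeat_range_vs_max"))
  if ("southern_repeats" %in% names(wide)) {
    add(spearman_assoc(wide$exp_max_repeats, wide$southern_repeats, "length_vs_southern"))
  }
  if ("southern_smear" %in% names(wide)) {
    add(spearman_assoc(wide$exp_range_repeats, wide$southern_smear, "repeat_range_vs_smear"))
  }
  add(spearman_assoc(wide$exp_median_motif, wide$exp_max_repeats, "purity_vs_length"))
  add(spearman_assoc(wide$exp_prop, wide$exp_median_motif, "meth_prop_vs_purity"))

  if ("wt_genotype" %in% names(wide)) {
    conc <- mean(wide$wt_median_repeats == wide$wt_genotype, na.rm = TRUE)
    add(assoc_row("wt_genotype_concordance", "concordance", estimate = conc,
                  n = sum(!is.na(wide$wt_median_repeats) & !is.na(wide$wt_genotype))))
  }

  if (dplyr::n_distinct(meta$tissue) > 1L) {
    add(tissue_contrasts(sample_meth, sample_repeats, sample_purity, meta, ref_tissue))
  }

  if (!is.null(extra_rows)) add(extra_rows)
  associations <- bind_rows(rows)

  # longitudinal stability on all reference-tissue samples of the expanded allele
  long_data <- meta |>
    filter(.data$tissue == ref_tissue) |>
    left_join(meth_wide(sample_meth), by = "sample_id") |>
    filter(!is.na(.data$exp_prop))
  longitudinal <- classify_longitudinal(long_data, "exp_prop",
                                        threshold = threshold, relative = relative)

  transmissions <- transmission_table(wide, threshold, relative)

  list(associations = associations, longitudinal = longitudinal,
       transmissions = transmissions, hypermethylation_groups = hyper$groups)
}

meth_wide <- function(sample_meth) {
  sample_meth |>
    select("sample_id", "allele", "median_of_median_scores",
           "median_prop_methylated", "range_prop") |>
    tidyr::pivot_wider(
      names_from = "allele",
      values_from = c("median_of_median_scores", "median_prop_methylated", "range_prop")
    ) |>
    rename_with(~ c(
      median_of_median_scores_expanded = "exp_median_score",
      median_of_median_scores_wild_type = "wt_median_score",
      median_prop_methylated_expanded = "exp_prop",
      median_prop_methylated_wild_type = "wt_prop",
      range_prop_expanded = "exp_range_prop",
      range_prop_wild_type = "wt_range_prop"
    )[.x], .cols = -"sample_id")
}

repeats_wide <- function(sample_repeats) {
  sample_repeats |>
    filter(.data$allele == "expanded") |>
    select("sample_id", exp_max_repeats = "max_repeats",
           exp_median_repeats = "median_repeats",
           exp_range_repeats = "range_repeats") |>
    left_join(
      sample_repeats |>
        filter(.data$allele == "wild_type") |>
        select("sample_id", wt_median_repeats = "median_repeats"),
      by = "sample_id"
    )
}

purity_wide <- function(sample_purity) {
  sample_purity |>
    filter(.data$allele == "expanded") |>
    select("sample_id", exp_median_gc = "median_gc",
           exp_median_motif = "median_motif_fraction")
}

tissue_contrasts <- function(sample_meth, sample_repeats, sample_purity, meta, ref_tissue) {
  other <- setdiff(unique(meta$tissue), ref_tissue)[1]
  base_by_tissue <- meta |>
    group_by(.data$individual_id, .data$tissue) |>
    slice_min(.data$timepoint_years, n = 1, with_ties = FALSE) |>
    ungroup() |>
    left_join(meth_wide(sample_meth), by = "sample_id") |>
    left_join(repeats_wide(sample_repeats), by = "sample_id") |>
    left_join(purity_wide(sample_purity), by = "sample_id")
  a <- base_by_tissue |> filter(.data$tissue == ref_tissue)
  b <- base_by_tissue |> filter(.data$tissue == other)
  ctr <- function(col, nm) wilcoxon_unpaired(a[[col]], b[[col]], name = nm)
  bind_rows(
    ctr("exp_prop", "tissue_meth_prop_expanded"),
    ctr("wt_prop", "tissue_meth_prop_wt"),
    ctr("exp_range_prop", "tissue_meth_range_expanded"),
    ctr("wt_range_prop", "tissue_meth_range_wt"),
    ctr("exp_max_repeats", "tissue_length_expanded"),
    ctr("exp_range_repeats", "tissue_length_range_expanded"),
    ctr("exp_median_motif", "tissue_purity_expanded")
  )
}

transmission_table <- function(wide, threshold, relative) {
  if (!"father_id" %in% names(wide)) {
    return(tibble(pedigree_id = character(0), father_id = character(0),
                  child_id = character(0)))
  }
  kids <- wide |> filter(!is.na(.data$father_id))
  if (!nrow(kids)) {
    return(tibble(pedigree_id = character(0), father_id = character(0),
                  child_id = character(0)))
  }
  fathers <- wide |>
    select(father_id = "individual_id", father_prop = "exp_prop",
           father_max_repeats = "exp_max_repeats")
  tr <- kids |>
    select("pedigree_id", "father_id", child_id = "individual_id",
           child_prop = "exp_prop", child_max_repeats = "exp_max_repeats") |>
    left_join(fathers, by = "father_id")
  skipped <- is.na(tr$father_prop) | is.na(tr$child_prop)
  if (any(skipped)) {
    inform(paste0(sum(skipped), " transmission(s) skipped: missing a parent or child measurement."))
    tr <- tr[!skipped, , drop = FALSE]
  }
  tr |>
    mutate(
      meth_classification = classify_transmission(.data$father_prop, .data$child_prop,
                                                  threshold, relative),
      length_change = .data$child_max_repeats - .data$father_max_repeats
    ) |>
    relocate("pedigree_id", "father_id", "child_id")
}
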