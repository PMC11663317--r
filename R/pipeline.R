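#' Run the full analysis pipeline
#'
#' Executes the two-branch analysis on a cohort: reads are filtered with the
#' methylation/purity profile (7 passes, 99% accuracy) for methylation and
#' sequence-purity metrics, and independently with the length profile
#' (1 pass, 80% accuracy) for repeat sizing; each branch is allele-assigned
#' by k-mer k-means; the association battery then runs on the per-sample
#' summaries. All tables are written as TSV together with a JSON run
#' manifest (package version, seed, per-stage read counts). Re-running with
#' the same seed overwrites the outputs deterministically.
#'
#' @param input A `c9_cohort` object or a fixture directory path
#'   (see [write_fixture()]).
#' @param output_dir Output directory, created if needed.
#' @param seed Integer seed for the clustering restarts.
#' @param k k-mer length for allele assignment.
#' @param threshold,t2 Main (inclusive) and alternate (strict) methylation
#'   call thresholds.
#' @param flank_length Flank length defining the locus anchors; taken from
#'   the cohort's config when available.
#' @param change_threshold,relative Longitudinal/familial change rule.
#' @param plots Also write PNG figures.
#' @return Invisibly, a `c9_pipeline` list with all result tables and the
#'   manifest.
#' @export
run_pipeline <- function(input, output_dir, seed = 1L, k = 6L,
                         threshold = 128L, t2 = 192L, flank_length = NULL,
                         change_threshold = 0.10, relative = FALSE,
                         plots = FALSE) {
  cohort <- if (inherits(input, "c9_cohort")) input else read_fixture(input)
  flank_length <- flank_length %||%
    (if (!is.null(cohort$config)) cohort$config$flank_length else 120L)
  anchors <- locus_anchors(flank_length)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  reads <- cohort$reads
  sp <- spans_locus(reads$sequence, anchors$left, anchors$right, each_side = TRUE)
  reads$spans_left_flank <- sp$left
  reads$spans_right_flank <- sp$right

  # branch A: methylation + purity (stringent consensus profile)
  prof_meth <- filter_profile("methylation_purity")
  reads_meth <- filter_reads(reads, prof_meth)
  qc <- bind_rows(read_qc(reads, prof_meth), read_qc(reads, filter_profile("length")))
  alleles_meth <- assign_alleles(reads_meth, k = k, seed = seed, anchors = anchors)
  cpg_meth <- cohort$cpg |> filter(.data$read_id %in% reads_meth$read_id)
  read_info <- reads_meth |> select("read_id", "sample_id") |>
    left_join(alleles_meth |> select("read_id", "allele"), by = "read_id")
  read_meth <- summarize_read_methylation(cpg_meth, threshold = threshold,
                                          reads = reads_meth) |>
    left_join(read_info, by = "read_id")
  sample_meth <- summarize_sample_methylation(read_meth)
  thresholds <- compare_thresholds(cpg_meth, read_info, t1 = threshold, t2 = t2)
  purity_meas <- measure_repeats(reads_meth, alleles_meth)
  sample_purity <- summarize_sample_repeats(purity_meas)

  # branch B: repeat length (permissive consensus profile)
  prof_len <- filter_profile("length")
  reads_len <- filter_reads(reads, prof_len)
  alleles_len <- assign_alleles(reads_len, k = k, seed = seed, anchors = anchors)
  repeat_meas <- measure_repeats(reads_len, alleles_len)
  sample_repeats <- summarize_sample_repeats(repeat_meas)

  assoc <- if (is.null(cohort$meta)) {
    inform("No sample metadata: association battery skipped.")
    list(associations = tibble(), longitudinal = tibble(),
         transmissions = tibble(), hypermethylation_groups = tibble())
  } else {
    run_associations(sample_meth, sample_repeats, cohort$meta,
                     sample_purity = sample_purity,
                     extra_rows = thresholds$correlation,
                     threshold = change_threshold, relative = relative)
  }

  # waterfall matrices for the sample with the deepest expanded coverage
  wf_sample <- sample_meth |>
    filter(.data$allele == "expanded") |>
    slice_max(.data$n_reads, n = 1, with_ties = FALSE) |>
    dplyr::pull("sample_id")
  wf <- purrr::map(setNames(c("expanded", "wild_type"), c("expanded", "wild_type")),
                   function(al) {
    ids <- read_info$read_id[read_info$sample_id %in% wf_sample & read_info$allele == al]
    waterfall_matrix(cpg_meth, ids)
  })

  out <- function(x, f) readr::write_tsv(x, file.path(output_dir, f))
  out(reads |> select(-"sequence"), "reads_qc_input.tsv")
  out(qc, "read_qc.tsv")
  out(alleles_meth, "alleles_methylation_branch.tsv")
  out(alleles_len, "alleles_length_branch.tsv")
  out(read_meth, "read_methylation.tsv")
  out(sample_meth, "sample_methylation.tsv")
  out(thresholds$samples, "threshold_comparison.tsv")
  out(purity_meas, "purity_measurements.tsv")
  out(sample_purity, "sample_purity.tsv")
  out(repeat_meas, "repeat_measurements.tsv")
  out(sample_repeats, "sample_repeats.tsv")
  out(assoc$associations, "associations.tsv")
  out(assoc$longitudinal, "longitudinal_classification.tsv")
  out(assoc$transmissions, "transmissions.tsv")
  out(assoc$hypermethylation_groups, "hypermethylation_groups.tsv")
  for (al in names(wf)) {
    m <- wf[[al]]
    df <- as.data.frame(m)
    if (nrow(df)) df <- cbind(read_id = rownames(m), df)
    readr::write_tsv(df, file.path(output_dir, paste0("waterfall_", al, ".tsv")))
  }

  manifest <- list(
    package = "c9methyl",
    version = as.character(utils::packageVersion("c9methyl")),
    seed = as.integer(seed), k = as.integer(k),
    threshold = as.integer(threshold), alternate_threshold = as.integer(t2),
    flank_length = as.integer(flank_length),
    waterfall_sample = wf_sample,
    counts = list(
      input_reads = nrow(reads),
      methylation_profile_reads = nrow(reads_meth),
      length_profile_reads = nrow(reads_len),
      summarized_reads = nrow(read_meth),
      samples_methylation = nrow(sample_meth),
      samples_repeats = nrow(sample_repeats),
      association_rows = nrow(assoc$associations)
    )
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (plots) write_pipeline_plots(output_dir, wf, sample_meth, sample_repeats,
                                  assoc, cohort$meta)

  res <- list(
    reads_methylation_profile = reads_meth, reads_length_profile = reads_len,
    qc = qc, alleles_methylation = alleles_meth, alleles_length = alleles_len,
    read_methylation = read_meth, sample_methylation = sample_meth,
    thresholds = thresholds, purity_measurements = purity_meas,
    sample_purity = sample_purity, repeat_measurements = repeat_meas,
    sample_repeats = sample_repeats, associations = assoc,
    waterfall = wf, manifest = manifest, output_dir = output_dir
  )
  class(res) <- "c9_pipeline"
  invisible(res)
}

#' @export
print.c9_pipeline <- function(x, ...) {
  cat("<c9_pipeline> results in", x$output_dir, "\n")
  cnt <- x$manifest$counts
  cat("  reads:", cnt$input_reads,
      "-> methylation profile:", cnt$methylation_profile_reads,
      "| length profile:", cnt$length_profile_reads, "\n")
  cat("  association rows:", cnt$association_rows, "\n")
  invisible(x)
}

write_pipeline_plots <- function(output_dir, wf, sample_meth, sample_repeats,
                                 assoc, meta) {
  sv <- function(p, f, w = 7, h = 5) {
    ggplot2::ggsave(file.path(output_dir, f), p, width = w, height = h, dpi = 150)
  }
  for (al in names(wf)) {
    if (nrow(wf[[al]])) sv(plot_waterfall(wf[[al]]), paste0("waterfall_", al, ".png"))
  }
  sv(plot_allele_methylation(sample_meth), "allele_methylation.png")
  base <- meta |>
    group_by(.data$individual_id) |>
    slice_min(.data$timepoint_years, n = 1, with_ties = FALSE) |>
    ungroup() |>
    left_join(sample_meth |> filter(.data$allele == "expanded"), by = "sample_id") |>
    left_join(sample_repeats |> filter(.data$allele == "expanded") |>
                select("sample_id", "max_repeats"), by = "sample_id")
  sv(plot_methylation_vs_length(base), "methylation_vs_length.png")
  if (nrow(assoc$transmissions)) {
    sv(plot_transmissions(assoc$transmissions), "transmissions.png")
  }
  invisible(NULL)
}
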