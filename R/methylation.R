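#' Per-read methylation summaries
#'
#' For each read, computes the median methylation score (mean of the two
#' middle values for even CpG counts) and the proportion of methylated CpGs,
#' where a CpG is called methylated when its score is `>= threshold`
#' (default 128, the top half of the 0-255 score scale). With
#' `strict = TRUE` the comparison is `> threshold` instead, matching the
#' wording of the alternate 75% rule (see [compare_thresholds()]).
#'
#' Reads without any CpG call are simply absent from `cpg` and hence from
#' the output; if `reads` is supplied, the number of such reads is reported
#' via a message.
#'
#' @param cpg Tibble of CpG calls (`read_id`, `read_pos`, `score`).
#' @param threshold Methylation-call threshold on the 0-255 scale.
#' @param strict Use `>` instead of `>=` at the threshold.
#' @param reads Optional reads tibble used only to report zero-CpG reads.
#' @return A tibble with `read_id`, `n_cpgs`, `median_score`,
#'   `prop_methylated`.
#' @examples
#' cpg <- tibble::tibble(read_id = "r1", read_pos = c(0L, 5L, 9L, 12L),
#'                       score = c(0L, 255L, 255L, 255L))
#' summarize_read_methylation(cpg)
#' @export
summarize_read_methylation <- function(cpg, threshold = 128L, strict = FALSE,
                                       reads = NULL) {
  if (is.na(threshold) || threshold < 0 || threshold > 255) {
    abort("`threshold` must lie in [0, 255].")
  }
  if (any(cpg$score < 0 | cpg$score > 255, na.rm = TRUE)) {
    abort("Methylation scores must lie in [0, 255].")
  }
  if (!is.null(reads)) {
    n_empty <- sum(!reads$read_id %in% cpg$read_id)
    if (n_empty > 0) {
      inform(paste0(n_empty, " read(s) have no CpG call and are excluded from methylation summaries."))
    }
  }
  meth <- if (strict) cpg$score > threshold else cpg$score >= threshold
  cpg |>
    mutate(.meth = meth) |>
    group_by(.data$read_id) |>
    summarise(
      n_cpgs = dplyr::n(),
      median_score = median(.data$score),
      prop_methylated = mean(.data$.meth),
      .groups = "drop"
    )
}

#' Restrict CpG calls to the repeat tract
#'
#' Sensitivity-analysis helper: drops CpG calls that fall outside the
#' located repeat tract of their read (i.e. flank CpGs), so per-read
#' summaries can be recomputed on tract CpGs only. The default analysis
#' keeps flank CpGs, matching waterfall plots drawn with the flanking
#' region.
#'
#' @param reads Reads tibble (`read_id`, `sequence`).
#' @param cpg CpG calls.
#' @param motif Repeat motif.
#' @return The subset of `cpg` lying within each read's tract.
#' @export
tract_cpgs <- function(reads, cpg, motif = "GGGGCC") {
  tract <- locate_tract(reads$sequence, motif)
  idx <- match(cpg$read_id, reads$read_id)
  if (anyNA(idx)) abort("`cpg` references reads absent from `reads`.")
  keep <- !is.na(tract$start[idx]) &
    cpg$read_pos >= tract$start[idx] & cpg$read_pos < tract$end[idx]
  cpg[keep, , drop = FALSE]
}

#' Per-sample methylation summaries
#'
#' Aggregates per-read methylation over each sample and allele: the median
#' of per-read median scores, the median of per-read proportions, and the
#' range (minimum to maximum) of the proportions.
#'
#' @param read_meth Output of [summarize_read_methylation()] joined with
#'   `sample_id` and `allele` columns (see [run_pipeline()] for the standard
#'   joins).
#' @return A tibble keyed by `sample_id` and `allele`.
#' @export
summarize_sample_methylation <- function(read_meth) {
  need <- c("sample_id", "allele", "median_score", "prop_methylated")
  missing_col <- setdiff(need, names(read_meth))
  if (length(missing_col)) {
    abort(paste0("`read_meth` lacks column(s): ", paste(missing_col, collapse = ", ")))
  }
  read_meth |>
    group_by(.data$sample_id, .data$allele) |>
    summarise(
      n_reads = dplyr::n(),
      median_of_median_scores = median(.data$median_score),
      median_prop_methylated = median(.data$prop_methylated),
      min_prop = min(.data$prop_methylated),
      max_prop = max(.data$prop_methylated),
      range_prop = max(.data$prop_methylated) - min(.data$prop_methylated),
      .groups = "drop"
    )
}

#' Compare the main and alternate methylation-call thresholds
#'
#' Computes per-sample median proportions of methylated CpGs under the main
#' rule (score `>= t1`, default 128) and the alternate rule (score `> t2`,
#' default 192, i.e. the top quarter of the scale) and their Spearman rank
#' correlation within each allele. The asymmetry of the comparators
#' (inclusive at 128, strict at the 75% threshold) is deliberate and
#' preserved from the analysis this package reimplements.
#'
#' @param cpg CpG calls.
#' @param read_info Tibble mapping `read_id` to `sample_id` and `allele`.
#' @param t1,t2 Main (inclusive) and alternate (strict) thresholds.
#' @return A list with `samples` (per sample/allele proportions under both
#'   rules) and `correlation` (one Spearman result per allele; `NA` with a
#'   note when fewer than 3 samples or a constant vector).
#' @export
compare_thresholds <- function(cpg, read_info, t1 = 128L, t2 = 192L) {
  m1 <- summarize_read_methylation(cpg, threshold = t1, strict = FALSE) |>
    select("read_id", prop_main = "prop_methylated")
  m2 <- summarize_read_methylation(cpg, threshold = t2, strict = TRUE) |>
    select("read_id", prop_alt = "prop_methylated")
  samples <- m1 |>
    inner_join(m2, by = "read_id") |>
    inner_join(read_info, by = "read_id") |>
    group_by(.data$sample_id, .data$allele) |>
    summarise(
      n_reads = dplyr::n(),
      prop_main = median(.data$prop_main),
      prop_alt = median(.data$prop_alt),
      .groups = "drop"
    )
  correlation <- samples |>
    group_by(.data$allele) |>
    group_modify(~ spearman_assoc(.x$prop_main, .x$prop_alt,
                                  name = "threshold_comparison")) |>
    ungroup()
  list(samples = samples, correlation = correlation)
}

#' Waterfall matrix of methylation scores
#'
#' Builds the reads-by-CpG-ordinal matrix behind waterfall-style plots: one
#' row per read, sorted by descending CpG count (ties broken by read id),
#' one column per CpG ordinal position; cells beyond a read's CpG count are
#' `NA`, which is distinct from a true score of 0.
#'
#' @param cpg CpG calls for the reads of one allele.
#' @param read_ids Optional subset/ordering domain of reads to include.
#' @return A numeric matrix with `read_id` rownames.
#' @seealso [plot_waterfall()]
#' @export
waterfall_matrix <- function(cpg, read_ids = NULL) {
  if (!is.null(read_ids)) cpg <- cpg[cpg$read_id %in% read_ids, , drop = FALSE]
  if (!nrow(cpg)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  cpg <- cpg |> arrange(.data$read_id, .data$read_pos)
  counts <- cpg |> dplyr::count(.data$read_id)
  counts <- counts[order(-counts$n, counts$read_id), , drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(counts), ncol = max(counts$n),
                dimnames = list(counts$read_id, NULL))
  ord <- split(cpg$score, factor(cpg$read_id, levels = counts$read_id))
  for (i in seq_along(ord)) mat[i, seq_along(ord[[i]])] <- ord[[i]]
  mat
}
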