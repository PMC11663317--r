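#' Locate the repeat tract within a read
#'
#' The tract runs from the first base of the first exact motif occurrence to
#' the last base of the last occurrence, reported as a 0-based half-open
#' interval. Reads without a motif occurrence yield an `NA` row.
#'
#' @param seq Character vector of read sequences.
#' @param motif Repeat motif (default `"GGGGCC"`).
#' @return A tibble with columns `start` and `end` (0-based half-open).
#' @examples
#' locate_tract("AAGGGGCCTT") # start 2, end 8
#' @export
locate_tract <- function(seq, motif = "GGGGCC") {
  hits <- gregexpr(motif, seq, fixed = TRUE)
  first <- vapply(hits, function(m) as.integer(m[1]), integer(1))
  last <- vapply(hits, function(m) as.integer(m[length(m)]), integer(1))
  found <- first > 0L
  tibble(
    start = ifelse(found, first - 1L, NA_integer_),
    end = ifelse(found, last - 1L + nchar(motif), NA_integer_)
  )
}

#' Count repeat units between the first and last motif occurrence
#'
#' The primary repeat count is span-based, `floor(tract_span / 6)` for the
#' 6-bp motif, so that interrupted units still count toward length. The
#' exact number of non-overlapping motif matches is returned alongside for
#' transparency.
#'
#' @inheritParams locate_tract
#' @return A tibble with `repeat_count` (span-based), `exact_motif_count`,
#'   `tract_span` (bases); `NA` rows for motif-free reads.
#' @examples
#' count_repeats(strrep("GGGGCC", 14))$repeat_count # 14
#' @export
count_repeats <- function(seq, motif = "GGGGCC") {
  tract <- locate_tract(seq, motif)
  span <- tract$end - tract$start
  n_exact <- vapply(gregexpr(motif, seq, fixed = TRUE),
                    function(m) if (m[1] == -1L) NA_integer_ else length(m),
                    integer(1))
  tibble(
    repeat_count = as.integer(span %/% nchar(motif)),
    exact_motif_count = n_exact,
    tract_span = as.integer(span)
  )
}

#' Sequence purity of the repeat tract
#'
#' Computed over the tract only (flanks excluded): `gc_fraction` is the
#' fraction of G or C bases, `motif_fraction` the fraction of tract bases
#' covered by non-overlapping exact motif matches.
#'
#' @inheritParams locate_tract
#' @return A tibble with `gc_fraction` and `motif_fraction` in \[0, 1\].
#' @examples
#' repeat_purity(paste0("GGGGCC", "GGGTCC", "GGGGCC"))
#' @export
repeat_purity <- function(seq, motif = "GGGGCC") {
  tract <- locate_tract(seq, motif)
  sub <- substring(seq, tract$start + 1L, tract$end)
  span <- tract$end - tract$start
  gc <- stringr::str_count(sub, "[GC]")
  n_match <- stringr::str_count(sub, stringr::fixed(motif))
  tibble(
    gc_fraction = ifelse(is.na(span), NA_real_, gc / span),
    motif_fraction = ifelse(is.na(span), NA_real_, nchar(motif) * n_match / span)
  )
}

#' Per-read repeat measurements
#'
#' Combines [locate_tract()], [count_repeats()] and [repeat_purity()] for a
#' set of reads. Motif-free reads are excluded (with a message) since no
#' tract can be located on them.
#'
#' @param reads Reads tibble.
#' @param alleles Optional allele calls ([assign_alleles()]) joined into the
#'   result.
#' @param motif Repeat motif.
#' @return A tibble with one row per measurable read: `read_id`,
#'   `sample_id`/`allele` when available, `repeat_count`,
#'   `exact_motif_count`, `tract_span`, `gc_fraction`, `motif_fraction`.
#' @export
measure_repeats <- function(reads, alleles = NULL, motif = "GGGGCC") {
  cnt <- count_repeats(reads$sequence, motif)
  pur <- repeat_purity(reads$sequence, motif)
  res <- bind_cols(reads[intersect(c("read_id", "sample_id", "individual_id"),
                                   names(reads))],
                   cnt, pur)
  motif_free <- is.na(res$repeat_count)
  if (any(motif_free)) {
    inform(paste0(sum(motif_free), " motif-free read(s) excluded from repeat metrics."))
    res <- res[!motif_free, , drop = FALSE]
  }
  if (!is.null(alleles)) {
    res <- res |> left_join(alleles |> select("read_id", "allele"), by = "read_id") |>
      relocate("allele", .after = "read_id")
  }
  res
}

#' Per-sample repeat summaries
#'
#' Maximum, median, minimum and range of per-read repeat counts, and median
#' purity metrics, per sample and allele. The per-sample maximum is the
#' primary length estimate (most consistent with Southern blot sizing); the
#' range (maximum minus minimum) quantifies within-individual somatic
#' variability.
#'
#' @param measurements Output of [measure_repeats()] carrying `sample_id`
#'   and `allele` columns.
#' @return A tibble keyed by `sample_id` and `allele`.
#' @export
summarize_sample_repeats <- function(measurements) {
  need <- c("sample_id", "allele", "repeat_count", "gc_fraction", "motif_fraction")
  missing_col <- setdiff(need, names(measurements))
  if (length(missing_col)) {
    abort(paste0("`measurements` lacks column(s): ", paste(missing_col, collapse = ", ")))
  }
  measurements |>
    group_by(.data$sample_id, .data$allele) |>
    summarise(
      n_reads = dplyr::n(),
      max_repeats = max(.data$repeat_count),
      median_repeats = median(.data$repeat_count),
      min_repeats = min(.data$repeat_count),
      range_repeats = max(.data$repeat_count) - min(.data$repeat_count),
      median_gc = median(.data$gc_fraction),
      median_motif_fraction = median(.data$motif_fraction),
      .groups = "drop"
    )
}
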