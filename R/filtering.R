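#' Quality-control profiles for consensus reads
#'
#' Two profiles mirror the two consensus-generation settings of the targeted
#' pipeline: `"methylation_purity"` (at least 7 full passes, predicted
#' accuracy >= 99%) for methylation and sequence-purity analyses, and
#' `"length"` (at least 1 full pass, predicted accuracy >= 80%) for repeat
#' sizing. Both require a read length between 10 bp and 100 kb and, because
#' truncated reads must be removed so that only reads containing the full
#' expansion are measured, both flanks to be spanned. Comparisons at the
#' stated boundaries are inclusive (`>=`).
#'
#' @param name `"methylation_purity"` or `"length"`.
#' @param min_full_passes,min_predicted_accuracy,min_read_length,max_read_length,require_both_flanks
#'   Optional overrides of the profile thresholds.
#' @return A `c9_filter_profile` list.
#' @examples
#' filter_profile("length")
#' @export
filter_profile <- function(name = c("methylation_purity", "length"),
                           min_full_passes = NULL,
                           min_predicted_accuracy = NULL,
                           min_read_length = 10L,
                           max_read_length = 100000L,
                           require_both_flanks = TRUE) {
  name <- match.arg(name)
  defaults <- switch(name,
    methylation_purity = list(passes = 7L, acc = 0.99),
    length = list(passes = 1L, acc = 0.80)
  )
  p <- list(
    name = name,
    min_full_passes = as.integer(min_full_passes %||% defaults$passes),
    min_predicted_accuracy = min_predicted_accuracy %||% defaults$acc,
    min_read_length = as.integer(min_read_length),
    max_read_length = as.integer(max_read_length),
    require_both_flanks = isTRUE(require_both_flanks)
  )
  class(p) <- "c9_filter_profile"
  p
}

#' @export
print.c9_filter_profile <- function(x, ...) {
  cat("<c9_filter_profile> ", x$name, "\n", sep = "")
  cat("  passes >= ", x$min_full_passes,
      ", accuracy >= ", x$min_predicted_accuracy,
      ", length in [", x$min_read_length, ", ", x$max_read_length, "]",
      if (x$require_both_flanks) ", both flanks required" else "", "\n", sep = "")
  invisible(x)
}

filter_flags <- function(reads, profile) {
  needed <- c("read_id", "sequence", "n_passes", "predicted_accuracy")
  if (profile$require_both_flanks) {
    needed <- c(needed, "spans_left_flank", "spans_right_flank")
  }
  missing_col <- setdiff(needed, names(reads))
  if (length(missing_col)) {
    abort(paste0("Reads table lacks required column(s): ",
                 paste(missing_col, collapse = ", ")))
  }
  for (col in setdiff(needed, c("read_id", "sequence"))) {
    if (anyNA(reads[[col]])) {
      abort(paste0("Read ", reads$read_id[which(is.na(reads[[col]]))[1]],
                   " has missing metadata in column '", col, "'."))
    }
  }
  len <- nchar(reads$sequence)
  tibble(
    read_id = reads$read_id,
    fail_passes = reads$n_passes < profile$min_full_passes,
    fail_accuracy = reads$predicted_accuracy < profile$min_predicted_accuracy,
    fail_too_short = len < profile$min_read_length,
    fail_too_long = len > profile$max_read_length,
    fail_flanks = if (profile$require_both_flanks) {
      !(reads$spans_left_flank & reads$spans_right_flank)
    } else FALSE
  )
}

#' Filter reads by a QC profile
#'
#' Returns exactly the reads meeting every threshold of `profile`, in their
#' input order. The input is not modified. A read with a missing metadata
#' field raises an error naming the read.
#'
#' @param reads A reads tibble (see [simulate_cohort()]).
#' @param profile A [filter_profile()].
#' @return The kept subset of `reads`.
#' @seealso [read_qc()] for per-read removal reasons.
#' @export
filter_reads <- function(reads, profile) {
  fl <- filter_flags(reads, profile)
  keep <- !(fl$fail_passes | fl$fail_accuracy | fl$fail_too_short |
              fl$fail_too_long | fl$fail_flanks)
  reads[keep, , drop = FALSE]
}

#' Per-read QC report
#'
#' @inheritParams filter_reads
#' @return A tibble with `read_id`, `kept`, and a comma-joined `reasons`
#'   column (`"pass"` for kept reads).
#' @export
read_qc <- function(reads, profile) {
  fl <- filter_flags(reads, profile)
  reason_mat <- as.matrix(fl[, -1])
  colnames(reason_mat) <- sub("^fail_", "", colnames(reason_mat))
  reasons <- apply(reason_mat, 1, function(r) {
    if (!any(r)) "pass" else paste(colnames(reason_mat)[r], collapse = ",")
  })
  tibble(read_id = fl$read_id, kept = reasons == "pass",
         reasons = unname(reasons), profile = profile$name)
}

#' Does a read span the full locus?
#'
#' A read spans the locus when both anchor sequences (the outer termini of
#' the two flanks) occur in it by exact match, with the left anchor before
#' the right one. Anchor matching replaces alignment-coordinate checks so
#' that the test works identically on SAM input and plain fixtures; exact
#' matching is appropriate for the error-free simulated flanks and is a
#' documented limitation for real reads.
#'
#' @param seq Character vector of read sequences.
#' @param left_anchor,right_anchor Anchor sequences, at least 20 bases each.
#' @param each_side If `TRUE`, return a list with logical vectors `left` and
#'   `right` (per-side presence, ordered); otherwise a single logical vector.
#' @return Logical vector (or list of two, with `each_side = TRUE`).
#' @export
spans_locus <- function(seq, left_anchor, right_anchor, each_side = FALSE) {
  if (nchar(left_anchor) < 20L || nchar(right_anchor) < 20L) {
    abort("Anchors must be at least 20 bases long (ambiguity risk).")
  }
  lpos <- as.integer(regexpr(left_anchor, seq, fixed = TRUE))
  rpos <- vapply(gregexpr(right_anchor, seq, fixed = TRUE),
                 function(m) as.integer(m[length(m)]), integer(1))
  ordered <- lpos > 0L & rpos > 0L & (lpos + nchar(left_anchor)) <= rpos
  if (each_side) {
    list(left = lpos > 0L & (rpos <= 0L | ordered),
         right = rpos > 0L & (lpos <= 0L | ordered))
  } else {
    ordered
  }
}
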