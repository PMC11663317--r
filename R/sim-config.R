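#' Configuration for the synthetic targeted-sequencing cohort
#'
#' Builds a validated configuration for [simulate_cohort()]. The defaults
#' emulate a blood cohort of 27 expansion carriers: every individual carries
#' a short wild-type allele (2-30 repeats) and an expanded allele whose
#' per-read repeat count is right-tailed around an individual modal length
#' (somatic mosaicism), with per-sample maxima reaching into the thousands
#' of repeats. Per-CpG 5mC probabilities rise linearly with the repeat count
#' of the read, CpGs near the read ends are highly methylated, and scores on
#' the integer 0-255 scale are obtained by clamped Gaussian rounding.
#'
#' @param n_individuals Number of individuals in the cohort.
#' @param wt_repeat_range Inclusive integer range of wild-type repeat counts;
#'   must lie within \[2, 30\].
#' @param expanded_modal_length Modal expanded repeat count per individual:
#'   a scalar (recycled), a vector of length `n_individuals`, or `NULL` to
#'   draw modal lengths from the built-in cohort model (ages, diagnosis
#'   groups, pedigrees and longitudinal structure; see Details).
#' @param mosaicism_dispersion Scale of the right-tailed per-read deviation:
#'   a read's repeat count is `round(modal * (1 + |N(0, dispersion)|))`.
#' @param interruption_rate Probability per repeat unit of a single-base
#'   interruption (substitution or deletion with equal probability).
#' @param flank_length Bases of flanking sequence on each side (40-120).
#' @param flank_cpg_meth_level Mean methylation fraction (0-1) of CpGs within
#'   `end_window` bases of a read end.
#' @param end_window Width in bases of the read-end windows in which flank
#'   CpGs are drawn at `flank_cpg_meth_level`; flank CpGs outside the windows
#'   use the baseline `expansion_meth_intercept`.
#' @param expansion_meth_slope Increase in mean methylation fraction per
#'   repeat unit for CpGs inside the tract.
#' @param expansion_meth_intercept Baseline mean methylation fraction; a
#'   scalar or a vector of length `n_individuals`.
#' @param score_noise_sd Gaussian noise of the emitted score, in score units
#'   (the 0-255 scale).
#' @param reads_per_allele_range Inclusive range of the per-sample, per-allele
#'   read count.
#' @param pass_count_distribution List with `yield_bp` (per-molecule
#'   sequencing yield budget in bases) and `max_lambda`; the number of full
#'   passes is `max(1, Poisson(min(max_lambda, yield_bp / read_length)))`, so
#'   long expanded molecules accumulate fewer passes than short wild-type
#'   molecules.
#' @param accuracy_distribution List with `base_q`, `q_per_pass` and `sd`;
#'   predicted accuracy is `1 - 10^-(base_q + q_per_pass * passes + N(0, sd))`,
#'   clamped to \[0.5, 0.999999\].
#' @param truncation_rate Probability that a read fails to span one flank
#'   (the outer part of one flank, including its anchor, is cut off).
#' @param include_longitudinal Add repeat draws over time for six individuals
#'   (13 samples in total, two of the six drifting in length) when
#'   `n_individuals >= 18`.
#' @param include_pedigrees Embed four father-offspring pedigrees covering
#'   seven paternal transmissions (contractions) when `n_individuals >= 12`.
#' @param tissue Tissue label written to the sample metadata.
#' @param seed Integer seed; required by [simulate_cohort()] so that every
#'   cohort is reproducible.
#' @return An object of class `c9_sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_individuals = 4, seed = 1)
#' cfg$wt_repeat_range
#' @export
sim_config <- function(n_individuals = 27L,
                       wt_repeat_range = c(2L, 30L),
                       expanded_modal_length = NULL,
                       mosaicism_dispersion = 0.4,
                       interruption_rate = 1e-3,
                       flank_length = 120L,
                       flank_cpg_meth_level = 0.9,
                       end_window = 35L,
                       expansion_meth_slope = 8.5e-5,
                       expansion_meth_intercept = 0.21,
                       score_noise_sd = 60,
                       reads_per_allele_range = c(15L, 40L),
                       pass_count_distribution = list(yield_bp = 1.2e5, max_lambda = 30),
                       accuracy_distribution = list(base_q = 1.0, q_per_pass = 0.35, sd = 0.2),
                       truncation_rate = 0.15,
                       include_longitudinal = TRUE,
                       include_pedigrees = TRUE,
                       tissue = "blood",
                       seed = NULL) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    wt_repeat_range = as.integer(wt_repeat_range),
    expanded_modal_length = expanded_modal_length,
    mosaicism_dispersion = mosaicism_dispersion,
    interruption_rate = interruption_rate,
    flank_length = as.integer(flank_length),
    flank_cpg_meth_level = flank_cpg_meth_level,
    end_window = as.integer(end_window),
    expansion_meth_slope = expansion_meth_slope,
    expansion_meth_intercept = expansion_meth_intercept,
    score_noise_sd = score_noise_sd,
    reads_per_allele_range = as.integer(reads_per_allele_range),
    pass_count_distribution = pass_count_distribution,
    accuracy_distribution = accuracy_distribution,
    truncation_rate = truncation_rate,
    include_longitudinal = isTRUE(include_longitudinal),
    include_pedigrees = isTRUE(include_pedigrees),
    tissue = as.character(tissue),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "c9_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "c9_sim_config"))
  if (is.na(cfg$n_individuals) || cfg$n_individuals < 1L) {
    abort("`n_individuals` must be a positive integer.")
  }
  r <- cfg$wt_repeat_range
  if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 2L || r[2] > 30L) {
    abort("`wt_repeat_range` must be an increasing integer pair within [2, 30].")
  }
  if (!is.null(cfg$expanded_modal_length)) {
    m <- cfg$expanded_modal_length
    if (!length(m) %in% c(1L, cfg$n_individuals)) {
      abort("`expanded_modal_length` must be a scalar or one value per individual.")
    }
    if (any(is.na(m)) || any(m < 64)) {
      abort("`expanded_modal_length` must be >= 64 repeats (below that the allele is not an expansion).")
    }
  }
  probs <- c(cfg$interruption_rate, cfg$truncation_rate, cfg$flank_cpg_meth_level)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("`interruption_rate`, `truncation_rate` and `flank_cpg_meth_level` must lie in [0, 1].")
  }
  ic <- cfg$expansion_meth_intercept
  if (!length(ic) %in% c(1L, cfg$n_individuals) || any(is.na(ic)) || any(ic < 0) || any(ic > 1)) {
    abort("`expansion_meth_intercept` must be in [0, 1], scalar or one value per individual.")
  }
  if (is.na(cfg$mosaicism_dispersion) || cfg$mosaicism_dispersion < 0) {
    abort("`mosaicism_dispersion` must be non-negative.")
  }
  if (is.na(cfg$score_noise_sd) || cfg$score_noise_sd < 0) {
    abort("`score_noise_sd` must be non-negative.")
  }
  rr <- cfg$reads_per_allele_range
  if (length(rr) != 2L || any(is.na(rr)) || rr[1] < 1L || rr[1] > rr[2]) {
    abort("`reads_per_allele_range` must be an increasing pair of positive integers.")
  }
  c9_flanks(cfg$flank_length) # validates the range
  if (cfg$end_window < 0L) abort("`end_window` must be non-negative.")
  invisible(cfg)
}

#' @export
print.c9_sim_config <- function(x, ...) {
  cat("<c9_sim_config>\n")
  cat("  individuals:      ", x$n_individuals, "\n")
  cat("  wild-type range:  ", paste(x$wt_repeat_range, collapse = "-"), "repeats\n")
  ml <- if (is.null(x$expanded_modal_length)) "cohort model" else
    paste(range(x$expanded_modal_length), collapse = "-")
  cat("  expanded modal:   ", ml, "\n")
  cat("  mosaicism disp.:  ", x$mosaicism_dispersion, "\n")
  cat("  interruption rate:", x$interruption_rate, "per unit\n")
  cat("  meth model:        clamp(", x$expansion_meth_intercept[1], " + ",
      x$expansion_meth_slope, " * repeats), flank ", x$flank_cpg_meth_level,
      ", noise sd ", x$score_noise_sd, "\n", sep = "")
  cat("  seed:             ", if (is.null(x$seed)) "<unset>" else x$seed, "\n")
  invisible(x)
}
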