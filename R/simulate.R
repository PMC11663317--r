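#' Simulate a targeted long-read cohort at the repeat locus
#'
#' Generates ground-truthed consensus reads for a cohort of repeat-expansion
#' carriers: read sequences (flank + GGGGCC tract + flank, with optional
#' single-base interruptions and flank truncation), one methylation score per
#' CpG dinucleotide, per-read pass-count/accuracy metadata, and a clinical
#' metadata table (diagnosis group, sex, ages, promoter methylation, Southern
#' blot estimates, longitudinal timepoints and father-offspring pedigrees).
#'
#' When `expanded_modal_length` is `NULL` the built-in cohort model draws a
#' modal expanded length per individual, ties age at collection to it (longer
#' expansions in older individuals), assigns diagnosis groups by age, embeds
#' four pedigrees with paternal contractions and six individuals with
#' longitudinal draws. Per-read expanded repeat counts are
#' `round(modal * (1 + |N(0, dispersion)|))`, giving the right-tailed
#' within-individual length distribution characteristic of somatic mosaicism;
#' the wild-type allele is simulated without mosaicism.
#'
#' @param config A [sim_config()] object; `config$seed` must be set.
#' @return An object of class `c9_cohort`: a list of tibbles `reads`
#'   (read_id, individual_id, sample_id, sequence, n_passes,
#'   predicted_accuracy, spans_left_flank, spans_right_flank), `cpg`
#'   (read_id, read_pos, score; `read_pos` is the 0-based position of the C
#'   of each CG), `truth` (per-read ground truth, including the
#'   `true_interruption_positions` and `true_per_cpg_meth_prob` list
#'   columns), and `meta` (one row per sample), plus the `config` used.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 3, seed = 7))
#' nrow(cohort$reads)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (is.null(config$seed)) {
    abort("`config$seed` must be set: simulated cohorts are only meaningful when reproducible.")
  }
  set.seed(config$seed)

  ind <- cohort_individuals(config)
  samp <- cohort_samples(config, ind)

  fl <- c9_flanks(config$flank_length)
  motif <- "GGGGCC"
  intercepts <- rep_len(config$expansion_meth_intercept, config$n_individuals)

  # one row per (sample, allele) with its read count
  nr <- config$reads_per_allele_range
  plan <- samp |>
    tidyr::crossing(allele = c("wild_type", "expanded")) |>
    mutate(n_reads = sample(nr[1]:nr[2], dplyr::n(), replace = TRUE))

  per_read <- plan |>
    mutate(read_idx = purrr::map(.data$n_reads, seq_len)) |>
    tidyr::unnest("read_idx") |>
    group_by(.data$sample_id) |>
    mutate(read_id = sprintf("%s/%04d", .data$sample_id, dplyr::row_number())) |>
    ungroup()

  n <- nrow(per_read)
  ind_idx <- match(per_read$individual_id, ind$individual_id)
  modal <- ifelse(per_read$allele == "expanded",
                  per_read$modal_length,
                  ind$wt_genotype[ind_idx])
  units <- ifelse(
    per_read$allele == "expanded",
    pmax(1L, as.integer(round(modal * (1 + abs(rnorm(n, 0, config$mosaicism_dispersion)))))),
    as.integer(modal)
  )

  tract <- build_tracts(units, config$interruption_rate, motif)

  # truncation: drop the outer part of one flank (including its anchor)
  truncated <- runif(n) < config$truncation_rate
  trunc_side <- ifelse(truncated, sample(c("left", "right"), n, replace = TRUE), NA)
  cut <- ifelse(truncated, sample.int(config$flank_length, n, replace = TRUE), 0L)
  left_seq <- ifelse(truncated & trunc_side == "left",
                     substring(fl$left, cut + 1L, config$flank_length), fl$left)
  right_seq <- ifelse(truncated & trunc_side == "right",
                      substring(fl$right, 1L, config$flank_length - cut), fl$right)
  sequence <- paste0(left_seq, tract$sequence, right_seq)
  left_len <- nchar(left_seq)
  tract_len <- nchar(tract$sequence)
  read_len <- nchar(sequence)

  # HiFi-style quality metadata: passes limited by a per-molecule yield
  # budget, accuracy rising with passes on a Phred-like scale
  pcd <- config$pass_count_distribution
  acd <- config$accuracy_distribution
  lambda <- pmin(pcd$max_lambda, pcd$yield_bp / read_len)
  n_passes <- pmax(1L, rpois(n, lambda))
  q <- acd$base_q + acd$q_per_pass * n_passes + rnorm(n, 0, acd$sd)
  predicted_accuracy <- pmin(0.999999, pmax(0.5, 1 - 10^(-q)))

  reads <- tibble(
    read_id = per_read$read_id,
    individual_id = per_read$individual_id,
    sample_id = per_read$sample_id,
    sequence = sequence,
    n_passes = as.integer(n_passes),
    predicted_accuracy = predicted_accuracy,
    spans_left_flank = !(truncated & trunc_side == "left"),
    spans_right_flank = !(truncated & trunc_side == "right")
  )

  # per-CpG methylation probabilities and scores
  cg_pos <- stringr::str_locate_all(sequence, stringr::fixed("CG"))
  pos0_list <- purrr::map(cg_pos, ~ .x[, 1] - 1L)
  n_cpg <- lengths(pos0_list)
  pos0 <- unlist(pos0_list, use.names = FALSE)
  rep_i <- rep.int(seq_len(n), n_cpg)

  in_tract <- pos0 >= left_len[rep_i] & pos0 < (left_len + tract_len)[rep_i]
  near_end <- pos0 < config$end_window | pos0 >= (read_len[rep_i] - config$end_window)
  base_prob <- intercepts[ind_idx][rep_i]
  tract_prob <- pmin(1, pmax(0, base_prob + config$expansion_meth_slope * units[rep_i]))
  prob <- ifelse(in_tract, tract_prob,
                 ifelse(near_end, config$flank_cpg_meth_level, base_prob))
  score <- as.integer(pmin(255, pmax(0, round(255 * prob + rnorm(length(prob), 0, config$score_noise_sd)))))

  cpg <- tibble(
    read_id = reads$read_id[rep_i],
    read_pos = as.integer(pos0),
    score = score
  )

  truth <- tibble(
    individual_id = per_read$individual_id,
    sample_id = per_read$sample_id,
    read_id = per_read$read_id,
    true_allele = per_read$allele,
    true_repeat_count = units,
    true_interruption_positions = tract$interruptions,
    true_per_cpg_meth_prob = split_by_read(prob, rep_i, n),
    true_spans_left = reads$spans_left_flank,
    true_spans_right = reads$spans_right_flank
  )

  meta <- samp |>
    left_join(ind |> select(-"modal_length"), by = "individual_id") |>
    transmute(
      sample_id = .data$sample_id,
      individual_id = .data$individual_id,
      group = .data$group,
      sex = .data$sex,
      age_at_collection = round(.data$age_baseline + .data$timepoint_years, 2),
      age_at_onset = .data$age_at_onset,
      promoter_methylation = .data$promoter_methylation,
      promoter_hypermethylated = .data$promoter_hypermethylated,
      southern_repeats = .data$southern_repeats,
      southern_smear = .data$southern_smear,
      timepoint_years = .data$timepoint_years,
      father_id = .data$father_id,
      pedigree_id = .data$pedigree_id,
      tissue = config$tissue,
      wt_genotype = .data$wt_genotype
    )

  structure(
    list(reads = reads, cpg = cpg, truth = truth, meta = meta, config = config),
    class = "c9_cohort"
  )
}

split_by_read <- function(x, rep_i, n_reads) {
  out <- rep(list(numeric(0)), n_reads)
  got <- split(x, factor(rep_i, levels = seq_len(n_reads)))
  out[as.integer(names(got))] <- got
  unname(out)
}

# Build repeat tracts of `units` GGGGCC copies with independent per-unit
# interruptions (single-base substitution or deletion, equal probability).
# Returns the sequences and the 0-based indices of interrupted units.
build_tracts <- function(units, rate, motif = "GGGGCC") {
  n <- length(units)
  n_int <- if (rate > 0) rbinom(n, units, rate) else integer(n)
  seqs <- character(n)
  ints <- vector("list", n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    if (n_int[i] == 0L) {
      seqs[i] <- strrep(motif, units[i])
      ints[[i]] <- integer(0)
      next
    }
    u <- rep(motif, units[i])
    pos <- sort(sample.int(units[i], n_int[i]))
    for (p in pos) {
      j <- sample.int(nchar(motif), 1L)
      if (runif(1) < 0.5) { # substitution
        old <- substr(u[p], j, j)
        substr(u[p], j, j) <- sample(setdiff(bases, old), 1L)
      } else { # deletion
        u[p] <- paste0(substr(u[p], 1L, j - 1L), substr(u[p], j + 1L, nchar(motif)))
      }
    }
    seqs[i] <- paste(u, collapse = "")
    ints[[i]] <- pos - 1L
  }
  list(sequence = seqs, interruptions = ints)
}

# Individual-level cohort model: modal expanded lengths, pedigree structure
# (paternal contractions), ages anchored to expansion length, diagnosis
# groups by age, and the clinical covariates fed to the association layer.
cohort_individuals <- function(config) {
  n <- config$n_individuals
  individual_id <- sprintf("I%02d", seq_len(n))

  father_id <- rep(NA_character_, n)
  pedigree_id <- rep(NA_character_, n)
  use_ped <- config$include_pedigrees && n >= 12L
  if (use_ped) {
    # four pedigrees, seven paternal transmissions
    ped <- list(`P1` = c(1L, 5L, 6L), `P2` = c(2L, 7L, 8L),
                `P3` = c(3L, 9L, 10L), `P4` = c(4L, 11L))
    for (p in names(ped)) {
      ids <- ped[[p]]
      pedigree_id[ids] <- p
      father_id[ids[-1]] <- individual_id[ids[1]]
    }
  }

  if (is.null(config$expanded_modal_length)) {
    modal <- round(runif(n, 700, 3300))
    if (use_ped) {
      fathers <- c(1L, 2L, 3L, 4L)
      modal[fathers] <- round(runif(4, 2300, 3300))
      kids <- which(!is.na(father_id))
      modal[kids] <- pmax(200, modal[match(father_id[kids], individual_id)] -
                            round(runif(length(kids), 1300, 2100)))
    }
  } else {
    modal <- round(rep_len(config$expanded_modal_length, n))
  }

  age <- pmin(80, pmax(26, round(40 + 0.011 * modal + rnorm(n, 0, 8), 2)))
  if (use_ped) {
    for (f in c(1L, 2L, 3L, 4L)) {
      kids <- which(father_id == individual_id[f])
      if (length(kids)) age[f] <- max(age[f], max(age[kids]) + 20)
    }
  }

  symptomatic <- (age + rnorm(n, 0, 3)) > 52
  if (n >= 4L) { # keep both groups represented
    if (sum(symptomatic) < 2L) symptomatic[order(age, decreasing = TRUE)[1:2]] <- TRUE
    if (sum(!symptomatic) < 2L) symptomatic[order(age)[1:2]] <- FALSE
  }
  group <- ifelse(symptomatic, "ALS", "presymptomatic")
  if (any(symptomatic)) group[which(symptomatic)[1]] <- "FTD"

  age_at_onset <- ifelse(symptomatic,
                         round(age - pmax(0.2, rnorm(n, 1.5, 1.2)), 2),
                         NA_real_)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.593, 0.407))
  promoter_methylation <- round(pmax(0.05, 0.7 * exp(0.0008 * modal + rnorm(n, 0, 1.1))), 2)
  promoter_hypermethylated <- promoter_methylation >= 10
  southern_repeats <- pmax(150, round(2.0 * modal * exp(rnorm(n, 0, 0.35))))
  southern_smear <- pmax(80, round(1.0 * modal * exp(rnorm(n, 0, 0.8))))
  if (n >= 10L) southern_smear[sample.int(n, 6L)] <- NA_integer_
  wt_genotype <- sample(config$wt_repeat_range[1]:config$wt_repeat_range[2], n, replace = TRUE)

  tibble(
    individual_id = individual_id, modal_length = modal,
    age_baseline = age, group = group, sex = sex, age_at_onset = age_at_onset,
    promoter_methylation = promoter_methylation,
    promoter_hypermethylated = promoter_hypermethylated,
    southern_repeats = southern_repeats, southern_smear = southern_smear,
    father_id = father_id, pedigree_id = pedigree_id, wt_genotype = wt_genotype
  )
}

# Sample-level table: a baseline draw per individual plus longitudinal
# timepoints for six individuals (13 samples in total; the first two of the
# six drift upward in modal length, the rest are stable).
cohort_samples <- function(config, ind) {
  n <- config$n_individuals
  use_long <- config$include_longitudinal && n >= 18L
  long_ids <- if (use_long) 12:17 else integer(0)
  n_tp <- rep(1L, n)
  if (use_long) n_tp[long_ids] <- c(3L, rep(2L, 5L))
  drift_ids <- if (use_long) long_ids[1:2] else integer(0)

  purrr::map_dfr(seq_len(n), function(i) {
    tps <- cumsum(c(0, if (n_tp[i] > 1L) runif(n_tp[i] - 1L, 1.5, 3.5) else numeric(0)))
    modal <- rep(ind$modal_length[i], n_tp[i])
    if (i %in% drift_ids && n_tp[i] > 1L) modal[-1] <- modal[-1] + 1500
    tibble(
      individual_id = ind$individual_id[i],
      sample_id = sprintf("%s_T%02d", ind$individual_id[i], seq_len(n_tp[i])),
      timepoint_years = round(tps, 2),
      modal_length = modal
    )
  })
}

#' @export
print.c9_cohort <- function(x, ...) {
  cat("<c9_cohort>\n")
  cat("  individuals:", dplyr::n_distinct(x$meta$individual_id),
      " samples:", nrow(x$meta), "\n")
  cat("  reads:", nrow(x$reads), " (",
      sum(x$truth$true_allele == "expanded"), "expanded /",
      sum(x$truth$true_allele == "wild_type"), "wild-type )\n")
  cat("  CpG calls:", nrow(x$cpg), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}
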