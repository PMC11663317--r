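#' Write a simulated cohort to a plain-text fixture directory
#'
#' Emits `reads.tsv`, `cpg.tsv`, `truth.tsv`, `truth_cpg.tsv`, `meta.tsv`
#' and `reads.fasta`. The tabular fixture round-trips losslessly through
#' [read_fixture()]; interruption positions are serialised as comma-joined
#' 0-based unit indices and the per-CpG truth probabilities as a long table.
#'
#' @param cohort A `c9_cohort` (see [simulate_cohort()]), or any list with
#'   tibbles `reads`, `cpg`, `truth`, `meta`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  if (anyDuplicated(cohort$reads$read_id)) {
    abort("Refusing to write fixture: duplicated read_id values.")
  }
  if (!all(cohort$cpg$read_id %in% c(cohort$reads$read_id, character(0)))) {
    abort("Refusing to write fixture: cpg table references unknown read_id values.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  readr::write_tsv(cohort$reads, file.path(dir, "reads.tsv"))
  readr::write_tsv(cohort$cpg |> rename(read_pos_0based = "read_pos"),
                   file.path(dir, "cpg.tsv"))

  truth_flat <- cohort$truth |>
    mutate(true_interruption_positions =
             purrr::map_chr(.data$true_interruption_positions,
                            ~ paste(.x, collapse = ","))) |>
    select(-dplyr::any_of("true_per_cpg_meth_prob"))
  readr::write_tsv(truth_flat, file.path(dir, "truth.tsv"))

  if ("true_per_cpg_meth_prob" %in% names(cohort$truth)) {
    pos_by_read <- split(cohort$cpg$read_pos,
                         factor(cohort$cpg$read_id, levels = cohort$truth$read_id))
    if (!identical(unname(lengths(pos_by_read)),
                   lengths(cohort$truth$true_per_cpg_meth_prob))) {
      abort("truth$true_per_cpg_meth_prob is inconsistent with the cpg table.")
    }
    truth_cpg <- tibble(
      read_id = rep(cohort$truth$read_id,
                    lengths(cohort$truth$true_per_cpg_meth_prob)),
      read_pos_0based = as.integer(unlist(pos_by_read, use.names = FALSE) %||% integer(0)),
      true_prob = as.numeric(unlist(cohort$truth$true_per_cpg_meth_prob,
                                    use.names = FALSE) %||% numeric(0))
    )
    readr::write_tsv(truth_cpg, file.path(dir, "truth_cpg.tsv"))
  }

  readr::write_tsv(cohort$meta, file.path(dir, "meta.tsv"))

  fa <- Biostrings::DNAStringSet(setNames(cohort$reads$sequence, cohort$reads$read_id))
  Biostrings::writeXStringSet(fa, file.path(dir, "reads.fasta"))
  invisible(dir)
}

#' Read a fixture directory back into a cohort object
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `c9_cohort` (with `config = NULL`).
#' @export
read_fixture <- function(dir) {
  rd <- function(f, types) readr::read_tsv(file.path(dir, f), col_types = types)
  reads <- rd("reads.tsv", readr::cols(
    read_id = "c", individual_id = "c", sample_id = "c", sequence = "c",
    n_passes = "i", predicted_accuracy = "d",
    spans_left_flank = "l", spans_right_flank = "l"
  ))
  cpg <- rd("cpg.tsv", readr::cols(read_id = "c", read_pos_0based = "i", score = "i")) |>
    rename(read_pos = "read_pos_0based")
  validate_cpg_positions(reads, cpg)

  truth <- rd("truth.tsv", readr::cols(
    individual_id = "c", sample_id = "c", read_id = "c", true_allele = "c",
    true_repeat_count = "i", true_interruption_positions = "c",
    true_spans_left = "l", true_spans_right = "l"
  )) |>
    mutate(true_interruption_positions = purrr::map(
      .data$true_interruption_positions,
      ~ if (is.na(.x) || .x == "") integer(0) else as.integer(strsplit(.x, ",")[[1]])
    ))

  tc_path <- file.path(dir, "truth_cpg.tsv")
  if (file.exists(tc_path)) {
    tc <- readr::read_tsv(tc_path, col_types = readr::cols(
      read_id = "c", read_pos_0based = "i", true_prob = "d"
    ))
    by_read <- split(tc$true_prob, factor(tc$read_id, levels = truth$read_id))
    truth$true_per_cpg_meth_prob <- unname(by_read)
    truth <- truth |>
      relocate("true_per_cpg_meth_prob", .after = "true_interruption_positions")
  }

  meta <- rd("meta.tsv", readr::cols(
    sample_id = "c", individual_id = "c", group = "c", sex = "c",
    age_at_collection = "d", age_at_onset = "d", promoter_methylation = "d",
    promoter_hypermethylated = "l", southern_repeats = "i", southern_smear = "i",
    timepoint_years = "d", father_id = "c", pedigree_id = "c", tissue = "c",
    wt_genotype = "i"
  ))

  structure(list(reads = reads, cpg = cpg, truth = truth, meta = meta, config = NULL),
            class = "c9_cohort")
}

# every CpG call must sit on the C of a CG in its read's sequence
validate_cpg_positions <- function(reads, cpg) {
  if (!nrow(cpg)) return(invisible(TRUE))
  idx <- match(cpg$read_id, reads$read_id)
  if (anyNA(idx)) {
    abort(paste0("CpG calls reference unknown reads: ",
                 paste(head(unique(cpg$read_id[is.na(idx)]), 3), collapse = ", ")))
  }
  dinuc <- substring(reads$sequence[idx], cpg$read_pos + 1L, cpg$read_pos + 2L)
  bad <- dinuc != "CG"
  if (any(bad)) {
    abort(paste0("CpG call does not sit on a CG dinucleotide (read ",
                 cpg$read_id[which(bad)[1]], ", 0-based position ",
                 cpg$read_pos[which(bad)[1]], ")."))
  }
  invisible(TRUE)
}

#' Write reads with 5mC calls as SAM with MM/ML base-modification tags
#'
#' Emits unaligned plain-text SAM records carrying the standard `MM:Z:C+m`
#' (delta-encoded skipped-C counts) and `ML:B:C` (integer 0-255 scores)
#' base-modification tags, plus `np:i` (full passes), `rq:f` (predicted
#' accuracy), and `XS:Z`/`XI:Z` (sample/individual) tags.
#'
#' @param reads,cpg Tibbles as in a `c9_cohort`.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam_mods <- function(reads, cpg, path) {
  validate_cpg_positions(reads, cpg)
  cpg_by_read <- split(cpg[c("read_pos", "score")],
                       factor(cpg$read_id, levels = reads$read_id))
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    seq <- reads$sequence[i]
    calls <- cpg_by_read[[i]]
    calls <- calls[order(calls$read_pos), , drop = FALSE]
    tags <- sprintf("np:i:%d\trq:f:%.6f\tXS:Z:%s\tXI:Z:%s",
                    reads$n_passes[i], reads$predicted_accuracy[i],
                    reads$sample_id[i], reads$individual_id[i])
    if (nrow(calls)) {
      c_pos <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C") - 1L
      rank <- match(calls$read_pos, c_pos)
      if (anyNA(rank)) abort(paste0("Modified position is not a C in read ", reads$read_id[i]))
      deltas <- diff(c(0L, rank)) - 1L
      tags <- paste0(tags, "\tMM:Z:C+m,", paste(deltas, collapse = ","), ";",
                     "\tML:B:C,", paste(calls$score, collapse = ","))
    }
    paste(reads$read_id[i], 4L, "*", 0L, 255L, "*", "*", 0L, 0L, seq, "*", tags,
          sep = "\t")
  }, character(1))
  writeLines(c("@HD\tVN:1.6\tSO:unknown", recs), path)
  invisible(path)
}

#' Read a SAM file with MM/ML 5mC annotations
#'
#' Parses unaligned or aligned plain-text SAM records, decodes `MM:Z:C+m` /
#' `ML:B:C` tags into per-CpG calls, and recomputes the flank-span flags from
#' the read sequence with [spans_locus()].
#'
#' @param path A `.sam` file.
#' @param anchors Anchors used to recompute span flags (see [locus_anchors()]).
#' @return A list with tibbles `reads` and `cpg`.
#' @export
read_sam_mods <- function(path, anchors = locus_anchors()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  reads_l <- vector("list", length(lines))
  cpg_l <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) abort(sprintf("Malformed SAM record on line %d.", i))
    qname <- f[1]; seq <- f[10]
    tags <- f[-(1:11)]
    tagval <- function(pre) {
      hit <- tags[startsWith(tags, pre)]
      if (length(hit)) substring(hit[1], nchar(pre) + 1L) else NA_character_
    }
    np <- suppressWarnings(as.integer(tagval("np:i:")))
    rq <- suppressWarnings(as.numeric(tagval("rq:f:")))
    mm <- tagval("MM:Z:")
    ml <- tagval("ML:B:C,")
    read_pos <- integer(0); score <- integer(0)
    if (!is.na(mm)) {
      if (!grepl("^C\\+m[.?]?,", mm)) {
        abort(paste0("Unsupported MM tag in read ", qname, ": ", mm))
      }
      body <- sub(";.*$", "", sub("^C\\+m[.?]?,", "", mm))
      deltas <- suppressWarnings(as.integer(strsplit(body, ",", fixed = TRUE)[[1]]))
      if (anyNA(deltas)) abort(paste0("Malformed MM deltas in read ", qname))
      c_pos <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C") - 1L
      rank <- cumsum(deltas + 1L)
      if (length(rank) && max(rank) > length(c_pos)) {
        abort(paste0("MM tag of read ", qname, " addresses more Cs than the sequence has."))
      }
      read_pos <- c_pos[rank]
      if (is.na(ml)) abort(paste0("MM without ML tag in read ", qname))
      score <- suppressWarnings(as.integer(strsplit(ml, ",", fixed = TRUE)[[1]]))
      if (length(score) != length(read_pos) || anyNA(score)) {
        abort(paste0("ML tag of read ", qname, " does not match its MM tag."))
      }
    }
    reads_l[[i]] <- tibble(
      read_id = qname,
      individual_id = tagval("XI:Z:") %||% NA_character_,
      sample_id = tagval("XS:Z:") %||% NA_character_,
      sequence = seq, n_passes = np, predicted_accuracy = rq
    )
    cpg_l[[i]] <- tibble(read_id = qname, read_pos = read_pos, score = score)
  }
  reads <- bind_rows(reads_l)
  if (nrow(reads)) {
    sp <- spans_locus(reads$sequence, anchors$left, anchors$right, each_side = TRUE)
    reads$spans_left_flank <- sp$left
    reads$spans_right_flank <- sp$right
  } else {
    reads$spans_left_flank <- logical(0)
    reads$spans_right_flank <- logical(0)
  }
  cpg <- bind_rows(cpg_l)
  if (!nrow(cpg)) cpg <- tibble(read_id = character(0), read_pos = integer(0), score = integer(0))
  validate_cpg_positions(reads, cpg)
  list(reads = reads, cpg = cpg)
}
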