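#' Count overlapping k-mers of a sequence
#'
#' @param seq A single sequence over A/C/G/T.
#' @param k k-mer length (>= 1).
#' @return A tibble with columns `kmer` and `count`, containing only the
#'   observed k-mers; counts sum to `max(nchar(seq) - k + 1, 0)`.
#' @examples
#' kmer_counts("GGGGCCGGGGCC", 6)
#' @export
kmer_counts <- function(seq, k = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be a positive integer.")
  if (length(seq) != 1L) abort("`seq` must be a single sequence; see assign_alleles() for sets.")
  if (grepl("[^ACGT]", seq)) {
    abort("Sequence contains non-ACGT characters; k-mer counting is defined over {A,C,G,T}.")
  }
  if (nchar(seq) < k) return(tibble(kmer = character(0), count = integer(0)))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
  counts <- counts[counts > 0]
  tibble(kmer = names(counts), count = as.integer(counts)) |>
    arrange(dplyr::desc(.data$count), .data$kmer)
}

# k-mer count matrix (reads x 4^k) over the inter-anchor segment of each read
kmer_matrix <- function(seq, k) {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(paste0("Non-ACGT characters in ", sum(bad), " read segment(s); first at index ",
                 which(bad)[1], "."))
  }
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seq), width = k)
}

# segment strictly between the two anchor matches (flank remainders included;
# they are constant across full-span reads and do not affect distances)
anchor_segment <- function(seq, anchors, read_id = NULL) {
  lpos <- as.integer(regexpr(anchors$left, seq, fixed = TRUE))
  rpos <- vapply(gregexpr(anchors$right, seq, fixed = TRUE),
                 function(m) as.integer(m[length(m)]), integer(1))
  bad <- lpos <= 0L | rpos <= 0L | (lpos + nchar(anchors$left)) > rpos
  if (any(bad)) {
    id <- if (is.null(read_id)) which(bad)[1] else read_id[which(bad)[1]]
    abort(paste0("Read ", id, " does not contain both locus anchors; ",
                 "filter reads for full span before allele assignment."))
  }
  substring(seq, lpos + nchar(anchors$left), rpos - 1L)
}

#' Assign reads to the wild-type or expanded allele
#'
#' Clusters per-read k-mer count vectors (computed on the segment between
#' the locus anchors, the stand-in for a fixed genomic window) with k-means,
#' two centroids, Euclidean distance on raw counts and 10 restarts. Raw
#' counts make tract length the dominating signal, which is the intended
#' separator between the short wild-type tract and the expansion. The
#' cluster whose mean count of the repeat-motif k-mer is larger is labelled
#' `expanded`; on a tie, the cluster with larger mean read length. Somatic
#' length variation within the expansion is absorbed into the expanded
#' cluster. Clustering is run within each sample (the two alleles of one
#' individual), controlled by `by`.
#'
#' @param reads A reads tibble of full-span, locus-filtered reads.
#' @param k k-mer length; defaults to the motif length, 6.
#' @param seed Integer seed making the restarts deterministic.
#' @param anchors Locus anchors (see [locus_anchors()]).
#' @param by Column defining clustering groups (default `"sample_id"`); use
#'   `NULL` to cluster all reads together.
#' @param motif The repeat motif used for cluster labelling.
#' @return A tibble with `read_id`, the grouping column, `allele`
#'   (`"wild_type"`/`"expanded"`), `cluster_distance` (Euclidean distance to
#'   the assigned centroid) and `feature_vector_norm`.
#' @export
assign_alleles <- function(reads, k = 6L, seed = 1L,
                           anchors = locus_anchors(), by = "sample_id",
                           motif = "GGGGCC") {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be a positive integer.")
  if (!is.null(by) && !by %in% names(reads)) {
    abort(paste0("Grouping column '", by, "' not found in reads."))
  }
  groups <- if (is.null(by)) factor(rep("all", nrow(reads))) else factor(reads[[by]])
  idx_by_group <- split(seq_len(nrow(reads)), groups)
  group_names <- sort(names(idx_by_group))

  out <- purrr::map(seq_along(group_names), function(g) {
    idx <- idx_by_group[[group_names[g]]]
    if (length(idx) < 2L) {
      abort(paste0("Group '", group_names[g], "' has fewer than 2 reads; ",
                   "allele assignment needs both alleles represented."))
    }
    seg <- anchor_segment(reads$sequence[idx], anchors, reads$read_id[idx])
    mat <- kmer_matrix(seg, k)
    if (nrow(unique(mat)) < 2L) {
      abort(paste0("All reads in group '", group_names[g], "' have identical k-mer ",
                   "profiles: degenerate clustering. If the sample is single-allele, ",
                   "assign the label directly instead of clustering."))
    }
    set.seed(seed + g)
    km <- kmeans(mat, centers = 2L, nstart = 10L)

    motif_col <- if (motif %in% colnames(mat)) mat[, motif] else rep(0, nrow(mat))
    mean_motif <- tapply(motif_col, km$cluster, mean)
    expanded_cluster <- if (mean_motif[["1"]] != mean_motif[["2"]]) {
      as.integer(names(which.max(mean_motif)))
    } else { # tie-break: expansion implies length
      mean_len <- tapply(nchar(reads$sequence[idx]), km$cluster, mean)
      as.integer(names(which.max(mean_len)))
    }
    dist_own <- sqrt(rowSums((mat - km$centers[km$cluster, , drop = FALSE])^2))
    res <- tibble(
      read_id = reads$read_id[idx],
      allele = ifelse(km$cluster == expanded_cluster, "expanded", "wild_type"),
      cluster_distance = unname(dist_own),
      feature_vector_norm = sqrt(rowSums(mat^2))
    )
    if (!is.null(by)) res[[by]] <- reads[[by]][idx]
    res
  })
  res <- bind_rows(out)
  res <- res[match(reads$read_id, res$read_id), , drop = FALSE]
  if (!is.null(by)) res <- relocate(res, dplyr::all_of(by), .after = "read_id")
  res
}
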