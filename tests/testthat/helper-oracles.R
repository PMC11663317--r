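# Independent brute-force oracles. These deliberately avoid the code paths
# (and, where feasible, the base functions) used by the implementation:
# explicit loops, sliding windows, enumeration of null distributions.

bf_filter_keep <- function(reads, profile) {
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    len <- nchar(reads$sequence[i])
    ok <- reads$n_passes[i] >= profile$min_full_passes &&
      reads$predicted_accuracy[i] >= profile$min_predicted_accuracy &&
      len >= profile$min_read_length && len <= profile$max_read_length
    if (profile$require_both_flanks) {
      ok <- ok && reads$spans_left_flank[i] && reads$spans_right_flank[i]
    }
    keep[i] <- ok
  }
  reads$read_id[keep]
}

bf_kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  words <- character(n - k + 1)
  for (i in seq_len(n - k + 1)) words[i] <- substr(seq, i, i + k - 1)
  tab <- table(words)
  setNames(as.integer(tab), names(tab))
}

# all 1-based start positions of motif in seq, by sliding window
bf_motif_positions <- function(seq, motif) {
  m <- nchar(motif)
  n <- nchar(seq)
  if (n < m) return(integer(0))
  pos <- integer(0)
  for (i in seq_len(n - m + 1)) {
    if (substr(seq, i, i + m - 1) == motif) pos <- c(pos, i)
  }
  pos
}

bf_tract <- function(seq, motif) {
  pos <- bf_motif_positions(seq, motif)
  if (!length(pos)) return(c(NA_integer_, NA_integer_))
  c(pos[1] - 1L, pos[length(pos)] - 1L + nchar(motif))
}

bf_purity <- function(seq, motif) {
  tr <- bf_tract(seq, motif)
  if (is.na(tr[1])) return(c(NA_real_, NA_real_))
  sub <- substr(seq, tr[1] + 1L, tr[2])
  chars <- strsplit(sub, "")[[1]]
  gc <- sum(chars %in% c("G", "C")) / length(chars)
  # greedy left-to-right non-overlapping matches
  i <- 1L; hits <- 0L; m <- nchar(motif)
  while (i <= nchar(sub) - m + 1L) {
    if (substr(sub, i, i + m - 1L) == motif) { hits <- hits + 1L; i <- i + m }
    else i <- i + 1L
  }
  c(gc, m * hits / nchar(sub))
}

bf_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# average ranks with explicit tie handling
bf_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  r
}

bf_spearman_rho <- function(x, y) {
  rx <- bf_rank(x); ry <- bf_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exact signed-rank null distribution over all 2^n sign patterns
bf_signrank_dist <- function(n) {
  ranks <- seq_len(n)
  v <- integer(2^n)
  for (mask in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    v[mask + 1] <- sum(ranks[bits])
  }
  table(v) / 2^n
}

bf_signrank_p <- function(d, dist_cache = new.env()) {
  d <- d[d != 0]
  n <- length(d)
  key <- as.character(n)
  if (is.null(dist_cache[[key]])) dist_cache[[key]] <- bf_signrank_dist(n)
  dist <- dist_cache[[key]]
  vals <- as.integer(names(dist))
  v <- sum(bf_rank(abs(d))[d > 0])
  p_le <- sum(dist[vals <= v]); p_ge <- sum(dist[vals >= v])
  min(1, 2 * min(p_le, p_ge))
}

# exact rank-sum (Mann-Whitney U) null distribution by subset enumeration
bf_ranksum_dist <- function(n, m) {
  idx <- utils::combn(n + m, n)
  u <- apply(idx, 2, function(s) sum(s) - n * (n + 1) / 2)
  table(u) / ncol(idx)
}

bf_ranksum_p <- function(a, b, dist_cache = new.env()) {
  n <- length(a); m <- length(b)
  key <- paste(n, m)
  if (is.null(dist_cache[[key]])) dist_cache[[key]] <- bf_ranksum_dist(n, m)
  dist <- dist_cache[[key]]
  vals <- as.numeric(names(dist))
  r <- bf_rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  p_le <- sum(dist[vals <= u]); p_ge <- sum(dist[vals >= u])
  min(1, 2 * min(p_le, p_ge))
}

bf_ols <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))
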