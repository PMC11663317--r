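#' Waterfall-style plot of per-read CpG methylation
#'
#' Rows are reads sorted by CpG count, columns are CpG ordinal positions,
#' tiles are shaded white (unmethylated) to red (methylated); positions a
#' read does not have are drawn as background, distinct from a score of 0.
#'
#' @param mat Matrix from [waterfall_matrix()].
#' @return A ggplot object.
#' @export
plot_waterfall <- function(mat) {
  if (!nrow(mat)) abort("Empty waterfall matrix.")
  df <- tibble(
    read = factor(rep(rownames(mat), ncol(mat)), levels = rev(rownames(mat))),
    cpg = rep(seq_len(ncol(mat)), each = nrow(mat)),
    score = as.vector(mat)
  ) |> filter(!is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpg, y = .data$read, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red", limits = c(0, 255)) +
    ggplot2::labs(x = "CpG position within read", y = "reads (sorted by CpG count)",
                  fill = "5mC score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Boxplot of per-sample methylation by allele
#'
#' @param sample_meth Output of [summarize_sample_methylation()].
#' @param metric Column to plot.
#' @return A ggplot object.
#' @export
plot_allele_methylation <- function(sample_meth, metric = "median_prop_methylated") {
  ggplot2::ggplot(sample_meth,
                  ggplot2::aes(x = .data$allele, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id),
                       alpha = 0.3, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Scatterplot of methylation against repeat length
#'
#' @param data Data frame with `max_repeats` and `median_prop_methylated`
#'   columns (one row per individual).
#' @return A ggplot object with a least-squares line.
#' @export
plot_methylation_vs_length <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$max_repeats,
                                     y = .data$median_prop_methylated)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue") +
    ggplot2::labs(x = "maximum repeat count", y = "median proportion methylated CpGs") +
    ggplot2::theme_minimal()
}

#' Longitudinal dotplot of a per-sample value
#'
#' @param data Long data frame with `timepoint_years`, a value column, and
#'   `individual_id`.
#' @param value Value column name.
#' @return A ggplot object.
#' @export
plot_longitudinal <- function(data, value = "exp_prop") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$timepoint_years,
                                     y = .data[[value]],
                                     colour = .data$individual_id,
                                     group = .data$individual_id)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "years from first draw", y = value, colour = "individual") +
    ggplot2::theme_minimal()
}

#' Pedigree barplot of parent and offspring methylation
#'
#' @param transmissions Transmissions table from [run_associations()].
#' @return A ggplot object.
#' @export
plot_transmissions <- function(transmissions) {
  long <- bind_rows(
    transmissions |> transmute(pedigree_id = .data$pedigree_id,
                               id = .data$father_id, role = "father",
                               prop = .data$father_prop),
    transmissions |> transmute(pedigree_id = .data$pedigree_id,
                               id = .data$child_id, role = "offspring",
                               prop = .data$child_prop)
  ) |> distinct()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$prop, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~pedigree_id, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(father = "steelblue", offspring = "seagreen3")) +
    ggplot2::labs(x = NULL, y = "median proportion methylated CpGs") +
    ggplot2::theme_minimal()
}
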