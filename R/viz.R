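# The four standard figures of a pairwise alignment comparison. All
# functions return ggplot objects whose $data holds the plotted matrices
# verbatim (figures are views of the results, never recomputations).

#' Colour-blind-safe palette for the five disagreement categories
#'
#' Shared by [plot_dissimilarity_matrix()] and
#' [plot_dissimilarity_summary()] so categories are coloured consistently
#' across figures.
#'
#' @return Named character vector of colours, names as in
#'   [category_labels()].
#' @export
category_palette <- function() {
  c(match = "#0072B2",          # blue
    conserved_gap = "#E8E8E8",  # light grey
    merge = "#E69F00",          # orange
    split = "#009E73",          # green
    shift = "#D55E00")          # vermilion
}

pac_or <- function(x, field) {
  if (inherits(x, "pac")) x[[field]] else x
}

#' Heatmap of the column-pair similarity matrix
#'
#' Greyscale heatmap of S with reference columns on the x-axis and
#' comparison columns on the y-axis (comparison column 1 at the bottom).
#' Dark diagonal lines indicate regions where the two alignments agree;
#' parallel grey lines reveal alternative column pairings, analogous to a
#' dot plot of a pairwise sequence alignment.
#'
#' @param x A `pac` object from [compare_alignments()] or a similarity
#'   matrix from [similarity_matrix()].
#' @return A ggplot object; `$data` has one row per (reference column,
#'   comparison column) cell with its similarity.
#' @export
plot_similarity_heatmap <- function(x) {
  S <- pac_or(x, "S")
  if (!is.matrix(S)) stop_format("'x' must be a pac object or similarity matrix")
  df <- data.frame(
    reference_column = rep(seq_len(nrow(S)), times = ncol(S)),
    comparison_column = rep(seq_len(ncol(S)), each = nrow(S)),
    similarity = as.vector(S)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_column,
                                   y = .data$comparison_column,
                                   fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1),
                                 name = "Column\nsimilarity") +
    ggplot2::labs(x = "Reference alignment column",
                  y = "Comparison alignment column") +
    ggplot2::theme_minimal()
}

#' Categorical heatmap of the cell-level disagreement matrix
#'
#' One tile per reference character: sequences on the y-axis, reference
#' columns on the x-axis, coloured by category (match, conserved gap,
#' merge, split, shift). Blocks of colour reveal which sequence regions
#' (columns) or sequence sets (rows) the two alignments disagree on.
#'
#' @param x A `pac` object or a category matrix from
#'   [dissimilarity_matrix()].
#' @param palette Named colour vector; defaults to [category_palette()].
#' @return A ggplot object; `$data` has one row per cell with its category
#'   as a factor over all five levels.
#' @export
plot_dissimilarity_matrix <- function(x, palette = category_palette()) {
  D <- pac_or(x, "D")
  if (!is.matrix(D)) stop_format("'x' must be a pac object or category matrix")
  n <- nrow(D)
  labs <- category_labels()
  df <- data.frame(
    sequence = factor(rep(seq_len(n), times = ncol(D)), levels = rev(seq_len(n))),
    reference_column = rep(seq_len(ncol(D)), each = n),
    category = factor(labs[as.vector(D)], levels = labs)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_column,
                                   y = .data$sequence,
                                   fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = palette, drop = FALSE,
                               name = "Category") +
    ggplot2::labs(x = "Reference alignment column", y = "Sequence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Line plot of per-column similarity
#'
#' The average column match for each reference column, normalised to the
#' proportion of characters that are not conserved gaps. Columns consisting
#' entirely of conserved gaps are undefined and appear as breaks in the
#' line. Optionally overlays the per-column cysteine proportion, which for
#' cysteine-rich protein families marks the structurally constrained
#' columns where agreement matters most.
#'
#' @param pac A `pac` object from [compare_alignments()].
#' @param show_cysteine Logical; add the cysteine-proportion series.
#' @return A ggplot object; `$data` holds the normalised match values (and
#'   cysteine proportions when requested).
#' @export
plot_similarity_summary <- function(pac, show_cysteine = FALSE) {
  if (!inherits(pac, "pac")) stop_format("'pac' must come from compare_alignments()")
  df <- data.frame(column = pac$summary$column,
                   series = "normalised match",
                   value = pac$summary$match)
  if (isTRUE(show_cysteine)) {
    df <- rbind(df, data.frame(column = seq_len(pac$reference$width),
                               series = "cysteine proportion",
                               value = cysteine_proportion(pac$reference)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("normalised match" = "#0072B2",
                                            "cysteine proportion" = "#E6C200"),
                                 name = NULL) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Reference alignment column", y = "Proportion") +
    ggplot2::theme_minimal()
}

#' Stacked area plot of per-column dissimilarity sources
#'
#' The average merge, split and shift occurrence for each reference
#' column, normalised to the proportion of characters that are not
#' conserved gaps and stacked, using the same category colours as
#' [plot_dissimilarity_matrix()]. The stack height is at most 1 (it equals
#' 1 minus the normalised match).
#'
#' @param pac A `pac` object from [compare_alignments()].
#' @return A ggplot object; `$data` holds the normalised merge/split/shift
#'   values per column.
#' @export
plot_dissimilarity_summary <- function(pac) {
  if (!inherits(pac, "pac")) stop_format("'pac' must come from compare_alignments()")
  s <- pac$summary
  df <- data.frame(
    column = rep(s$column, 3L),
    category = factor(rep(c("merge", "split", "shift"), each = nrow(s)),
                      levels = c("merge", "split", "shift")),
    value = c(s$merge, s$split, s$shift)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$value,
                                   fill = .data$category)) +
    ggplot2::geom_area(stat = "identity", position = "stack", na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = category_palette()[c("merge", "split",
                                                             "shift")],
                               name = "Dissimilarity") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Reference alignment column",
                  y = "Proportion of non-conserved-gap characters") +
    ggplot2::theme_minimal()
}
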