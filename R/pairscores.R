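# Classical alignment-agreement scores: the sum-of-pairs score (SPS) and
# the total column score (CS). Both are computed directly from the residue
# instances (identified by ungapped position), independently of the
# column-matching machinery in core.R, matching their standard benchmark
# definitions.

#' Sum-of-pairs and total column scores
#'
#' The sum-of-pairs score is the proportion of all within-column residue
#' pairs of the reference alignment that are retained - i.e. the same two
#' residue instances co-occur in a single column - in the comparison
#' alignment. The total column score is the proportion of reference columns
#' whose full content (residue instances and gap placement, for every
#' sequence) is reproduced identically by some single comparison column.
#'
#' @param reference,comparison `msa_aln` objects of the same ungapped
#'   sequences; rows are paired with [validate_pair()].
#' @return An object of class `pair_scores`: list with `sps_per_column`
#'   (length-p vector; `NaN` for columns with fewer than two residues,
#'   which contribute no pairs), `sps_overall` and `cs_overall`.
#' @details Gap cells never form pairs. Columns with fewer than two
#'   residues contribute zero pairs to both the numerator and denominator
#'   of `sps_overall`. Unlike the matched-column score of
#'   [column_score()], `cs_overall` does not use the similarity-matrix
#'   argmax: it asks for an exactly identical comparison column.
#' @examples
#' ref <- alignment(c("ACG", "A-G"))
#' cmp <- alignment(c("ACG", "AG-"))
#' sum_of_pairs(ref, cmp)$sps_overall
#' @export
sum_of_pairs <- function(reference, comparison) {
  assert_alignment(reference, "reference")
  assert_alignment(comparison, "comparison")
  val <- validate_pair(reference, comparison)
  comparison <- alignment(comparison$rows[val$row_order, , drop = FALSE],
                          ids = comparison$ids[val$row_order],
                          normalise = FALSE)
  sum_of_pairs_encoded(encode_occurrences(reference),
                       encode_occurrences(comparison))
}

# Shared implementation over already row-corresponded encoded alignments.
sum_of_pairs_encoded <- function(Penc, Qenc) {
  n <- Penc$n
  p <- Penc$width
  q <- Qenc$width

  # qcol[x, l]: comparison column holding the l-th residue of row x
  maxlen <- max(Qenc$upos)
  qcol <- matrix(NA_integer_, n, max(maxlen, 1L))
  for (x in seq_len(n)) {
    jj <- which(Qenc$upos[x, ] > 0L)
    if (length(jj)) qcol[x, Qenc$upos[x, jj]] <- jj
  }

  retained <- numeric(p)
  total <- numeric(p)
  for (i in seq_len(p)) {
    rows <- which(Penc$upos[, i] > 0L)
    m <- length(rows)
    if (m < 2L) next
    # comparison column of each residue instance in this reference column
    cc <- qcol[cbind(rows, Penc$upos[rows, i])]
    total[i] <- choose(m, 2)
    cnt <- tabulate(match(cc, unique(cc)))
    retained[i] <- sum(choose(cnt, 2))
  }
  sps_per_column <- retained / total          # NaN where total == 0
  sps_overall <- if (sum(total) > 0) sum(retained) / sum(total) else NaN

  # CS: exact full-column reproduction, including gap placement
  ref_keys <- apply(Penc$labels, 2L, paste, collapse = "\r")
  cmp_keys <- apply(Qenc$labels, 2L, paste, collapse = "\r")
  cs_overall <- mean(ref_keys %in% cmp_keys)

  structure(list(sps_per_column = sps_per_column,
                 sps_overall = sps_overall,
                 cs_overall = cs_overall),
            class = "pair_scores")
}

#' @export
print.pair_scores <- function(x, ...) {
  cat("Pairwise agreement scores\n")
  cat(sprintf("  sum-of-pairs score (SPS): %s\n", format(x$sps_overall)))
  cat(sprintf("  total column score (CS):  %s\n", format(x$cs_overall)))
  invisible(x)
}

#' Plot the per-column sum-of-pairs score
#'
#' Line plot of the per-reference-column sum-of-pairs score. Columns with
#' fewer than two residues have no defined score and appear as breaks in
#' the line; if no column has a defined score the plot carries a warning
#' annotation.
#'
#' @param result A `pair_scores` object from [sum_of_pairs()] or a `pac`
#'   object from [compare_alignments()].
#' @return A ggplot object (its `data` holds the plotted values verbatim).
#' @export
plot_sps <- function(result) {
  spc <- if (inherits(result, "pac")) result$sps_per_column
         else if (inherits(result, "pair_scores")) result$sps_per_column
         else stop_format("'result' must come from sum_of_pairs() or compare_alignments()")
  df <- data.frame(column = seq_along(spc),
                   sps = ifelse(is.nan(spc), NA_real_, spc))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$sps)) +
    ggplot2::geom_line(colour = "#0072B2", na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, colour = "#0072B2", na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Reference alignment column",
                  y = "Sum-of-pairs score") +
    ggplot2::theme_minimal()
  if (all(is.na(df$sps))) {
    gg <- gg + ggplot2::annotate("text", x = mean(df$column), y = 0.5,
                                 label = "no column has two or more residues")
  }
  gg
}
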