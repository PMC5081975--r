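# Core of the column-equivalency comparison method: occurrence encoding,
# the column-pair similarity matrix, best-match column pairing, per-cell
# categorisation, and the summary scores.

#' Category labels for alignment disagreement
#'
#' The five mutually exclusive, exhaustive categories a reference cell can
#' fall into once its column is paired with its best-matching comparison
#' column. Codes 1-5 in this order are used wherever categories are stored
#' as integers.
#'
#' @return Character vector
#'   `c("match", "conserved_gap", "merge", "split", "shift")`.
#' @details With the default orientation, a *merge* is a gap in the
#'   reference aligned against a residue in the comparison (the comparison
#'   packed residues into fewer columns) and a *split* is a reference
#'   residue aligned against a comparison gap. `compare_alignments()` and
#'   the CLI expose a switch to swap the two labels.
#' @export
category_labels <- function() {
  c("match", "conserved_gap", "merge", "split", "shift")
}

#' Occurrence-encode an alignment
#'
#' Labels every non-gap cell with its residue symbol plus the number of
#' times that symbol has already appeared in the same row (counting non-gap
#' cells left to right), so that every non-gap cell is unique within its
#' row. Two cells of different alignments are then equivalent only when
#' they hold the same occurrence of the same residue, which distinguishes
#' columns that align non-homologous occurrences of a repeated residue.
#'
#' @param a An `msa_aln` object.
#' @return An object of class `msa_enc`: a list with `labels` (n x width
#'   character matrix of labels such as `"A1"`, `"A2"`, `"C1"`, with `"-"`
#'   for gaps) and `upos` (n x width integer matrix giving each non-gap
#'   cell's ungapped position in its row, 0 for gaps).
#' @examples
#' a <- alignment(c("AC-AG", "ACA-G"))
#' encode_occurrences(a)$labels[1, ]
#' @export
encode_occurrences <- function(a) {
  assert_alignment(a)
  labels <- matrix("-", a$n, a$width)
  upos <- matrix(0L, a$n, a$width)
  for (x in seq_len(a$n)) {
    r <- a$rows[x, ]
    ng <- which(r != "-")
    if (length(ng)) {
      syms <- r[ng]
      occ <- stats::ave(seq_along(syms), syms, FUN = seq_along)
      labels[x, ng] <- paste0(syms, occ)
      upos[x, ng] <- seq_along(ng)
    }
  }
  rownames(labels) <- a$ids
  rownames(upos) <- a$ids
  structure(list(labels = labels, upos = upos, ids = a$ids,
                 n = a$n, width = a$width),
            class = "msa_enc")
}

assert_encoded <- function(x, arg = "encoded alignment") {
  if (!inherits(x, "msa_enc")) {
    stop_format(sprintf("'%s' must come from encode_occurrences()", arg))
  }
  x
}

#' Equivalency of two occurrence-encoded cells
#'
#' The binary equivalency underlying the similarity matrix: 1 when both
#' cells are non-gap and carry the same residue symbol *and* the same
#' occurrence index, 0 otherwise. In particular two gaps score 0, and the
#' first `"A"` of a row is never equivalent to the second.
#'
#' @param a,b Occurrence-encoded cell labels (e.g. `"A2"`), `"-"` for gaps.
#'   Vectorised.
#' @return Integer 0/1 vector.
#' @examples
#' cell_equivalent("A1", "A1")  # 1
#' cell_equivalent("A1", "A2")  # 0
#' cell_equivalent("-", "-")    # 0
#' @export
cell_equivalent <- function(a, b) {
  as.integer(a != "-" & b != "-" & a == b)
}

#' Column-pair similarity matrix of two alignments
#'
#' For every pair of a reference column `i` and a comparison column `j`,
#' the fraction of rows whose occurrence-encoded cells are equivalent:
#' \deqn{S_{ij} = \frac{1}{n} \sum_{x=1}^{n} \varepsilon(P_{xi}, Q_{xj})}
#' where \eqn{\varepsilon} is [cell_equivalent()]. Every entry is a
#' rational with denominator n.
#'
#' @param Penc,Qenc Occurrence-encoded alignments ([encode_occurrences()])
#'   with equal row counts and corresponding rows (see [validate_pair()]).
#' @return A p x q numeric matrix with entries in `[0, 1]`.
#' @details Because occurrence-encoded labels are unique within a row, each
#'   row contributes at most one equivalent cell per label; the matrix is
#'   accumulated from those sparse hits in O(n * width) rather than by the
#'   O(n * p * q) double loop over column pairs, which keeps comparisons of
#'   1000-sequence, 1000-column alignments fast.
#' @examples
#' P <- encode_occurrences(alignment(c("ACG", "A-G")))
#' Q <- encode_occurrences(alignment(c("ACG", "AG-")))
#' similarity_matrix(P, Q)
#' @export
similarity_matrix <- function(Penc, Qenc) {
  assert_encoded(Penc, "Penc")
  assert_encoded(Qenc, "Qenc")
  n <- Penc$n
  if (n != Qenc$n) {
    stop_validation(sprintf("row counts differ: %d vs %d", n, Qenc$n))
  }
  p <- Penc$width
  q <- Qenc$width
  if (as.double(p) * q >= 2^31) {
    stop_format("similarity matrix too large to index")
  }
  keys <- vector("list", n)
  for (x in seq_len(n)) {
    lp <- Penc$labels[x, ]
    lq <- Qenc$labels[x, ]
    j <- which(lq != "-")
    i <- match(lq[j], lp)         # labels are unique within a row
    keep <- !is.na(i)
    keys[[x]] <- (j[keep] - 1L) * p + i[keep]
  }
  counts <- tabulate(unlist(keys, use.names = FALSE), nbins = p * q)
  S <- matrix(counts / n, nrow = p, ncol = q)
  dimnames(S) <- list(seq_len(p), seq_len(q))
  S
}

#' Pair each reference column with its best-matching comparison column
#'
#' For each reference column `i`, the match is the comparison column `j`
#' maximising `S[i, j]`. Ties (including all-zero rows of S) are broken by
#' the smallest `|j - i|`, then the smallest `j`, and are flagged so they
#' can be audited.
#'
#' @param S Similarity matrix from [similarity_matrix()].
#' @return An object of class `match_vector`: list with `match` (integer,
#'   length p) and `tie_flags` (logical, length p).
#' @examples
#' S <- matrix(c(1, 0, 0, 0, 0.5, 0.5, 0, 0, 0.5), 3, 3, byrow = TRUE)
#' match_columns(S)$match
#' @export
match_columns <- function(S) {
  if (!is.matrix(S) || !is.numeric(S)) {
    stop_format("'S' must be a numeric similarity matrix")
  }
  p <- nrow(S)
  q <- ncol(S)
  match <- integer(p)
  tie_flags <- logical(p)
  for (i in seq_len(p)) {
    row <- S[i, ]
    js <- which(row == max(row))
    if (length(js) > 1L) {
      tie_flags[i] <- TRUE
      d <- abs(js - i)
      js <- js[d == min(d)]
    }
    match[i] <- min(js)
  }
  structure(list(match = match, tie_flags = tie_flags),
            class = "match_vector")
}

as_match_vector <- function(m, p) {
  if (inherits(m, "match_vector")) return(m)
  m <- as.integer(m)
  if (length(m) != p) stop_format("match vector length does not equal p")
  structure(list(match = m, tie_flags = logical(p)), class = "match_vector")
}

#' Categorise every reference cell against its matched comparison cell
#'
#' Once reference column `i` is paired with comparison column `j =
#' match[i]`, each cell pair `(a, b) = (P[x, i], Q[x, j])` falls into
#' exactly one of five categories: *match* (equal non-gap labels),
#' *conserved gap* (both gaps), *merge* (gap in the reference against a
#' comparison residue), *split* (reference residue against a comparison
#' gap), or *shift* (unequal non-gap labels, i.e. a homology
#' reassignment).
#'
#' @param Penc,Qenc Occurrence-encoded alignments.
#' @param match A `match_vector` from [match_columns()] (or a bare integer
#'   vector of length p).
#' @param swap_merge_split Logical; if `TRUE` the *merge* and *split*
#'   labels are exchanged (i.e. merge = comparison gap, split = reference
#'   gap).
#' @return An n x p integer matrix of category codes 1-5 (see
#'   [category_labels()]), class `category_matrix`, with the label set in
#'   attribute `"categories"`.
#' @examples
#' P <- encode_occurrences(alignment(c("ACG", "A-G")))
#' Q <- encode_occurrences(alignment(c("ACG", "AG-")))
#' m <- match_columns(similarity_matrix(P, Q))
#' dissimilarity_matrix(P, Q, m)
#' @export
dissimilarity_matrix <- function(Penc, Qenc, match,
                                 swap_merge_split = FALSE) {
  assert_encoded(Penc, "Penc")
  assert_encoded(Qenc, "Qenc")
  m <- as_match_vector(match, Penc$width)
  if (any(m$match < 1L | m$match > Qenc$width)) {
    stop_format("match vector indexes outside the comparison alignment")
  }
  A <- Penc$labels
  B <- Qenc$labels[, m$match, drop = FALSE]
  agap <- A == "-"
  bgap <- B == "-"
  merge_code <- if (swap_merge_split) 4L else 3L
  split_code <- if (swap_merge_split) 3L else 4L
  codes <- matrix(5L, Penc$n, Penc$width)    # shift unless shown otherwise
  codes[A == B & !agap] <- 1L
  codes[agap & bgap] <- 2L
  codes[agap & !bgap] <- merge_code
  codes[!agap & bgap] <- split_code
  rownames(codes) <- Penc$ids
  structure(codes, class = c("category_matrix", class(codes)),
            categories = category_labels())
}

#' Per-column category proportions
#'
#' Collapses the cell-level category matrix to a 5 x p matrix whose entry
#' `(k, i)` is the proportion of sequences whose cell in reference column
#' `i` falls in category `k` (row order: match, conserved gap, merge,
#' split, shift). Every column sums to 1.
#'
#' @param D Category matrix from [dissimilarity_matrix()].
#' @return A 5 x p numeric matrix with category rownames.
#' @export
results_matrix <- function(D) {
  if (!is.matrix(D) || !all(D %in% 1:5)) {
    stop_format("'D' must be an integer category matrix with codes 1-5")
  }
  n <- nrow(D)
  R <- vapply(seq_len(ncol(D)), function(i) tabulate(D[, i], 5L),
              integer(5L)) / n
  rownames(R) <- category_labels()
  colnames(R) <- seq_len(ncol(D))
  R
}

#' Overall similarity score of two alignments
#'
#' The proportion of matching characters among all characters that are not
#' conserved gaps:
#' \deqn{\mathrm{score} = \frac{\frac1p\sum_i R_{1i}}{1 - \frac1p\sum_i R_{2i}}}
#' Conserved gaps are excluded from the denominator so that shared gaps in
#' low-occupancy columns do not inflate the score.
#'
#' @param R Results matrix from [results_matrix()].
#' @return A fraction in `[0, 1]`.
#' @export
overall_score <- function(R) {
  if (!is.matrix(R) || nrow(R) != 5L) {
    stop_format("'R' must be a 5 x p results matrix")
  }
  cg <- mean(R[2L, ])
  if (cg >= 1) {
    stop_validation("overall score is undefined: the alignment pair consists entirely of conserved gaps")
  }
  mean(R[1L, ]) / (1 - cg)
}

#' Proportion of perfectly reproduced reference columns
#'
#' A stricter score than [overall_score()]: the fraction of reference
#' columns whose cells are all matches or conserved gaps, i.e. columns
#' reproduced exactly (for every sequence) by their matched comparison
#' column.
#'
#' @param D Category matrix from [dissimilarity_matrix()].
#' @return A fraction in `[0, 1]`.
#' @export
column_score <- function(D) {
  if (!is.matrix(D) || !all(D %in% 1:5)) {
    stop_format("'D' must be an integer category matrix with codes 1-5")
  }
  mean(colSums(D <= 2L) == nrow(D))
}

#' Per-column similarity and dissimilarity summaries
#'
#' Normalises each column of the results matrix to the proportion of
#' characters that are not conserved gaps: `match_i / (1 - conserved_gap_i)`
#' and likewise for merge, split and shift. Columns consisting entirely of
#' conserved gaps have no non-gap characters and are reported as `NA`
#' (they are omitted from the summary plots).
#'
#' @param R Results matrix from [results_matrix()].
#' @return A data.frame with columns `column`, `match`, `merge`, `split`,
#'   `shift` (all proportions in `[0, 1]` or `NA`).
#' @export
per_column_summaries <- function(R) {
  if (!is.matrix(R) || nrow(R) != 5L) {
    stop_format("'R' must be a 5 x p results matrix")
  }
  denom <- 1 - R[2L, ]
  undef <- denom <= 0
  norm <- function(k) {
    v <- R[k, ] / denom
    v[undef] <- NA_real_
    unname(v)
  }
  data.frame(column = seq_len(ncol(R)),
             match = norm(1L), merge = norm(3L),
             split = norm(4L), shift = norm(5L))
}

#' Per-column cysteine proportion
#'
#' The fraction of sequences with a `"C"` in each column. Useful alongside
#' the similarity summary for cysteine-rich protein families, whose
#' alignment accuracy often hinges on key cysteine motifs. For nucleotide
#' alignments this is simply the proportion of the literal symbol `"C"`
#' (cytosine).
#'
#' @param a An `msa_aln` object.
#' @return Numeric vector of length `width` with values in `[0, 1]`.
#' @export
cysteine_proportion <- function(a) {
  assert_alignment(a)
  unname(colMeans(a$rows == "C"))
}

#' Compare two alternative multiple sequence alignments
#'
#' The package's main entry point. Validates that the two alignments
#' contain the same ungapped sequences, pairs their rows, occurrence-encodes
#' both, computes the column-pair similarity matrix S, pairs each reference
#' column with its best-matching comparison column, categorises every
#' reference cell (match / conserved gap / merge / split / shift), and
#' derives the summary scores, including the classical sum-of-pairs and
#' total column scores.
#'
#' @param reference,comparison `msa_aln` objects or file paths (passed to
#'   [read_alignment()]). The reference indexes all per-cell and per-column
#'   results.
#' @param format Format passed to [read_alignment()] when paths are given.
#' @param swap_merge_split Logical; swap the merge and split labels (see
#'   [dissimilarity_matrix()]).
#' @param reference_name,comparison_name Optional display names; default to
#'   file basenames or `"reference"` / `"comparison"`.
#'
#' @return An object of class `pac` (pairwise alignment comparison): a list
#'   with the input alignments (`reference`, `comparison`, the latter with
#'   rows reordered to correspond to the reference), `S` (p x q similarity
#'   matrix), `D` (n x p category matrix), `R` (5 x p results matrix),
#'   `match` and `tie_flags` (column pairing), `overall_score`,
#'   `column_score`, `sps` and `sps_per_column` (sum-of-pairs), `cs` (total
#'   column score), `summary` (per-column normalised proportions), and
#'   `warnings`.
#'
#' @examples
#' ref <- alignment(c("ACG", "A-G"), ids = c("s1", "s2"))
#' cmp <- alignment(c("ACG", "AG-"), ids = c("s1", "s2"))
#' pac <- compare_alignments(ref, cmp)
#' pac$overall_score
#' @export
compare_alignments <- function(reference, comparison, format = "auto",
                               swap_merge_split = FALSE,
                               reference_name = NULL,
                               comparison_name = NULL) {
  if (is.character(reference) && !is.matrix(reference)) {
    if (is.null(reference_name)) reference_name <- basename(reference)
    reference <- read_alignment(reference, format)
  }
  if (is.character(comparison) && !is.matrix(comparison)) {
    if (is.null(comparison_name)) comparison_name <- basename(comparison)
    comparison <- read_alignment(comparison, format)
  }
  assert_alignment(reference, "reference")
  assert_alignment(comparison, "comparison")
  if (is.null(reference_name)) reference_name <- "reference"
  if (is.null(comparison_name)) comparison_name <- "comparison"

  val <- validate_pair(reference, comparison)
  comparison <- alignment(comparison$rows[val$row_order, , drop = FALSE],
                          ids = comparison$ids[val$row_order],
                          normalise = FALSE)

  Penc <- encode_occurrences(reference)
  Qenc <- encode_occurrences(comparison)
  S <- similarity_matrix(Penc, Qenc)
  mv <- match_columns(S)
  D <- dissimilarity_matrix(Penc, Qenc, mv,
                            swap_merge_split = swap_merge_split)
  R <- results_matrix(D)
  ps <- sum_of_pairs_encoded(Penc, Qenc)

  # overall score from integer cell counts: identical in exact arithmetic
  # to overall_score(R), but free of floating-point summation error, so a
  # self-comparison scores exactly 1
  n_match <- sum(D == 1L)
  n_cg <- sum(D == 2L)
  if (n_cg == length(D)) {
    stop_validation("overall score is undefined: the alignment pair consists entirely of conserved gaps")
  }

  structure(list(
    reference_name = reference_name,
    comparison_name = comparison_name,
    reference = reference,
    comparison = comparison,
    S = S, D = D, R = R,
    match = mv$match, tie_flags = mv$tie_flags,
    overall_score = n_match / (length(D) - n_cg),
    column_score = column_score(D),
    sps = ps$sps_overall,
    sps_per_column = ps$sps_per_column,
    cs = ps$cs_overall,
    summary = per_column_summaries(R),
    swap_merge_split = swap_merge_split,
    warnings = val$warnings
  ), class = "pac")
}

#' @export
print.pac <- function(x, ...) {
  cat("Pairwise alignment comparison\n")
  cat(sprintf("  reference:  %s (%d x %d)\n",
              x$reference_name, x$reference$n, x$reference$width))
  cat(sprintf("  comparison: %s (%d x %d)\n",
              x$comparison_name, x$comparison$n, x$comparison$width))
  cat(sprintf("  overall similarity score: %.1f%%\n", 100 * x$overall_score))
  cat(sprintf("  identical-column score:   %.1f%%\n", 100 * x$column_score))
  cat(sprintf("  sum-of-pairs score (SPS): %.1f%%\n", 100 * x$sps))
  cat(sprintf("  total column score (CS):  %.1f%%\n", 100 * x$cs))
  if (any(x$tie_flags)) {
    cat(sprintf("  note: %d column match(es) involved ties\n",
                sum(x$tie_flags)))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
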