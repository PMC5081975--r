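#' Read a multiple sequence alignment from file
#'
#' Reads an alignment in FASTA, Clustal, MSF, or Phylip format and returns
#' a normalised [alignment()] object (residues uppercased; the gap symbols
#' `"."` and `"~"` unified to `"-"`).
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"` (default), `"fasta"`, `"clustal"`, `"msf"`,
#'   `"phylip"`. With `"auto"` the format is detected from the file content:
#'   a `CLUSTAL` header, an MSF header (`MSF:` or `!!`), a numeric Phylip
#'   first line, otherwise FASTA if the first non-blank character is `>`.
#'
#' @return An `msa_aln` object.
#'
#' @details Parsing is delegated to \pkg{Biostrings} (FASTA, Clustal,
#'   Phylip) and \pkg{seqinr} (MSF). Ragged input (sequences of unequal
#'   aligned length) raises a format error naming the offending sequence.
#'
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-G", ">s2", "A-CG"), fa)
#' read_alignment(fa)
#' @export
read_alignment <- function(path,
                           format = c("auto", "fasta", "clustal", "msf",
                                      "phylip")) {
  format <- match.arg(format)
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop_io("'path' must be a single non-empty file path")
  }
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (format == "auto") format <- sniff_format(path)
  parsed <- switch(format,
    fasta   = read_aln_fasta(path),
    clustal = read_aln_biostrings(path, "clustal"),
    phylip  = read_aln_biostrings(path, "phylip"),
    msf     = read_aln_msf(path)
  )
  alignment(parsed$seqs, ids = parsed$ids)
}

# Content-based format detection; order matters (Clustal and MSF headers are
# unambiguous, a numeric first line is Phylip, ">" falls through to FASTA).
sniff_format <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format(sprintf("file is empty: %s", path))
  first <- trimws(lines[1L])
  if (startsWith(toupper(first), "CLUSTAL")) return("clustal")
  if (startsWith(first, "!!") || any(grepl("MSF:", lines, fixed = TRUE))) {
    return("msf")
  }
  if (grepl("^[0-9]+[ \t]+[0-9]+$", first)) return("phylip")
  if (startsWith(first, ">")) return("fasta")
  stop_format(sprintf(
    "cannot determine alignment format of %s; supported formats: fasta, clustal, msf, phylip",
    path))
}

read_aln_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop_format(sprintf("failed to parse %s as FASTA: %s",
                                        path, conditionMessage(e)))
                  })
  if (length(set) == 0L) stop_format(sprintf("no sequences found in %s", path))
  widths <- Biostrings::width(set)
  if (length(unique(widths)) > 1L) {
    off <- which(widths != widths[1L])[1L]
    stop_format(sprintf(
      "ragged alignment in %s: sequence %s has %d columns, expected %d",
      path, names(set)[off], widths[off], widths[1L]))
  }
  # FASTA ids: first whitespace-delimited token of the description line
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1L), 1L)
  list(ids = ids, seqs = as.character(set))
}

read_aln_biostrings <- function(path, fmt) {
  set <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = fmt),
    error = function(e) {
      stop_format(sprintf("failed to parse %s as %s: %s",
                          path, fmt, conditionMessage(e)))
    })
  set <- methods::as(set, "AAStringSet")
  list(ids = names(set), seqs = as.character(set))
}

read_aln_msf <- function(path) {
  ali <- tryCatch(
    seqinr::read.alignment(path, format = "msf", forceToLower = FALSE),
    error = function(e) {
      stop_format(sprintf("failed to parse %s as MSF: %s",
                          path, conditionMessage(e)))
    })
  seqs <- unlist(ali$seq, use.names = FALSE)
  widths <- nchar(seqs)
  ids <- trimws(ali$nam)
  if (length(unique(widths)) > 1L) {
    off <- which(widths != widths[1L])[1L]
    stop_format(sprintf(
      "ragged alignment in %s: sequence %s has %d columns, expected %d",
      path, ids[off], widths[off], widths[1L]))
  }
  list(ids = ids, seqs = seqs)
}

#' Validate that two alignments are comparable and pair their rows
#'
#' Two alignments are comparable when they are alternative alignments of
#' the same set of ungapped sequences. Rows are paired by identifier when
#' the two id sets are equal, otherwise by unique de-gapped sequence
#' content (with a warning recorded). Ambiguous content matching -
#' duplicated de-gapped sequences whose ids disagree - is an error.
#'
#' @param reference,comparison `msa_aln` objects.
#'
#' @return An object of class `pair_validation`: a list with `row_order`
#'   (integer permutation; `row_order[x]` is the comparison row holding the
#'   same ungapped sequence as reference row `x`) and `warnings`
#'   (character vector of notes).
#'
#' @examples
#' a <- alignment(c("AC-G", "A-CG"), ids = c("s1", "s2"))
#' b <- alignment(c("A-CG", "ACG-"), ids = c("s2", "s1"))
#' validate_pair(a, b)$row_order
#' @export
validate_pair <- function(reference, comparison) {
  assert_alignment(reference, "reference")
  assert_alignment(comparison, "comparison")
  if (reference$n != comparison$n) {
    stop_validation(sprintf(
      "alignments have different sequence counts: %d vs %d",
      reference$n, comparison$n))
  }
  warnings <- character()
  ref_seq <- degapped_rows(reference)
  cmp_seq <- degapped_rows(comparison)

  if (setequal(reference$ids, comparison$ids)) {
    row_order <- match(reference$ids, comparison$ids)
    bad <- which(ref_seq != cmp_seq[row_order])
    if (length(bad)) {
      stop_validation(sprintf(
        "sequence %s differs between the alignments once gaps are removed",
        reference$ids[bad[1L]]))
    }
  } else {
    warnings <- c(warnings,
                  "sequence ids differ between alignments; rows were paired by ungapped sequence content")
    if (anyDuplicated(ref_seq) || anyDuplicated(cmp_seq)) {
      dup <- c(ref_seq[duplicated(ref_seq)], cmp_seq[duplicated(cmp_seq)])[1L]
      stop_validation(sprintf(
        "cannot pair rows unambiguously: duplicated ungapped sequence (%s...) with mismatched ids",
        substr(dup, 1L, 12L)))
    }
    row_order <- match(ref_seq, cmp_seq)
    if (anyNA(row_order)) {
      miss <- which(is.na(row_order))[1L]
      stop_validation(sprintf(
        "sequence %s of the reference has no counterpart in the comparison alignment",
        reference$ids[miss]))
    }
  }
  structure(list(row_order = row_order, warnings = warnings),
            class = "pair_validation")
}

#' @export
print.pair_validation <- function(x, ...) {
  cat("Alignment pair validation\n")
  cat("  row order:", paste(x$row_order, collapse = " "), "\n")
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n    ")
  invisible(x)
}

#' Write a result matrix to CSV
#'
#' Writes any 2-D result matrix (similarity matrix, category-code matrix,
#' results matrix) as CSV with header row and column labels. Unlabelled
#' dimensions receive 1-based indices, matching the column numbering used
#' throughout the package.
#'
#' @param matrix A numeric or integer matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_matrix(diag(3), f)
#' @export
write_matrix <- function(matrix, path) {
  if (!is.matrix(matrix)) stop_format("'matrix' must be a matrix")
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop_io("'path' must be a single non-empty file path")
  }
  m <- matrix
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  ok <- tryCatch({
    utils::write.csv(as.data.frame(m), file = path, row.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Write the comparison summary as JSON
#'
#' Serialises the scalar summaries of a pairwise alignment comparison
#' (overall score, column score, sum-of-pairs score, total column score,
#' dimensions, warnings) to a JSON file.
#'
#' @param pac A `pac` object from [compare_alignments()].
#' @param path Output file path.
#' @param extra Optional named list merged into the JSON object (e.g. a
#'   generator seed).
#' @return Invisibly, `path`.
#' @export
write_summary <- function(pac, path, extra = list()) {
  if (!inherits(pac, "pac")) stop_format("'pac' must come from compare_alignments()")
  out <- c(list(
    reference_name = pac$reference_name,
    comparison_name = pac$comparison_name,
    n = pac$reference$n,
    reference_width = pac$reference$width,
    comparison_width = pac$comparison$width,
    overall_score = pac$overall_score,
    column_score = pac$column_score,
    sum_of_pairs_score = pac$sps,
    total_column_score = pac$cs,
    merge_split_swapped = pac$swap_merge_split,
    category_codes = as.list(stats::setNames(1:5, category_labels())),
    warnings = pac$warnings
  ), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
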