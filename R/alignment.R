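#' Construct a multiple sequence alignment object
#'
#' An `msa_aln` is the package's container for one multiple sequence
#' alignment: a rectangular character matrix of uppercase residue symbols
#' plus the gap symbol `"-"`, with one row per sequence.
#'
#' @param rows Character matrix (n sequences x width columns) of single
#'   characters, or a character vector of equal-length aligned sequence
#'   strings (one per sequence).
#' @param ids Character vector of unique sequence identifiers, one per row.
#' @param normalise Logical; if `TRUE` (default) residues are uppercased and
#'   the alternative gap symbols `"."` and `"~"` are mapped to `"-"`.
#'
#' @return An object of class `msa_aln`: a list with elements `ids`
#'   (character), `rows` (n x width character matrix with `ids` as
#'   rownames), `n` (sequence count) and `width` (column count).
#'
#' @details Invariants enforced: at least two sequences, at least one
#'   column, all rows the same length, unique identifiers, and every cell
#'   either `"-"` or an alphabetic residue symbol. Violations raise a
#'   format error.
#'
#' @examples
#' aln <- alignment(c("AC-G", "A-CG"), ids = c("s1", "s2"))
#' aln$width
#' @export
alignment <- function(rows, ids = NULL, normalise = TRUE) {
  if (is.character(rows) && !is.matrix(rows)) {
    widths <- nchar(rows)
    if (length(unique(widths)) > 1L) {
      off <- which(widths != widths[1L])[1L]
      nm <- if (!is.null(ids)) ids[off] else paste("sequence", off)
      stop_format(sprintf(
        "aligned sequences have unequal lengths: %s has %d characters, expected %d",
        nm, widths[off], widths[1L]))
    }
    rows <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  }
  if (!is.matrix(rows) || !is.character(rows)) {
    stop_format("'rows' must be a character matrix or vector of aligned strings")
  }
  if (is.null(ids)) ids <- rownames(rows)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(rows)))
  ids <- as.character(ids)
  if (normalise) {
    rows[] <- chartr(".~", "--", toupper(rows))
  }
  if (nrow(rows) < 2L) stop_format("an alignment needs at least 2 sequences")
  if (ncol(rows) < 1L) stop_format("an alignment needs at least 1 column")
  if (length(ids) != nrow(rows)) {
    stop_format("number of ids does not match number of sequences")
  }
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicated sequence identifier: %s",
                        ids[duplicated(ids)][1L]))
  }
  bad <- !(rows == "-" | grepl("^[A-Z]$", rows))
  if (any(bad)) {
    cell <- which(bad, arr.ind = TRUE)[1L, ]
    stop_format(sprintf(
      "invalid alignment character '%s' in sequence %s, column %d",
      rows[bad][1L], ids[cell[1L]], cell[2L]))
  }
  rownames(rows) <- ids
  colnames(rows) <- NULL
  structure(list(ids = ids, rows = rows,
                 n = nrow(rows), width = ncol(rows)),
            class = "msa_aln")
}

#' @export
print.msa_aln <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              x$n, x$width))
  shown <- utils::head(seq_len(x$n), 8L)
  seqs <- apply(x$rows[shown, , drop = FALSE], 1L, paste, collapse = "")
  if (x$width > 60L) seqs <- paste0(substr(seqs, 1L, 60L), "...")
  cat(sprintf("  %-12s %s\n", substr(x$ids[shown], 1L, 12L), seqs), sep = "")
  if (x$n > 8L) cat(sprintf("  ... and %d more sequences\n", x$n - 8L))
  invisible(x)
}

is_msa_aln <- function(x) inherits(x, "msa_aln")

assert_alignment <- function(x, arg = "alignment") {
  if (!is_msa_aln(x)) {
    stop_format(sprintf("'%s' must be an msa_aln object (see read_alignment())",
                        arg))
  }
  x
}

# De-gapped sequence string of every row.
degapped_rows <- function(a) {
  vapply(seq_len(a$n), function(x) {
    r <- a$rows[x, ]
    paste(r[r != "-"], collapse = "")
  }, character(1L))
}
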