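# Random test-case builders. Callers set the seed; everything here is
# plain sampling.

# Random gapping of given ungapped sequences into `width` columns
random_gapping <- function(seqs, width, ids = sprintf("s%d", seq_along(seqs))) {
  rows <- matrix("-", length(seqs), width)
  for (x in seq_along(seqs)) {
    chars <- strsplit(seqs[x], "")[[1]]
    pos <- sort(sample.int(width, length(chars)))
    rows[x, pos] <- chars
  }
  alignment(rows, ids = ids, normalise = FALSE)
}

# A pair of alternative alignments of the same random sequences
random_pair <- function(n_max = 6L, width_max = 8L,
                        alphabet = c("A", "C", "G", "T")) {
  n <- sample(2:n_max, 1L)
  width <- sample(2:width_max, 1L)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample.int(width, 1L), replace = TRUE),
          collapse = "")
  }, character(1L))
  ids <- sprintf("s%d", seq_len(n))
  list(ref = random_gapping(seqs, width, ids),
       cmp = random_gapping(seqs, width, ids))
}

aln_strings <- function(a) apply(a$rows, 1L, paste, collapse = "")

degapped <- function(a) {
  apply(a$rows, 1L, function(r) paste(r[r != "-"], collapse = ""))
}

# deterministic fixture base: full occupancy except a gap window in
# rows 1:2, columns 7:9 (room for shift_block to land in)
block_base <- function(n = 6, width = 12, seed = 11) {
  set.seed(seed)
  rows <- matrix(sample(c("A", "C", "D", "E", "F", "G", "H", "K"),
                        n * width, replace = TRUE), n, width)
  rows[1:2, 7:9] <- "-"
  alignment(rows, ids = sprintf("s%d", seq_len(n)), normalise = FALSE)
}

tiny_path <- function(ext) {
  system.file("extdata", paste0("tiny.", ext), package = "msadiff")
}

# The hand-checked two-sequence, three-column worked example used across
# the test files
worked_example <- function() {
  list(ref = alignment(c("ACG", "A-G"), ids = c("s1", "s2")),
       cmp = alignment(c("ACG", "AG-"), ids = c("s1", "s2")))
}
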