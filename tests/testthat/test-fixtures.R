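pert_cases <- function(a) {
  # one applicable perturbation of each kind for a full-occupancy block
  # with a gap region in rows 1:2, columns 7:9
  list(
    perturbation("insert_gap_column", at = 3),
    perturbation("split_column", column = 4, rows = 1:2),
    perturbation("shift_block", rows = 1:2, columns = c(4, 6), offset = 3),
    perturbation("translocate_rows", rows = a$n, offset = 2)
  )
}

test_that("every perturbation preserves each row's ungapped sequence", {
  set.seed(301)
  for (rep in 1:20) {
    a <- block_base(seed = 300 + rep)
    before <- vapply(seq_len(a$n),
                     function(x) paste(a$rows[x, a$rows[x, ] != "-"],
                                       collapse = ""), character(1))
    for (pert in pert_cases(a)) {
      b <- apply_perturbation(a, pert)
      after <- vapply(seq_len(b$n),
                      function(x) paste(b$rows[x, b$rows[x, ] != "-"],
                                        collapse = ""), character(1))
      expect_identical(unname(after), unname(before))
      expect_true(inherits(validate_pair(a, b), "pair_validation"))
    }
  }
})

test_that("perturbation chains still preserve ungapped sequences", {
  set.seed(302)
  for (rep in 1:10) {
    a <- block_base(seed = 400 + rep)
    fp <- generate_pair(a, pert_cases(a)[c(1, 2, 4)])
    expect_identical(unname(degapped(fp$comparison)), unname(degapped(fp$reference)))
  }
})

test_that("inapplicable perturbations raise usage errors", {
  a <- block_base()
  expect_error(apply_perturbation(a, perturbation("insert_gap_column", at = 99)),
               class = "msadiff_usage_error")
  expect_error(apply_perturbation(a, perturbation("split_column", column = 7,
                                                  rows = 1)),      # gap cell
               class = "msadiff_usage_error")
  expect_error(apply_perturbation(a, perturbation("merge_columns", column = 1)),
               class = "msadiff_usage_error")  # occupancy not complementary
  expect_error(apply_perturbation(a, perturbation("shift_block", rows = 3,
                                                  columns = c(4, 6), offset = 3)),
               class = "msadiff_usage_error")  # landing region occupied
})

test_that("generate_pair is deterministic under a fixed seed", {
  fp1 <- generate_pair(list(n = 6, width = 20),
                       list(perturbation("insert_gap_column", at = 5)),
                       seed = 99)
  fp2 <- generate_pair(list(n = 6, width = 20),
                       list(perturbation("insert_gap_column", at = 5)),
                       seed = 99)
  expect_identical(fp1, fp2)
})

test_that("an unperturbed pair predicts and achieves a perfect score", {
  fp <- generate_pair(list(n = 4, width = 12), list(), seed = 5)
  expect_true(fp$predicted)
  expect_identical(fp$expected$overall_score, 1)
  pac <- compare_alignments(fp$reference, fp$comparison)
  expect_identical(pac$overall_score, 1)
})

test_that("a single split produces exactly the predicted split cells", {
  set.seed(303)
  rows <- matrix(sample(c("A", "C", "G", "T"), 4 * 8, replace = TRUE), 4, 8)
  base <- alignment(rows, normalise = FALSE)
  fp <- generate_pair(base, list(perturbation("split_column", column = 3,
                                              rows = 1)))
  expect_true(fp$predicted)
  pac <- compare_alignments(fp$reference, fp$comparison)
  # the moved residue becomes the sole SPLIT cell, at (row 1, column 3)
  expect_identical(which(pac$D == 4L), which(matrix(seq_len(32), 4, 8) == 9))
  counts <- tabulate(pac$D, 5)
  expect_identical(counts, unname(as.integer(fp$expected$category_counts)))
})

test_that("translocated rows show up as a shift/merge block in D", {
  a <- block_base(n = 8, width = 12, seed = 12)
  fp <- generate_pair(a, list(perturbation("translocate_rows", rows = 7:8,
                                           offset = 3)))
  pac <- compare_alignments(fp$reference, fp$comparison)
  moved <- pac$D[7:8, , drop = FALSE]
  kept <- pac$D[1:6, , drop = FALSE]
  expect_true(all(moved %in% c(3L, 4L, 5L)))   # merge / split / shift only
  expect_true(all(kept %in% c(1L, 2L)))        # anchors unaffected
})

test_that("the perturbation mini-language round-trips through the parser", {
  perts <- parse_perturbations(
    "split_column:column=3,rows=1-2; insert_gap_column:at=7;shift_block:rows=1+4,columns=2-5,offset=2")
  expect_length(perts, 3L)
  expect_identical(perts[[1]]$kind, "split_column")
  expect_identical(perts[[1]]$rows, 1:2)
  expect_identical(perts[[2]]$at, 7L)
  expect_identical(perts[[3]]$rows, c(1L, 4L))
  expect_identical(perts[[3]]$columns, c(2L, 5L))
  expect_identical(parse_perturbations(""), list())
  expect_error(parse_perturbations("warp_speed:factor=9"),
               class = "msadiff_usage_error")
})

test_that("cli_generate writes reproducible FASTA pairs and expectations", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  args <- c("--n", "6", "--length", "15", "--gap-prob", "0",
            "--perturb", "split_column:column=4,rows=1-2",
            "--seed", "42")
  expect_identical(cli_generate(c(args, "--out", out1)), 0L)
  expect_identical(cli_generate(c(args, "--out", out2)), 0L)
  for (f in c("reference.fasta", "comparison.fasta", "expected.json")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  exp <- jsonlite::read_json(file.path(out1, "expected.json"))
  expect_true(exp$predicted)

  # round trip: comparing the generated pair reproduces the expectations
  pac <- compare_alignments(file.path(out1, "reference.fasta"),
                            file.path(out1, "comparison.fasta"))
  counts <- tabulate(pac$D, 5)
  expect_identical(counts,
                   vapply(exp$expected_category_counts, as.integer,
                          integer(1), USE.NAMES = FALSE))
  expect_equal(pac$overall_score, exp$expected_overall_score,
               tolerance = 1e-12)
})

test_that("cli_compare writes matrices, summary and figures, and prints the score", {
  gen <- withr::local_tempdir()
  cmp <- withr::local_tempdir()
  expect_identical(cli_generate(c("--n", "4", "--length", "10",
                                  "--seed", "7", "--out", gen)), 0L)
  out <- capture.output(
    status <- cli_compare(c(file.path(gen, "reference.fasta"),
                            file.path(gen, "comparison.fasta"),
                            "--out", cmp, "--plots",
                            "similarity_heatmap,dissimilarity_matrix",
                            "--plot-format", "png")))
  expect_identical(status, 0L)
  expect_match(paste(out, collapse = "\n"), "overall similarity score: 1.0000")
  for (f in c("S.csv", "D.csv", "R.csv", "summary.json",
              "similarity_heatmap.png", "dissimilarity_matrix.png")) {
    expect_true(file.exists(file.path(cmp, f)))
  }
  js <- jsonlite::read_json(file.path(cmp, "summary.json"))
  expect_equal(js$overall_score, 1)

  # determinism of the text outputs
  cmp2 <- withr::local_tempdir()
  capture.output(cli_compare(c(file.path(gen, "reference.fasta"),
                               file.path(gen, "comparison.fasta"),
                               "--out", cmp2, "--plots", "none")))
  for (f in c("S.csv", "D.csv", "R.csv", "summary.json")) {
    expect_identical(readLines(file.path(cmp2, f)),
                     readLines(file.path(cmp, f)))
  }
})

test_that("the CLI maps failure kinds to distinct exit codes", {
  tmp <- withr::local_tempdir()
  # missing input file: I/O error, no partial outputs
  expect_identical(suppressMessages(
    cli_compare(c(file.path(tmp, "no.fa"), file.path(tmp, "no2.fa"),
                  "--out", file.path(tmp, "out")))), 2L)
  expect_false(dir.exists(file.path(tmp, "out")))

  # unparseable content: format error
  junk <- file.path(tmp, "junk.txt")
  writeLines("gibberish", junk)
  ok <- file.path(tmp, "ok.fasta")
  writeLines(c(">a", "AC", ">b", "AC"), ok)
  expect_identical(suppressMessages(cli_compare(c(junk, ok, "--out", tmp))), 3L)

  # incomparable alignments: validation error
  other <- file.path(tmp, "other.fasta")
  writeLines(c(">a", "GG", ">b", "GG"), other)
  expect_identical(suppressMessages(cli_compare(c(ok, other, "--out", tmp))), 4L)

  # bad flags: usage error
  expect_identical(suppressMessages(cli_compare(c(ok, ok, "--plots", "bogus"))), 1L)
  expect_identical(suppressMessages(cli_generate(c("--n", "1"))), 1L)

  # --format overrides auto-detection and can force a mismatch
  expect_identical(suppressMessages(
    cli_compare(c(ok, ok, "--format", "clustal", "--out", tmp))), 3L)
})

test_that("a cysteine scaffold places all-C columns where requested", {
  out <- withr::local_tempdir()
  expect_identical(cli_generate(c("--n", "32", "--length", "30",
                                  "--cys-columns", "5,12,20", "--seed", "3",
                                  "--out", out)), 0L)
  a <- read_alignment(file.path(out, "reference.fasta"))
  expect_identical(a$n, 32L)
  expect_true(all(a$rows[, c(5, 12, 20)] == "C"))
})
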