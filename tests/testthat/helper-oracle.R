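# Naive reference implementations of every quantity the package computes,
# written as direct loops over the definitions. These stay deliberately
# independent of the package's vectorised code paths and serve as oracles
# in the equivalence tests.

# Occurrence labels, counted left to right per row
oracle_encode <- function(rows) {
  out <- matrix("-", nrow(rows), ncol(rows))
  for (x in seq_len(nrow(rows))) {
    seen <- integer(0)
    for (i in seq_len(ncol(rows))) {
      ch <- rows[x, i]
      if (ch != "-") {
        k <- if (is.na(seen[ch])) 1L else seen[ch] + 1L
        seen[ch] <- k
        out[x, i] <- paste0(ch, k)
      }
    }
  }
  out
}

oracle_eps <- function(a, b) {
  if (a == b && a != "-") 1L else 0L
}

# Column-pair similarity by the triple loop
oracle_similarity <- function(Pl, Ql) {
  n <- nrow(Pl)
  S <- matrix(0, ncol(Pl), ncol(Ql))
  for (i in seq_len(ncol(Pl))) {
    for (j in seq_len(ncol(Ql))) {
      s <- 0L
      for (x in seq_len(n)) s <- s + oracle_eps(Pl[x, i], Ql[x, j])
      S[i, j] <- s / n
    }
  }
  S
}

# Argmax with the package's stated tie rule: smallest |j - i|, then
# smallest j
oracle_match <- function(S) {
  p <- nrow(S)
  m <- integer(p)
  for (i in seq_len(p)) {
    js <- which(S[i, ] == max(S[i, ]))
    if (length(js) > 1L) {
      d <- abs(js - i)
      js <- js[d == min(d)]
    }
    m[i] <- min(js)
  }
  m
}

# Category of each reference cell against its matched comparison cell,
# by the five predicates (merge = reference gap vs comparison residue)
oracle_categories <- function(Pl, Ql, m) {
  out <- matrix("", nrow(Pl), ncol(Pl))
  for (x in seq_len(nrow(Pl))) {
    for (i in seq_len(ncol(Pl))) {
      a <- Pl[x, i]
      b <- Ql[x, m[i]]
      out[x, i] <-
        if (a == b && a != "-") "match"
        else if (a == "-" && b == "-") "conserved_gap"
        else if (a == "-" && b != "-") "merge"
        else if (a != "-" && b == "-") "split"
        else "shift"
    }
  }
  out
}

oracle_results <- function(cats) {
  labs <- c("match", "conserved_gap", "merge", "split", "shift")
  R <- matrix(0, 5L, ncol(cats))
  for (i in seq_len(ncol(cats))) {
    for (k in seq_along(labs)) {
      s <- 0L
      for (x in seq_len(nrow(cats))) {
        if (cats[x, i] == labs[k]) s <- s + 1L
      }
      R[k, i] <- s / nrow(cats)
    }
  }
  R
}

# Overall score straight from its definition: matching characters as a
# proportion of characters that are not conserved gaps
oracle_overall <- function(cats) {
  m <- 0L
  cg <- 0L
  for (x in seq_len(nrow(cats))) {
    for (i in seq_len(ncol(cats))) {
      if (cats[x, i] == "match") m <- m + 1L
      if (cats[x, i] == "conserved_gap") cg <- cg + 1L
    }
  }
  m / (length(cats) - cg)
}

oracle_column_score <- function(cats) {
  ok <- 0L
  for (i in seq_len(ncol(cats))) {
    if (all(cats[, i] %in% c("match", "conserved_gap"))) ok <- ok + 1L
  }
  ok / ncol(cats)
}

# Ungapped position of every cell (0 for gaps), by loops
oracle_upos <- function(rows) {
  out <- matrix(0L, nrow(rows), ncol(rows))
  for (x in seq_len(nrow(rows))) {
    l <- 0L
    for (i in seq_len(ncol(rows))) {
      if (rows[x, i] != "-") {
        l <- l + 1L
        out[x, i] <- l
      }
    }
  }
  out
}

# Sum-of-pairs by exhaustive enumeration of (column, row pair) combinations
oracle_sps <- function(ref_rows, cmp_rows) {
  pu <- oracle_upos(ref_rows)
  qu <- oracle_upos(cmp_rows)
  # comparison column of residue instance (row, ungapped position)
  qcol_of <- function(x, l) {
    for (j in seq_len(ncol(cmp_rows))) if (qu[x, j] == l) return(j)
    stop("instance not found in comparison")
  }
  p <- ncol(ref_rows)
  retained <- numeric(p)
  total <- numeric(p)
  for (i in seq_len(p)) {
    rows <- which(pu[, i] > 0L)
    if (length(rows) < 2L) next
    for (a in seq_len(length(rows) - 1L)) {
      for (b in (a + 1L):length(rows)) {
        x <- rows[a]; y <- rows[b]
        total[i] <- total[i] + 1
        if (qcol_of(x, pu[x, i]) == qcol_of(y, pu[y, i])) {
          retained[i] <- retained[i] + 1
        }
      }
    }
  }
  list(per_column = retained / total,
       overall = if (sum(total) > 0) sum(retained) / sum(total) else NaN)
}

# Total column score: reference column reproduced exactly by some single
# comparison column (occurrence labels including gap placement)
oracle_cs <- function(ref_rows, cmp_rows) {
  Pl <- oracle_encode(ref_rows)
  Ql <- oracle_encode(cmp_rows)
  hits <- 0L
  for (i in seq_len(ncol(Pl))) {
    for (j in seq_len(ncol(Ql))) {
      if (all(Pl[, i] == Ql[, j])) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits / ncol(Pl)
}

category_codes_from_labels <- function(cats) {
  matrix(match(cats, c("match", "conserved_gap", "merge", "split", "shift")),
         nrow(cats), ncol(cats))
}
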