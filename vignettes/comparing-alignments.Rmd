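---
title: "Comparing alternative multiple sequence alignments with msadiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing alternative multiple sequence alignments with msadiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msadiff)
```

## The problem

Different alignment programs routinely make different homology predictions
for the same set of sequences, especially in families rich in insertions and
deletions such as cysteine-rich proteins. Since there is no objective
function for the "biological correctness" of a multiple sequence alignment
(MSA), a practical question is instead: *where* and *how* do two alternative
alignments of the same sequences disagree? msadiff quantifies this,
categorises each disagreement, and visualises the result.

The two classical summary statistics — the sum-of-pairs score (SPS) and the
total column score (CS) — compress all agreement information into single
numbers and scale non-linearly with per-column similarity. msadiff computes
them too (`sum_of_pairs()`), but its core is a complementary, column-indexed
method that attributes every disagreement to a mechanism.

## The model

Both alignments are treated as character matrices over residues plus the gap
symbol `-`: the reference $P$ ($n \times p$) and the comparison $Q$
($n \times q$), with rows paired so that row $x$ of both holds the same
ungapped sequence (`validate_pair()` pairs rows by identifier, falling back
to unique sequence content).

**Occurrence encoding.** A residue can recur in a row, so each non-gap cell
is labelled by its symbol plus its occurrence index in that row (`A1`, `C1`,
`A2`, ...). Every non-gap cell is then unique within its row, and aligning
the first `A` of a sequence against its second `A` is correctly scored as a
disagreement. For rows holding identical ungapped sequences this labelling
is equivalent to identifying cells by ungapped position, which is what the
fast similarity computation exploits.

**Column-pair similarity.** For reference column $i$ and comparison column
$j$,
$$S_{ij} = \frac{1}{n}\sum_{x=1}^{n} \varepsilon(P_{xi},\, Q_{xj}),
\qquad
\varepsilon(a,b) = \begin{cases}1 & a = b \ \wedge\ a \neq \text{"-"}\\
0 & \text{otherwise,}\end{cases}$$
so every entry of $S$ is a rational with denominator $n$. Two gaps are *not*
counted as equivalent: $S$ measures shared residue placement only.

**Column matching.** Each reference column $i$ is paired with the comparison
column $j$ maximising $S_{ij}$. The maximiser is not always unique; msadiff
breaks ties by the smallest $|j-i|$, then the smallest $j$, and flags every
tie in the result (`tie_flags`) so they can be audited. An all-zero row of
$S$ (a reference column with no counterpart at all) still receives a match
under the same rule, so that the cell categorisation below is total.

**Cell categorisation.** With $j$ the matched column, each reference cell
falls in exactly one of five categories:

| category | condition | reading |
|---|---|---|
| match | equal non-gap labels | same homology prediction |
| conserved gap | gap in both | agreement on absence |
| merge | gap in $P$, residue in $Q$ | comparison packed residues into fewer columns |
| split | residue in $P$, gap in $Q$ | comparison spread the column out |
| shift | unequal non-gap labels | homology reassignment |

The five categories are exhaustive and mutually exclusive, so the per-column
proportions (the $5 \times p$ results matrix $R$) sum to one in every
column — a conservation law the test suite asserts on every tested input.

**Scores.** The overall similarity score is the proportion of matching
characters among characters that are not conserved gaps. Excluding conserved
gaps stops low-occupancy columns from inflating similarity through shared
absence. A stricter column score reports the fraction of reference columns
reproduced perfectly (all cells match or conserved gap). Both are reported
alongside the classical SPS and CS.

## Design choices

Several aspects of the method are genuinely open; the package fixes them as
follows.

*Merge/split orientation.* The two mechanism labels could be attached to
either alignment's gaps. msadiff defines **merge** as a reference gap facing
a comparison residue and **split** as a reference residue facing a
comparison gap, reading the comparison relative to the reference. Because
conventions differ, `compare_alignments(swap_merge_split = TRUE)` (CLI:
`--swap-merge-split`) exchanges the two labels; no score changes, since the
overall and column scores depend only on matches and conserved gaps.

*Tie-breaking.* Preferring the nearest column index (then the leftmost)
keeps matched columns near the diagonal of $S$, which is where alternative
alignments of the same sequences concentrate, and makes results
deterministic. Ties are rare in informative columns and always flagged.

*Exactness.* $S$ and $R$ entries are rationals with denominator $n$, and the
overall score inside `compare_alignments()` is computed from integer cell
counts, `matches / (cells − conserved gaps)`, rather than by averaging
floating-point column proportions. The two are identical in exact
arithmetic, but the count form guarantees that a self-comparison scores
exactly 1 and lets the tests assert exact rational values. The standalone
`overall_score()` retains the matrix formulation for use on an $R$ matrix
alone.

*Total column score.* `sum_of_pairs()`'s CS asks for a comparison column
identical to the reference column in full — residue instances and gap
placement. An all-gap reference column therefore counts as reproduced only
if the comparison also has an all-gap column. CS is deliberately computed
without the argmax matching, keeping its classical benchmark meaning;
`column_score()` is the matched-column analogue.

*Normalised summaries.* Per-column summaries divide by the proportion of
characters that are not conserved gaps (the same denominator logic as the
overall score). Columns that are entirely conserved gaps have no defined
summary; they are reported as `NA` and drawn as line breaks, never as
zeros.

## The synthetic-data generator

The paper-style use case — a curated reference versus an automatic
aligner — needs alignment pairs with *known* disagreements.
`generate_pair()` builds them: a base alignment (given, or sampled by
`random_alignment()`) plus a list of perturbations, each of which provably
preserves every row's ungapped sequence:

- `split_column` / `merge_columns` — move residues out of a column into a
  new neighbour, or merge two complementary columns;
- `shift_block` — slide a residue block within gap space in selected rows;
- `translocate_rows` — displace whole sequences sideways, emulating the
  block translocation seen when an aligner misplaces an entire subfamily;
- `insert_gap_column` — a null perturbation that changes geometry only.

For a single perturbation the induced column correspondence is known, so
the expected count of every category is derived analytically, cell by cell,
before any comparison machinery runs; `generate_pair()` attaches these
expectations only after verifying (via the similarity matrix) that the
known correspondence strictly wins the column matching — otherwise the pair
is marked unpredicted and tests fall back to oracle comparison. Defaults
emulate a small protein family block: 20-letter alphabet, 30 % gap
occupancy, with an optional all-cysteine scaffold
(`cys_columns`) mimicking the conserved cysteine architecture of
defensin-like families.

What the generator does *not* emulate: realistic residue substitution
structure (columns are i.i.d.), phylogenetic correlation between rows, and
the compound, interacting misalignments real aligners produce. Passing the
fixture-recovery tests therefore demonstrates that the machinery measures
exactly what each mechanism injects — not that any particular aligner
behaves well on real data.

## Numerical and scale notes

The similarity matrix is accumulated from per-row label hits in
$O(n \cdot \text{width})$ rather than the naive $O(n p q)$ triple loop, so a
1000-sequence × 1000-column comparison completes in seconds in pure R; the
test suite asserts the full comparison in well under two minutes. Test
problem sizes are chosen to keep the default suite fast: oracle-equivalence
sweeps use 500 random pairs with $n \le 6$, width $\le 8$ over a 4-letter
alphabet, where exhaustive brute-force enumeration is itself trivially
checkable; the scale check runs once at 1000 × 1000.

## Worked example

```{r worked}
ref <- alignment(c("ACG", "A-G"), ids = c("s1", "s2"))
cmp <- alignment(c("ACG", "AG-"), ids = c("s1", "s2"))
pac <- compare_alignments(ref, cmp)
pac$S
pac$match
category_labels()[pac$D]
pac$overall_score
```

Column 2 of the reference pairs with comparison column 2, where sequence
`s2`'s gap faces the comparison's `G1`: a merge. Column 3 shows the
complementary split. Four of six characters match and there are no
conserved gaps, so the overall score is $4/6$.

## Limitations

- Strictly pairwise: many-way comparisons are out of scope, as is any
  alignment construction or refinement.
- No significance testing: scores are descriptive; their sampling
  behaviour under a null model is not addressed.
- `cysteine_proportion()` counts the literal symbol `C`, which in a
  nucleotide alignment is cytosine — documented, not guarded.
- Figures are faithful views of the matrices; publication cosmetics
  (palettes, orientation) are configurable but not a correctness surface.
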