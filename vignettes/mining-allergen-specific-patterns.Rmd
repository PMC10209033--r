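---
title: "Mining statistically significant allergen-specific patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining statistically significant allergen-specific patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspmine)
```

## The problem

Some proteins trigger IgE-mediated allergic reactions and some do not, and
part of that difference is carried by short contiguous stretches of amino
acids — epitope-like motifs. Given a collection of proteins labeled
allergenic (+1) or nonallergenic (−1) and annotated with a biological
category (wheat, bovine, thymic self-antigen, ...), `aspmine` searches
*exhaustively* over every contiguous substring of every sequence for
patterns that are over-represented in the allergenic class, while

* controlling the family-wise error rate (FWER) over the astronomically
  large family of tests (a 20-letter alphabet admits
  $\sum_{k=1}^{50} 20^k > 10^{65}$ patterns up to length 50; even the
  patterns actually present in a realistic dataset number in the billions),
  and
* guarding against the confounding between biological category and label:
  proteins are not i.i.d. — members of one category share sequence simply
  because they are homologous, so a category-specific substring can
  masquerade as an allergen-specific one.

## Data model

A dataset is a table of `(id, sequence, category, label)` records
(`protein_dataset()`). Categories are classified by `classify_categories()`
into *paired* (both classes present), *positive-only* (allergens only) and
*negative-only* (nonallergens only); the distinction drives the selection
rules below.

## Per-pattern test

For a pattern $q$, let $D[q]$, $D^+[q]$, $D^-[q]$ count the proteins (not
occurrences) of the whole collection, the allergens and the nonallergens
that contain $q$ as a substring, with class sizes $n^+$ and $n^-$.
Conditional on margins, the allergen-side count follows the hypergeometric
law

$$g(n^+, n^-, D[q], a) = \frac{\binom{n^+}{a}\binom{n^-}{D[q]-a}}
  {\binom{n^+ + n^-}{D[q]}},$$

and the two-tailed p-value doubles the mass of the tables no more likely
than the observed one:

$$p(D, q) = \min\Bigl(1,\; 2 \sum_{a \in A(D,q)} g(n^+, n^-, D[q], a)\Bigr),
\qquad A = \{a : g(a) \le g(D^+[q])\}.$$

The doubling can push the sum above one, so the value is capped; capping
never changes a rejection decision at any practically calibrated level.
Cell probabilities are computed in log space (`lchoose`) for robustness at
large $n$; the test suite checks them against an exact-rational
enumeration on all tables with $n \le 40$.

## FWER calibration by label permutation

With billions of correlated tests, Bonferroni ($\delta = \alpha/T$) is
hopeless — at full scale it demands $p < 1.3\times10^{-11}$. `aspmine`
instead calibrates the per-test level by the Westfall–Young permutation
scheme: labels are shuffled globally $M$ times (class sizes preserved,
sequences and categories untouched), the minimum p-value over all patterns
is recorded for each shuffle, and the adjusted level $\delta$ is the
$k$-th smallest of those minima with $k = \lceil \alpha M \rceil$. A
pattern is declared significant when $p < \delta$ *strictly*, which bounds
the estimated FWER by $(k-1)/M < \alpha$. (The default is $M = 10{,}000$
at full scale; the desk-scale analyses in this package's tests use
$M$ between 50 and 200.) `adjusted_pvalue()` reports the empirical
adjusted p-value $\#\{m: \min p_m \le p\}/M$.

## Making the permutation pass feasible: branch and bound

Computing a minimum over *all* patterns for each of $M$ permutations is
infeasible naively. Patterns form a prefix tree — each child appends one
residue on the right, and child occurrence lists are projections of their
parent's, so support can only shrink along a branch. For a node of support
$D[q]$ the label-free bound

$$p_{\mathrm{low}}(q) = \min\bigl\{\,g(n^+, n^-, m^+, m^+),\;
   g(n^+, n^-, m^-, 0)\bigr\},\quad m^\pm = \min(D[q], n^\pm),$$

lower-bounds the p-value of $q$ and every descendant under every labeling
(the hypergeometric pmf is unimodal, so its minimum sits at a boundary
cell, and the boundary cells are nonincreasing in support). During a
single traversal the calibration (`wy_calibrate()`) maintains all $M$
running minima and cuts a subtree when $p_{\mathrm{low}}$ exceeds the
**largest** running minimum: no permutation's minimum can then be improved
inside the subtree.

This threshold is deliberately conservative. Pruning at the $k$-th
smallest running minimum would suffice to reproduce $\delta$ itself, but
entries of the minimum vector above $\delta$ could then be left unrefined;
pruning at the largest minimum keeps the *entire* output bit-identical to
the full enumeration, which is what `wy_calibrate_naive()` — an
independent implementation built on a sparse pattern-by-protein presence
matrix — verifies in the tests. The same bound prunes the final
significant-pattern scan (`find_significant_patterns()`) against the fixed
level $\delta$.

The R and C++ p-value routines intentionally perform the same libm calls
in the same order (including the `1 + 10^{-7}` tie cushion on
$g(a) \le g_{\mathrm{obs}}$ familiar from `fisher.test`), so the
naive-vs-pruned comparison can demand exact equality rather than a
tolerance.

## From significant patterns to ASPs

Significance alone is not specificity. An allergen-specific pattern (ASP)
must additionally

2. be absent from every nonallergenic protein, and
3. not be attributable to a single category, shown by occurring in at
   least one paired category (3a) or in two or more distinct positive-only
   categories (3b).

A paired category contains both classes, so enrichment there cannot be a
category artifact; a pattern confined to one positive-only category is
undecidable and is dropped. The two-tailed test carries no direction, so
condition 1's direction is enforced explicitly as
$D^+[q]/n^+ > D^-[q]/n^-$ (integer cross-multiplication, no floating
division).

Nonallergen-enriched patterns (*non-ASPs*) are retained for prediction
only. They may occur in a few allergens, so the absence condition does not
apply; for their category screen — which the ASP definition leaves
open — this package requires occurrence in at least one paired category
*or* in two or more distinct categories overall. With a single
negative-only category (the typical layout), a pattern confined to it
cannot be distinguished from a category-specific one, which this rule
mirrors from 3a/3b.

All nested significant patterns are reported — no closed-pattern
reduction — because merging is deferred to the concatenation step.

## ConcASPs

ASPs overlap heavily (a significant 8-mer usually drags significant 4- to
7-mers along). `find_concasps()` merges them by *overlapped
concatenation*: within each allergenic protein, all (possibly overlapping)
occurrence intervals of all ASPs are located and intervals that overlap or
abut are unioned; each maximal merged interval names a candidate sequence,
witnessed by that protein. An abstract chain of overlapped concatenations
is unconstrained, but only chains witnessed by an actual allergen sequence
satisfy the containment requirement, and per-protein interval union
enumerates exactly those without combinatorial blowup. Candidates are
deduplicated as sequences (witnesses pooled) and a maximality filter drops
any candidate contained in another. The filter is a length-ordered
pairwise scan in C++ — at the method's realistic scale (thousands of short
candidates) this is sub-second, and it leaves the quadratic pure-R scan
available as an independent oracle in the tests. `exact_inclusion_match()`
performs the plain substring check used to compare mined patterns against
known IgE-epitope peptide lists.

Occurrence coordinates are 0-based and half-open throughout, so abutment
is exactly `start == end` and slices can be compared without off-by-one
adjustments.

## Prediction

Each protein becomes a binary vector of pattern-containment indicators
($x_{ij} = 1$ iff pattern $Q_j \sqsubseteq z_i$) over the mined ASPs and
non-ASPs, and a soft-margin linear SVM

$$\min_{w, b}\ \tfrac12 w^\top w +
  C \sum_i \max\{0,\, 1 - y_i (w^\top x_i + b)\}$$

is fit by libsvm's C-classification (`e1071::svm`, no scaling). The
weight on a pattern is directly interpretable as its contribution to
predicted allergenicity. The margin hinge $1 - y_i f(x_i)$ is the
standard soft-margin loss; a hinge of the form $\max\{0, y_i f(x_i)\}$ is
degenerate (minimized by $w = 0$, $b \to -\infty$) and cannot learn. The
tests cross-check the fitted objective against an interior-point solution
of the dual QP (`kernlab::ipop`).

Because proteins within a category are related, performance is estimated
by *leave-category-out* cross-validation: one fold per paired category,
the whole category held out, and — critically — the ASP/non-ASP mining
repeated from scratch on the remaining data with a fold-derived seed, so
the held-out category can never leak into feature discovery. k-mer
baselines are provided in the same harness: binary indicators over 6-mers
with document frequency at least 15 (a threshold that yields a feature
count comparable to the mined pattern set at full scale), and ratio
features over 1-/2-mers.

$C$ is chosen on the training categories by an inner leave-category-out
loop over the grid $\log_{10} C \in \{-27/9, -23/9, \dots, 9/9\}$,
extended by steps of $4/9$ past a boundary for as long as the extension
strictly improves the score, with ties resolved to the smallest $C$ (the
strict-improvement rule is what makes the extension terminate when the
metric is flat in $C$). The inner loop reuses the feature spec mined on
the outer training set rather than re-mining per inner fold: re-mining
would nest two permutation calibrations for the sole benefit of the
scalar $C$, and the quantity being protected from leakage — held-out
*test* performance — is untouched by this shortcut. AUC-selected $C$ is
reused for AUC-10%.

Metrics follow the printed conventions: predictions at threshold
$\theta = 0$ with `score >= 0` positive give TP/FP/TN/FN, F1 and MCC (MCC
defined as 0 whenever a marginal is zero); AUC is the rank (Mann–Whitney)
statistic with half-credit ties, identical to the area under the ROC
polyline with tied scores traversed diagonally; AUC-10% integrates the
same polyline over FPR $\in [0, 0.1]$ and multiplies by 10, so a perfect
classifier scores 1 and a constant one 0.05. Per-fold and
pooled-concatenated metrics are both reported, since averaging curves and
concatenating scores answer slightly different questions on folds of very
unequal size.

## The synthetic generator

`generate_dataset()` emulates the *structure* of a curated
allergen/nonallergen collection: a category taxonomy with paired,
positive-only and negative-only categories, unbalanced class sizes, and
planted motifs standing in for shared epitopes. Sequences are i.i.d.
residues from a background distribution (uniform over the 20 standard
amino acids by default); each motif overwrites a uniformly chosen,
collision-free window with class- and category-specific probability.
Overwriting rather than inserting keeps the length distribution
independent of the planted signal, so a miner cannot cheat off sequence
length; collision-free placement makes the recorded ground truth exactly
recoverable by re-scanning the output.

The default desk-scale profile is five paired categories of 10+10
proteins, four positive-only categories of 10, one negative-only category
of 20 (so $n = 160$, $n^+ = 90$), lengths uniform in 50–150. The
benchmark settings used by the test suite and the acceptance script —
motif insertion rate 0.8 in allergens and 0 in nonallergens, $M = 100$ to
$200$ permutations, 200 null replicates for the FWER estimate — are the
package's chosen study conditions at this profile.

What the generator does *not* emulate: homologous families within a
category (real categories share long stretches, not just planted motifs),
composition biases, length/label correlation, or ambiguity codes. Passing
on synthetic data therefore demonstrates the statistical machinery —
FWER control, recovery, leakage-free evaluation — not field performance
on curated databases.

## Numerical and degenerate-input conventions

* Hypergeometric cells outside the admissible range return 0; capped
  p-values live in $(0, 1]$.
* Tie handling in the tail set uses the multiplicative $1 + 10^{-7}$
  cushion, mirrored bitwise between the R and compiled routes.
* Order-statistic ties in the permutation minima resolve by position in
  the sorted-with-duplicates vector.
* Patterns with equal support along a chain are still distinct nodes; the
  traversal is depth-first with children in alphabetical residue order,
  so traversal statistics are reproducible.
* Empty candidate sets flow through: empty ASP tables produce empty
  ConcASP sets, zero-feature folds fall back to constant scores (AUC 0.5),
  and empty reports are empty histograms rather than errors.
* A sequence shorter than $k$ under ratio features yields an all-zero row
  with a warning; single-class test sets yield `NA` AUC with a warning.
* `possible_pattern_count()` uses a small arbitrary-precision integer
  accumulator (base-$10^7$ limbs in doubles), since the count exceeds the
  double-precision integer range already at length 50.

## Known limitations

* The miner targets contiguous patterns only; gapped or approximate motifs
  are out of scope.
* Permutations shuffle labels globally. Shuffling within category would
  test a different (conditional) null; the global null matches the
  calibration the selection rules assume.
* `wy_calibrate_naive()` materializes all distinct substrings and is meant
  for datasets of a few kilobases total — it is an oracle, not a tool.
* The interval-union construction of ConcASPs realizes witnessed chains of
  overlapped concatenations; chains never witnessed by a protein are not
  (and should not be) produced.
* At full scale the recursive traversal's depth equals the longest
  within-protein repeat chain; extremely long, highly repetitive sequences
  are better counted via `count_distinct_patterns()` (suffix automaton)
  than enumerated.

## A compact run

```{r example, eval = FALSE}
cfg <- planted_config(seed = 1, n_motifs = 2, p_pos = 0.8)
gen <- generate_dataset(cfg)
d <- gen$dataset

plan <- generate_permutations(d, m_perms = 200, seed = 7)
cal <- wy_calibrate(d, plan, alpha = 0.05)
cal

asps <- select_asps(find_significant_patterns(d, cal$delta, "allergen"),
                    d, calibration = cal)
nrow(asps)
find_concasps(asps, d)$seq

cv <- leave_category_out_cv(d, "asp", m_perms = 100, seed = 11)
cv$mean_auc
```
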