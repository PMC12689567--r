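---
title: "PMC index methods: scoring, reconstruction, sensitivity and consistency checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PMC index methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcindex)
```

## The model and its assumptions

The Policy Modeling Consistency (PMC) index treats a policy text as a vector
of binary content indicators. An indicator schema declares first-level
dimensions (policy objectives, policy entities, intelligent technology
application, medical quality control, control measures, data support,
implementation guarantee, policy audience, policy timeliness in the bundled
system) and, under each, binary second-level criteria: a coder reads the
policy and records 1 if the text explicitly addresses the criterion, else 0.
The dimension score is the unweighted mean of its indicators and the index is
the sum of the dimension scores, so with nine dimensions the index lives on
[0, 9] and is graded Poor / Acceptable / Good / Excellent / Superb / Perfect.

Assumptions worth making explicit:

- **Uniform weights.** Every second-level indicator counts equally. The
  schema format reserves an optional `weight` field, but the default pipeline
  ignores it: weighting schemes (entropy, PCA, expert AHP) change the
  interpretation of the 0–9 range and are out of scope.
- **Binary coding.** The model measures *presence* of content, not quality or
  intensity. Two policies that both "mention data sharing" score identically
  however different their provisions.
- **Text as ground truth.** The index evaluates policy design, not
  implementation outcomes.

## Numerical conventions

Scores are held exactly as integer numerators over the dimension size T
(T = 3 here), and a policy's index is summed in integer arithmetic over the
least common denominator before a single division. This matters at grade
boundaries: a policy with numerators (2,3,3,2,3,2,3,3,3) has index 24/3 = 8
exactly and must grade Perfect, which naive summation of rounded 0.67 cells
would miss. Displayed values round half-up at two decimals; display rounding
never feeds back into computation.

Grade bands are lower-inclusive and upper-exclusive with a closed top band.
This is the only convention consistent with the bundled scorecards, where
8.00 grades Perfect and 5.00 grades Good.

Ranking sorts by exact index descending; ties keep input order (the bundled
score table is stored in published rank order, so the two 8.00 policies
P11 and P6 keep their published ranks 1 and 2). No fractional ranks are
assigned.

## The bundled dataset and marginal reconstruction

The bundled fixture transcribes the evaluation of 22 Chinese national
medical-quality intelligent-management policies (2016–2025): the 22 × 9
first-level score table (exact thirds) and the 27 per-indicator ones-counts
at n = 22. Counts were recovered from published three-decimal means with
`counts_from_means()`, which accepts the nearest integer only when it agrees
with the printed mean to 0.005.

The full 22 × 27 binary matrix is not published. `reconstruct_matrix()`
therefore builds one feasible witness per dimension as a small 0/1
transportation problem: row sums are fixed by 3 × score, column sums by the
indicator counts. Policies are processed in input order; each policy's ones
go first to columns whose remaining demand equals the number of remaining
policies (forced cells), then to the largest remaining demand, ties in schema
order. Both marginals are asserted on every call. Any feasible witness is
equivalent for every index-level quantity — dimension scores, the index, all
averages, coverage, contingency tables — because those depend only on the
marginals; the witness is deterministic so tests are reproducible.

Two caveats are flagged in the data itself. The published indicator-level
summary for the X8 (policy audience) dimension is internally inconsistent
for binary data (means above 1, an impossible p-value), so the X8 row is
excluded from the chi-square reproduction; and only the sum X8-1 + X8-2 = 38
is determined by the score table, so the fixture stores a synthetic 19/19
split, marked `synthetic = TRUE`. X8-3 = 1 is documented coverage (4.55%).
No index-level quantity depends on the split.

## Sensitivity scenarios

Three scenarios per target indicator: baseline (unchanged), partial
(coverage rate raised by a relative 30%), and full (coverage 100%). Because
the corpus-average index equals (total ones)/(3n), scenario averages follow
in closed form: full optimization of an indicator with count c adds
(n − c)/(3n).

"Raise coverage by 30%" is interpreted as a relative increase of the count,
c → 1.3c. A fractional target count cannot be realised by whole policies, so
partial mode is pluggable: `expected_value` (default) keeps the fractional
count for analytic averaging; `round_down` / `round_up` flip whole policies
deterministically; `stochastic` flips a seeded random subset whose expected
size matches the expected-value rule. The default reproduces the published
partial value for X6-1 (417.4/66 → 6.32). The published partial value for
X8-3 (6.30) is not reproducible under any single rule that also yields 6.32
for X6-1 (1.3 × 1 = 1.3 extra ones gives 415.3/66 → 6.29); partial values
are therefore documented as rule-dependent and only the expected-value rule
is asserted.

Grade-change flags compare the bands of the displayed two-decimal values,
matching how published sensitivity tables operate.

Sensitive indicators are selected by the published logic: the k
lowest-average dimensions, and within each, its minimum-coverage
indicator(s), coverage ties all kept (which is how X6 contributes both X6-1
and X6-2 at 8/22).

## Within-dimension consistency checks

For each dimension the three indicators form a 3 × 2 contingency table of
(ones, zeros) counts; the Pearson chi-square statistic Σ(O−E)²/E with
margin-derived expectations and **no continuity correction** on df = 2 tests
homogeneity of coverage inside the dimension. This construction reproduces
all eight well-formed published statistics exactly (16.995, 34.815, 8.238,
3.771, 16.950, 4.4, 6.6, 15.661), which is how it was fixed; it is
documented as derived rather than prescribed. The test itself is delegated
to `stats::chisq.test(correct = FALSE)`; an independent first-principles
oracle checks it in the test suite over exhaustively enumerated small
tables. Degenerate tables (a zero column margin, e.g. a fully saturated
dimension) take a defined-zero path with a warning; expected counts below 5
warn but do not block, since small policy corpora routinely violate the rule
of thumb. Within-SDs are the n−1 sample standard deviation of a binary
column, sqrt(n·p(1−p)/(n−1)).

## PMC surface and radar

The nine dimension scores arrange row-major into the 3 × 3 PMC surface. For
the smooth rendering the package uses tensor-product monotone Hermite
interpolation (rows then columns): it reproduces the control values exactly
at the nodes and can never overshoot the range of the 3 × 3 grid, which is
all that matters for the qualitative convex/concave reading. Whether the
original surfaces interpolate or tile is not documented anywhere, so a
nearest-neighbour `tile` mode is exposed alongside. The radar view reports
dimension averages and flags those below a configurable threshold
(default 0.6, the conventional cut between adequately covered dimensions
and improvement targets).

## Text mining

The front end counts, it does not model: tokenization with a pluggable
segmenter (the default splits on non-letter characters and protects
multi-word lexicon terms; a Chinese dictionary-based segmenter can be
registered under a new plugin id with `register_tokenizer()`), stop-word
removal over the union of word lists (case-folded by default), ranked term
frequencies with deterministic lexicographic tie-breaks, and document-level
(or sliding-window) co-occurrence networks. Tokens containing digits are
dropped wholesale: numbers carry no policy semantics here, and stripping
digits from mixed tokens would invent words. Whether frequencies count raw
tokens or per-document occurrences is exposed as `count_mode`, since
published high-frequency tables rarely say which they used.

## Synthetic data: what it emulates and what it does not

`generate_coding_matrix()` emulates the binary coding structure — per-
indicator coverage probabilities, independent across cells — in two modes:
`quota` places exactly round(p·n) ones per column for exact parameter
recovery, `stochastic` draws Bernoulli cells for distributional realism.
`generate_corpus()` builds token corpora whose post-filter term frequencies
and document co-occurrences equal a planted ledger *by construction*: each
planted pair gets dedicated two-term documents and leftover term mass goes
to per-term documents, so no unplanned co-occurrence can arise; the seed
only shuffles orderings, which the pipeline must be invariant to.

Neither generator models what real policy corpora have: correlated
indicators (policies that cover data sharing tend to cover data platforms),
corpus-wide drift over time, or natural-language structure. Passing tests on
synthetic data therefore demonstrate that the bookkeeping is exact and the
pipeline deterministic — not that the indicator system is valid for any
particular policy domain, which remains an expert judgement.

Problem sizes used in the test suite are deliberately small: the bundled 22
× 27 corpus, exhaustive 3 × 2 tables up to n = 6, and stochastic coverage
checks at n = 500 over 100 seeds, which keeps the whole suite in the
ten-second range while still exercising every code path.

## Known limitations

- The X8-1/X8-2 coverage split in the bundled data is synthetic (see above).
- Partial-optimization scenario values depend on the allocation rule; only
  the expected-value rule is pinned by data.
- The chi-square contingency construction is reverse-engineered from
  published statistics, not prescribed by a methods section.
- The index inherits the limits of binary uniform-weight coding: it cannot
  distinguish depth of treatment, and dimension scores built from three
  indicators are coarse (multiples of 1/3).
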