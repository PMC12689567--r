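# pmcindex

Quantitative evaluation of policy-text corpora with the Policy Modeling
Consistency (PMC) index, for policy analysts who need a reproducible,
text-based measure of how complete and internally consistent a set of policy
documents is before (or independent of) implementation data.

## The model

A hierarchical indicator system assigns each policy a set of first-level
dimensions X_1, ..., X_m (policy objectives, policy entities, data support,
...), each decomposed into binary second-level indicators X_ij ∈ {0, 1}: 1 if
the policy text explicitly addresses the criterion, 0 otherwise. With uniform
indicator weights, the dimension score is the mean of its indicators,

    X_i = ( Σ_j X_ij ) / T(X_i),

and the PMC index of a policy is the sum of its dimension scores,

    PMC = Σ_i X_i ∈ [0, m].

For the bundled system (m = 9 dimensions, T = 3 indicators each) the index
ranges over [0, 9] and is graded into six consistency bands: Poor [0, 4),
Acceptable [4, 5), Good [5, 6), Excellent [6, 7), Superb [7, 8), Perfect
[8, 9]. All arithmetic is exact (integer numerators over T); two-decimal
rounding is display-only, which is what makes sums of 0.33/0.67 cells come
out as the scorecards print them.

Around that core the package provides:

- binary coding-matrix I/O, coverage accounting, and reconstruction of a
  feasible coding matrix from published marginals (row sums from first-level
  scores, column sums from per-indicator counts);
- the 3×3 PMC surface and radar exports for per-policy and corpus profiles;
- scenario-based sensitivity analysis (baseline / +30% coverage / full
  coverage of a target indicator) on the corpus-average index;
- within-dimension Pearson chi-square consistency checks, per-indicator
  means and n−1 within-SDs;
- a text-mining front end (pluggable tokenizer, stop-word filtering, ranked
  term frequencies, co-occurrence networks, word-cloud export);
- synthetic generators for coding matrices and token corpora with exactly
  recoverable ground truth;
- a bundled evaluation dataset of 22 Chinese national medical-quality
  intelligent-management policies (2016–2025).

## Worked example

```r
library(pmcindex)

fx <- mqimp_fixture()                       # bundled 22-policy evaluation data
ev <- evaluate_from_first_level(fx$scores)  # score, grade and rank the corpus
ev
#> PMC evaluation of 22 policies
#> Average PMC index: 6.29 (Excellent)
#> Grade histogram:
#>       grade n_policies
#>        Poor          0
#>  Acceptable          4
#>        Good          2
#>   Excellent          8
#>      Superb          6
#>     Perfect          2
#> Top of ranking:
#>  policy_id pmc_display   grade rank
#>        P11        8.00 Perfect    1
#>         P6        8.00 Perfect    2
#>         P2        7.33  Superb    3
#>         P4        7.33  Superb    4
#>         P9        7.33  Superb    5
```

The corpus averages 6.29 on the 0–9 index — "Excellent" overall — with two
Perfect and no Poor policies. `tidy(ev)` returns the full scorecard table,
`radar_data(ev)` flags the weak dimensions (X4 medical quality control 0.53,
X6 data support 0.45, X8 policy audience 0.59, all below the 0.6 threshold),
and `average_surface(ev)` arranges the nine averages into the PMC surface.

Sensitivity of the corpus average to the weakest indicators:

```r
run_sensitivity(fx$counts, c("X4-2", "X6-1", "X6-2", "X8-3"))
#>   target baseline partial full baseline_grade full_grade grade_changed
#> 1   X4-2     6.29    6.32 6.50      Excellent  Excellent         FALSE
#> 2   X6-1     6.29    6.32 6.50      Excellent  Excellent         FALSE
#> 3   X6-2     6.29    6.32 6.50      Excellent  Excellent         FALSE
#> 4   X8-3     6.29    6.29 6.61      Excellent  Excellent         FALSE
```

Even driving any single weak indicator to 100% coverage leaves the corpus
grade unchanged, so the "Excellent" conclusion is stable against
single-indicator coding perturbations. `dimension_chisq(fx$counts)` adds the
within-dimension chi-square consistency checks (e.g. X6: statistic 4.4,
p = 0.11, i.e. uniformly weak indicators rather than one outlier).

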