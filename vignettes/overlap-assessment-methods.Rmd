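---
title: "Assessing primary-study overlap under explicit matrix-construction assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing primary-study overlap under explicit matrix-construction assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapCCA)
```

## The statistic and its inputs

An overview of systematic reviews (SRs) synthesises reviews, not primary
studies, so the same primary study frequently sits inside several included
SRs. The corrected covered area (CCA) summarises that redundancy from an
evidence matrix — rows are primary studies (or, more precisely, the
references reporting them), columns are SRs, and a cell is filled when the
review includes the reference. With $N$ the number of filled cells, $r$
the row count, $c$ the column count and $SZ$ the number of structural
zeros,

$$\mathrm{CCA} = 100\cdot\frac{N - r}{rc - r - SZ}.$$

The numerator counts duplicate study entries ($N - r$, since the first
occurrence of each row is not a duplicate); the denominator counts the
opportunities for duplication. A *structural zero* is a cell that could
not have been filled under any circumstances: the study was published
after the review's search date. Removing such cells from the denominator
(the missingness adjustment) can only increase the CCA, because the
numerator is untouched — this monotonicity is asserted property-style in
the test suite and end-to-end on generated data.

The pairwise CCA restricts the matrix to one pair of reviews, drops rows
with no inclusion in either, and applies the same formula with $c = 2$.
On an unadjusted matrix this is algebraically the Jaccard index of the two
study sets, $100\cdot|A\cap B|/|A\cup B|$, which is what the test suite
uses as an independent set-based oracle.

## The sixteen construction scenarios

The matrix itself embodies four assumptions, each exposed as an explicit
operation:

1. **Level of analysis.** `buildMatrix(ds)` uses every review;
   `buildMatrix(ds, level = "outcome", outcome = o)` keeps only reviews
   reporting outcome `o` and references contributing data to it.
2. **Scope.** `adjustScope()` keeps only reviews relevant to the
   overview's main outcome (the `covers_main_outcome` flag) and deletes
   rows whose references contribute to no overview outcome.
3. **Publication threads.** `collapseThreads()` merges references sharing
   a `study_id` into one study-level row; a study is included by a review
   as soon as any member report is, and a collapsed cell is structurally
   missing only if every member cell was.
4. **Structural missingness.** `markStructuralMissingness()` turns
   unreachable absences into structural zeros.

`enumerateScenarios()` crosses the two levels with the three binary
adjustments into the canonical list of 16 scenarios: 1–8 overview-level,
9–16 outcome-level, each block ordered none, scope, threads, missingness,
scope+threads, scope+missingness, threads+missingness, all three. The
one- and three-adjustment scenarios are anchored by convention (scenario
1 unadjusted, 2 scope, 3 threads, 4 missingness, 8 all); the order of the
two-adjustment scenarios (5–7, 13–15) is this package's documented
canonical choice, recorded in every output's metadata header so results
remain interpretable against any other ordering.

`applyScenario()` composes the flagged adjustments in the fixed order
scope → threads → missingness. No order is mandated by the definitions,
but this one guarantees that structural zeros are counted on the rows and
columns actually analysed — a denominator correction should refer to the
matrix it corrects. Scope before threads is immaterial in practice: the
two operations commute whenever thread members share outcome labels
(asserted as a property test on generated data, where threads inherit the
study's outcomes).

## Conventions at the edges

Several small decisions matter for reproducibility and are therefore
fixed and documented rather than left implicit:

* **Dates.** Inputs accept full ISO-8601 dates or bare years. A bare year
  is anchored conservatively: `Y` becomes `Y-12-31` for review search
  dates and `Y-01-01` for reference publication dates, which minimises
  false structural zeros when only year precision is available. The
  reachability comparison is strict: a cell is structurally missing only
  when the publication date is strictly later than the search date, so
  same-day (and same-year, after canonicalisation) pairs count as
  reachable. For study-level rows, the thread's earliest member date is
  used.
* **Included but unreachable.** An included cell whose publication
  postdates the search is logically impossible but occasionally appears
  in hand-transcribed data; it is left included and flagged with a
  data-quality warning, never silently rewritten.
* **Interpretation bands.** The conventional CCA bands are ambiguous at
  exactly 5, 10 and 15. `classifyOverlap()` fixes `[0,5)` slight,
  `[5,10)` moderate, `[10,15]` high, `(15,100]` very high — honouring the
  strict inequalities printed at the outer bands and closing the high
  band at both ends. `classifyChange()` labels the across-scenario change
  `[0,5]` minimal, `(5,10)` moderate, `[10,∞)` marked.
* **Undefined values.** A CCA that cannot be computed — fewer than two
  reviews, an empty matrix, or a denominator consumed by structural zeros
  — is `NA` with a reason, and undefined pairwise values are excluded
  from medians and quartiles but counted in `n_undefined`. Treating them
  as 0 is deliberately refused: "no comparable evidence" is not "no
  overlap". Likewise a scenario that fails to construct is recorded as
  `NA` with its error message; it never aborts the sweep, and undefined
  scenarios are excluded from impact ranges.
* **Quartiles.** Pairwise summaries use the linear-interpolation quantile
  convention (R's default, type 7), stated so boxplots are reproducible.
* **Outcome labels** are free strings compared case-insensitively after
  whitespace trimming. Identifiers are opaque; publication threads must
  be declared via `study_id`, and no citation parsing is attempted.
* **Scope at outcome level** still drops non-relevant columns (following
  the definition of the adjustment); on outcome-level matrices this is
  usually near-vacuous because the column filter by outcome has already
  done most of the work — the sweep shows scenarios 9 and 10 coinciding
  whenever all outcome-reporting reviews also cover the main outcome.
* **Pairwise structural zeros.** Under missingness adjustment, each
  pair's $SZ$ is counted within that pair's retained sub-matrix (the
  denominator then refers to the cells actually compared);
  `pairwiseCCA(..., globalSZ = TRUE)` exposes the alternative of reusing
  the whole-matrix count.

## The synthetic-overview generator

`generateOverview()` exists so that every pipeline stage and invariant is
testable without external data. It emulates the structures that drive the
four assumptions:

* review search dates spread uniformly over 2016–2020;
* study publication dates with a `lateFraction` share falling after the
  earliest search date (the source of structural zeros; default 0.1);
* per-study inclusion propensities drawn from a Beta distribution with
  mean `inclusionProb` (default 0.15) and concentration
  `popularityConcentration` (default 10) — low concentration reproduces
  the "few heavily co-cited studies" regime, `Inf` the homogeneous
  regime used for closed-form checks;
* publication threads of $1 + \mathrm{Poisson}(\texttt{threadMeanExtraRefs})$
  references (default mean 0.2 extra reports, appearing up to a year
  after the study), all members sharing the study's outcome labels;
* outcome labels `O1…On` assigned with the configured probabilities,
  `O1` being the main outcome and guaranteed non-empty on both axes.

The defaults describe a typical intervention overview: 15 reviews (the
median among published overviews) and 80 candidate studies, yielding
roughly a dozen included studies per review. A review can only include a
study already published at its search date, and cites one or more of the
thread's reachable reports. Draws use per-phase sub-streams of a single
seed, so the output is bit-reproducible and the caller's RNG state is
untouched.

Two closed-form anchors tie the generator to theory. With homogeneous
propensity $p$, two reviews, no threads and no late studies, the pairwise
CCA of a generated dataset converges to

$$100\cdot\frac{p}{2-p},$$

the conditional both-inclusion probability given membership in the union
(`expectedPairwiseCCA()`); the test suite verifies recovery within
three Monte-Carlo standard errors at 5,000 studies and 20 replicates for
$p \in \{0.2, 0.5, 0.8\}$. Degenerate configurations hit the exact
extremes (propensity 1 → CCA 100%; partitioned studies → CCA 0%).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real overviews: correlated review scopes (real SRs
share eligibility criteria, so inclusion is far from independent),
citation errors and ambiguous thread membership (threads are declared
perfectly here), non-uniform search-date clustering, and outcome labels
that are reported but contribute no data. Real transcribed matrices enter
through `readOverviewDataset()` / `readEvidenceMatrix()` and flow through
the identical code path.

## Problem sizes and determinism

The bundled checks run at deliberately modest sizes chosen to exercise
every code path: property tests on hundreds of random matrices of up to
30 rows × 8 reviews, sweeps on generated overviews of 6–8 reviews and
40–60 studies, and the Monte-Carlo recovery at 2 reviews × 5,000 studies
× 20 replicates. All stochastic tests fix their seeds, and the sweep
itself is purely deterministic in its input, which is asserted by
bit-comparing repeated runs.

## Known limitations

* The package quantifies overlap; it does not prescribe what to do about
  it (review selection, primary-study deduplication before pooling, or
  bias adjustment are out of scope), and the interpretation bands it
  reports are conventional, not validated benchmarks.
* Structural-missingness decisions are only as good as the dates: with
  year-only precision the conservative canonicalisation can miss genuine
  structural zeros within the boundary year.
* Thread handling relies on user-declared `study_id`; no automatic
  companion-report detection is attempted.
* Multi-outcome sweeps are run one outcome at a time (the outcome-level
  scenarios default to the main outcome); results are never pooled across
  outcomes.
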