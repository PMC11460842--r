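# rapidscore

Rubric-based rapid scoring and prioritization of investigational
therapeutics.

When hundreds of candidate therapeutics emerge faster than they can be
reviewed in depth, assessment teams need a triage instrument: a quick,
systematic preliminary score that decides *which* therapeutics deserve a
thorough review first. `rapidscore` implements such an instrument as a
reusable engine, for public-health assessment teams, HTA analysts and
anyone running a structured portfolio triage:

* **Rubric model** — an editable YAML rubric of criteria, each holding
  mutually exclusive *characteristics* with integer scores on a universal
  −10..+10 scale; *characteristics of exclusion* carry a −100 sentinel.
* **Scoring and ranking** — for a therapeutic *t* with one selected
  characteristic per criterion *c*, the overall benefit score is additive,

  *B(t) = Σ<sub>c</sub> s(c, t)*,

  and the portfolio is ranked by *B* with excluded therapeutics strictly
  last. Adjacent pairs get verbal interval statements ("clearly greater",
  "greater", "very similar") from configurable score-gap thresholds, and a
  Kendall-tau sensitivity analysis measures rank stability under score
  jitter.
* **Dual-rater workflow** — two independent entries per therapeutic,
  per-criterion discrepancy detection, third-member adjudication, the
  10-consecutive-clean-entries stability criterion, and six-month review
  scheduling with month-end clamping.
* **Validation and reliability** — three-member Likert panel consensus
  (2-of-3 at "agree" or better, ≥ 75 % of interval statements), raw
  percent agreement and Cohen's kappa.
* **Synthetic fixtures** — seeded generators for portfolios and noisy
  raters so the whole workflow is testable with no external data.

The scale directly encodes importance in the scores themselves — there are
no criterion weights — which is what distinguishes this design from
weighted MCDA tools such as SOJA.

## Worked example

```r
library(rapidscore)

r <- default_rubric()                 # 8 criteria; safety scores 2, 1, 0, -2, -3
a <- simulate_portfolio(r, n_therapeutics = 6, seed = 42, exclusion_prob = 0.2)
rk <- rank_portfolio(a, r)
rk
#> <rst_ranking: 6 therapeutics (3 excluded), rubric v1.0-default>
#> # A tibble: 6 x 4
#>    rank therapeutic_id overall_benefit excluded
#>   <int> <chr>                    <int> <lgl>
#> 1     1 T001                        12 FALSE
#> 2     2 T003                        10 FALSE
#> 3     3 T006                         8 FALSE
#> 4     4 T004                       -94 TRUE
#> 5     5 T002                       -98 TRUE
#> 6     6 T005                       -98 TRUE
```

T001 leads with an overall benefit of 12 (the sum of its eight selected
characteristic scores); the three therapeutics that drew a characteristic
of exclusion carry the −100 sentinel in their totals and are pinned to the
bottom regardless of their other scores. The attached interval statements
verbalize adjacent gaps — `T001` is "greater" than `T003` (Δ = 2), while
`T002` and `T005` are "very similar" (Δ = 0):

```r
rk$interval_statements
#> # A tibble: 5 x 4
#>   id_a  id_b  delta category
#> 1 T001  T003      2 greater
#> 2 T003  T006      2 greater
#> 3 T006  T004    102 clearly_greater
#> 4 T004  T002      4 greater
#> 5 T002  T005      0 very_similar
```

A validation panel is evaluated the same way a review meeting would read
it — one ordinal-ranking item plus interval statements, passing when the
ordinal item reaches 2-of-3 consensus and at least 75 % of statements do:

```r
glance(evaluate_panel(stage_three_fixture()))
#> # A tibble: 1 x 7
#>   ordinal_consensus statements_with_consensus statement_total statement_pct ...
#> 1 TRUE                                     10              12          83.3
```

`tidy()`, `glance()` and `autoplot()` methods cover rankings, validations,
stability analyses and rubrics; `plot_rubric()` shows a rubric's score
spread.

## Command line

A thin CLI over the same functions ships at `inst/cli/rst.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "rst.R", package = "rapidscore"))')" \
  rank --rubric inst/extdata/default_rubric.yaml --input portfolio.csv --out ranking.csv
```

Subcommands: `validate-rubric`, `score`, `rank`, `discrepancies`,
`adjudicate`, `schedule`, `panel-validate` (exits non-zero on a failed
validation, so it gates pipelines), `reliability`, `simulate`,
`stability`.

## A note on the default rubric

Only the safety criterion's characteristic set (scores 2, 1, 0, −2, −3) is
canonical. The other seven criteria's characteristics, and the three
exclusion placeholders, were authored for this package as editable
defaults within the typical −5..+5 band; edit
`inst/extdata/default_rubric.yaml` (or your own copy) to match your
programme's wording.
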