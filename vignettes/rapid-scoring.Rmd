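---
title: "Rapid scoring of therapeutic portfolios: model, workflow and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid scoring of therapeutic portfolios: model, workflow and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidscore)
```

## The decision problem and the model

A triage instrument for a fast-moving therapeutic landscape has to be
quick (minutes per candidate), transparent, and robust to incomplete
information. `rapidscore` implements an additive multi-criteria scoring
model. A **rubric** holds an ordered set of criteria; each criterion holds
mutually exclusive **characteristics**, each carrying an integer score on
a universal scale. An assessment selects exactly one characteristic per
criterion, and the therapeutic's **overall benefit** is the plain sum of
the selected scores:

$$B(t) = \sum_{c \in \text{criteria}} s_{c}(t).$$

Three modelling assumptions follow from this form:

* **Additivity / mutual independence.** Criteria contribute independently;
  there are no interaction terms. Rubric validation enforces the
  structural surrogate (distinct criterion ids, no duplicate
  characteristics) but cannot verify semantic independence — that is a
  rubric-authoring responsibility.
* **Importance lives in the scores, not in weights.** A characteristic
  that matters more simply carries a larger magnitude on the −10..+10
  scale. This replaces the criterion weights of weighted-sum MCDA tools
  and keeps the arithmetic auditable by inspection.
* **Incomplete information is first-class.** "Unknown" characteristics
  (typically scored 0) let a candidate be scored the day it appears and
  re-scored as evidence accrues.

### The scale and the exclusion sentinel

The universal scale runs from −10 to +10, with most characteristics
expected in the typical −5..+5 band; larger magnitudes are reserved for
genuinely decisive findings. **Characteristics of exclusion** (e.g.,
development discontinued) are scored at a −100 sentinel instead. The
sentinel serves score fidelity — the total visibly records *why* a
candidate collapsed — but it does not by itself guarantee bottom
placement: a candidate at −100 + 35 outranks an extreme non-excluded
candidate at −80. Ranking therefore sorts on the key

`(excluded ascending, overall_benefit descending, therapeutic_id ascending)`,

making the exclusion flag dominant and the id a deterministic tie-break.
Under the default rubric the flag is also numerically redundant: with all
non-exclusion scores in −5..+5 and eight criteria, the best excluded total
is below the worst non-excluded total, and the test suite verifies this.
Multiple exclusion selections each contribute −100; we read the sentinel
as a per-characteristic score, the simplest consistent interpretation.

### Interval statements

Review panels talk about rankings in verbal gap categories. With
thresholds `t_similar < t_clear` (defaults 1 and 5), a score gap
`|Δ| ≤ t_similar` is *very similar*, `|Δ| ≥ t_clear` is *clearly greater*,
and anything between is *greater*. The source instrument names only the
verbal categories, so the cutpoints are configurable parameters, chosen
here so that a one-point gap (one characteristic one step apart) is noise
and a five-point gap (the full typical half-band) is decisive.

## The dual-rater workflow

Each therapeutic is entered independently by two raters;
`detect_discrepancies()` reports exactly the criteria where their
selections differ, and `adjudicate()` builds the final assessment from
the agreed selections plus one decision per discrepant criterion. The
decision may match either rater or be a new third-party consensus — the
discussion is allowed to produce a selection neither rater made. The
instrument is treated as stable once a trailing run of entries (default
10, configurable) shows no discrepancies: `stability_streak()` reads
"consecutive" as a trailing run in entry order that any discrepancy
resets to zero. Reassessment is due whenever new information arises or
six calendar months elapse, whichever is first; month arithmetic clamps
to month end (Aug 31 + 6 months → Feb 28) via `lubridate`, a deterministic
and documented convention.

One open point we had to decide: whether a criterion may be skipped
entirely. We require a selection for every criterion — rubrics should
carry an explicit "Unknown" characteristic (scored 0) instead, which
keeps totals comparable across therapeutics.

## Panel validation and reliability

A three-member panel answers one ordinal-ranking item and a set of
interval statements on a 5-point Likert scale. We encode "agree or
strongly agree" as values ≥ 4; the source procedure pools the two, so the
pass rule never distinguishes them. An item reaches **consensus** when at
least 2 of 3 responses are ≥ 4. The ranking is validated when the ordinal
item reaches consensus *and* the fraction of statements with consensus is
at least the threshold (default 75 %). The rule compares the exact
fraction — 10/12 passes because 10/12 ≥ 0.75 — while the displayed
percentage is rounded to the nearest integer (83). Comparing the rounded
display value instead would create artifacts exactly at the boundary.

Reliability is reported two ways: raw percent agreement over all
(therapeutic × criterion) selection items — the same arithmetic serves
inter-rater and intra-rater modes — and Cohen's kappa per criterion as the
chance-corrected companion, computed from
$\kappa = (p_o - p_e)/(1 - p_e)$ with `NA` returned when expected
agreement is 1 (kappa is undefined if both raters use a single identical
label throughout). Tests cross-check kappa against an independent
implementation (`e1071::classAgreement`).

## Rank-stability sensitivity

`rank_stability()` anticipates formal sensitivity analysis: each
replicate jitters every non-exclusion score contribution by an integer
drawn uniformly from ±`perturbation`, clips to the scale, re-ranks, and
records Kendall's tau against the unperturbed order. Exclusion sentinels
are never jittered — an exclusion is a categorical judgment, not a noisy
measurement. Tau is computed with `stats::cor(method = "kendall")`; since
rank vectors are permutations, ties play no role. Zero perturbation gives
tau = 1 up to floating point, and a gap larger than twice the maximum
total jitter cannot reverse a pair.

## The synthetic-data generator

The real portfolio behind the instrument's pilot is unpublished, so the
generator emulates *structural* properties only: uniform characteristic
selection per criterion, a per-therapeutic exclusion probability, and a
per-selection rater disagreement probability. Defaults are fixed at the
pilot's conditions: 69 therapeutics per portfolio, three panel raters, 12
interval statements; where the pilot reports no rate we chose once —
`disagreement_prob = 0.05` (trained raters who reached ten consecutive
clean entries after roughly thirty therapeutics must disagree rarely) and
`exclusion_prob = 0.1` (exclusions are meant to be exceptional). What the
generator does **not** emulate: correlation between criteria (real
evidence quality and clinical impact co-vary), evidence accrual over
time, score drift as rubrics are revised, and any clinical content. A
passing test suite therefore demonstrates the *mechanics* — scoring,
ranking, reconciliation, consensus arithmetic — not that the default
rubric would rank any real portfolio appropriately; that judgment
requires the human validation stage the workflow encodes.

All generators are pure functions of (configuration, rubric, seed): the
same inputs give byte-identical output, and the RNG state of the caller
is restored afterwards. Test problem sizes were chosen desk-scale: the
ranking oracle enumerates all 18 assessments of a 3-criterion rubric
exactly; agreement-recovery checks use 1,000 items (125 therapeutics × 8
criteria), where three binomial standard errors give a ±4 % band at
d = 0.25; stability summaries use 69-therapeutic portfolios and a few
hundred replicates.

## Degenerate inputs and numerical conventions

* Empty portfolios rank to an empty ranking; empty dual-entry histories
  have streak 0; agreement on an empty item set is an error, not `NaN`.
* All scores are integers — every published score is an integer, and
  integer arithmetic keeps equality tests exact.
* Rubric violations are returned as data (a tibble, one row per
  violation), never raised one at a time, so a file's problems are
  reported all at once; constructors and `read_rubric()` abort with the
  full list.
* CSV artifacts are UTF-8 with a header row; dates are ISO-8601. The
  rubric file is YAML, chosen as a human-reviewable stand-in for the
  original spreadsheet rubric.

## Limitations

The default rubric is only partially canonical: the safety criterion's
five characteristics (2, 1, 0, −2, −3) are the published set, while the
other seven criteria's characteristics and the three exclusion
placeholders were authored here from the published list of elements
considered, and should be replaced with a programme's own wording before
operational use. Interval-statement thresholds, the Likert agreement
cutoff, the consensus rule and the streak length are configurable
precisely because the sources leave them verbal; the defaults are
reasoned, not validated. And the additive model inherits MCDA's classic
caveat: a different group of score-setters would produce different
rankings — the dual-entry and panel stages exist to surface exactly that.
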