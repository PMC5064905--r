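---
title: "Weighted-checklist scoring of health facility quality: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-checklist scoring of health facility quality: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etiqh)
```

## The instrument model

The e-TIQH (electronic Tool to Improve Quality of Healthcare) methodology
assesses primary healthcare facilities along six quality dimensions, each
covered by one *sub-tool*: (1) physical environment and equipment, (2) job
expectations, (3) professional knowledge, skills and ethics, (4) management
and administration, (5) staff motivation, and (6) client satisfaction.
Sub-tools are administered as checklists, structured interviews or direct
clinical observation, and contain one or more *quality standards* — the
qualitative statements of what good care looks like — each operationalised
by *verification criteria*: binary indicators answerable "yes" (wire code
1), "no" (0) or "not applicable" (99). Every criterion carries an integer
importance weight $w_c \in \{1,\dots,5\}$, 1 marking a less important
criterion and 5 one essential for good quality care.

Sub-tool 3 additionally distinguishes four clinical-observation scenarios —
under-5 IMCI case management, pregnant women, fever patients over 5 years,
and TB/HIV suspects — via scenario tags on its criteria. Only criteria of
scenarios actually observed during a visit count towards the score.

`etiqh` represents this hierarchy as an `etiqh_instrument` object,
serialised to a versioned YAML schema (`read_instrument()`,
`write_instrument()`). Two instruments ship with the package:

* `demo_instrument()` — small, hand-traceable; its standard 3.1 carries the
  canonical weights (3, 3, 4, 4, 4, 4, 4), 26 points in all, used in the
  worked examples below;
* `reference_instrument()` — a full-scale synthetic fixture whose
  per-dimension maximum points are exactly (117, 34, 477, 217, 66, 24),
  summing to 935, with placeholder criterion texts.

Two accounting choices in the reference fixture were genuinely open and are
deliberate. First, the canonical accounting quotes 33 indicators alongside
217 points for sub-tool 4, which cannot both hold under 1–5 weights
(33 × 5 = 165 < 217); since the six point totals are mutually consistent
with the 935-point grand total, the fixture keeps the points and uses a
documented 50-criterion profile (17 criteria of weight 5, 33 of weight 4).
Second, nothing fixes how sub-tool 3's 477 points distribute over the four
scenarios; the fixture assigns 115/116/116/104 points beyond the 26 points
of the untagged standard 3.1 and documents that split as its own.

## The two-step score calculation

Scoring a facility visit proceeds in two steps.

**Step 1 — criterion proportions.** For each criterion $c$, the answers of
all respondents (providers or patients interviewed, or repeated direct
observations) are averaged:
$$p_c = \frac{\#\text{yes}}{\#\text{yes} + \#\text{no}},$$
with NA answers excluded from numerator and denominator alike. A criterion
whose answers are all NA — or that was never answered, or whose scenario
was not observed — is *undefined*.

**Step 2 — weighted aggregation.** The sub-tool percentage is the
weight-normalised sum over the defined criteria $D$:
$$\text{score} = 100 \cdot \frac{\sum_{c \in D} w_c\,p_c}{\sum_{c \in D} w_c}.$$

The overall facility score is the unweighted arithmetic mean of the defined
sub-tool percentages. Scenario ("disease-specific") scores apply the same
formula restricted to the criteria carrying one scenario tag.

The NA rule deserves emphasis: an undefined criterion *contracts the
denominator* rather than scoring zero. This matches the instrument's
semantics — "not applicable" marks services or equipment a facility is not
expected to have — and is visible in the accounting convention that
sub-tool 3's maximum points shrink when fewer than four scenarios are
observed. Consequences tested as invariants: flipping any single no→yes
never lowers a score; rescaling all weights by a positive constant changes
nothing; all-NA criteria reduce the achievable points by exactly their
weight.

A missing row is *not* an NA: NA is an explicit answer, while an absent one
indicates a data-capture gap. Scoring excludes both identically, but
`validate_session()` flags missing answers (`MISSING_ANSWER`), emulating
the bounce-back behaviour of the original data-entry front end, along with
`RESPONDENT_COUNT` (fewer respondents than the rule requires) and
`SCENARIO_GAP` (answers recorded for a scenario not marked observed). That
issue taxonomy is this package's own; the original device's internal
consistency checks are not documented beyond the bounce-back.

```{r worked-example}
inst <- demo_instrument()
crit <- criteria_table(inst)
s31 <- crit$criterion_id[crit$standard_id == "3.1"]
ans <- setNames(rep("no", 7), s31)
ans[c("3.1a", "3.1b", "3.1d")] <- "yes"
rec <- data.frame(subtool = 3, criterion_id = names(ans), respondent = 1,
                  value = unname(ans))
subtool_score(inst, new_session("F1", "2011", rec), 3)
# one respondent met 3.1a, 3.1b (weight 3) and 3.1d (weight 4):
# 100 * (3 + 3 + 4) / 26 = 38.46 %
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` in `classify_score()` | 75 (%) | scores strictly below are "unsatisfactory"; 75.0 itself is satisfactory |
| star thresholds in `p_stars()` | 0.05 / 0.01 / 0.001 | `*`, `**`, `***` on paired-test p-values |
| `decimals` in `write_scores()` | 1 | reported percentages are rounded only at output; all internal arithmetic is full precision |
| `k` in `summary_sheet()` | 5 | strengths/weaknesses listed per facility |
| `cutoff` in `criterion_report()` | 0.75 | fraction of facilities fully meeting a criterion for a green "met" flag |

Respondent-count rules are stored per sub-tool and facility type in the
instrument. The canonical descriptions are partially conflicting (a
dispensary needs "one to three" provider interviews, elsewhere "3–10"
providers and "5–10" respondents are quoted), so the package defaults are a
reconciliation: facility-level checklists (sub-tools 1 and 4) take one
observation everywhere; provider interviews and clinical observations
(2, 3) take 1–3 in dispensaries, 3–6 in health centers, 10 in hospital
OPDs; staff motivation (5) takes 1–3 / 5–10 / 10; client exit interviews
(6) take 5–10 at every type. Instruments may override any of these in
their YAML definition.

## Aggregation and trend-testing choices

*Aggregation* (`aggregate_scores()`) averages facilities with equal weight
within councils and regions — no size weighting — and excludes a facility
from a dimension's mean only where that dimension is undefined. Stratified
means (by ownership category) therefore recombine exactly into the
unstratified mean when weighted by facility counts; that identity is
tested.

*Summary sheets* rank weaknesses by weighted shortfall $w_c (1 - p_c)$ and
strengths by weighted attainment $w_c\,p_c$, ties broken by criterion id.
The original workflow names the output (a two-copy sheet of strengths and
weaknesses per dimension) but not a ranking rule, so the rule is the
package's own; it makes a heavily weighted half-missed criterion rank above
a lightly weighted fully missed one, which matches how assessors prioritise
feedback.

*Trends* (`paired_trend_test()`, `trend_table()`, `trend_tests()`) compare
a later round against the stratum's first (baseline) round with a
two-sided paired t-test over *complete pairs*: facilities assessed in both
rounds, matched by stable facility id so that reclassifications (e.g. a
dispensary upgraded to a health center) do not break pairs. Facilities
present in only one round are reported as excluded, never silently
dropped. Because the test uses complete pairs, its mean difference need not
equal the difference of the printed round means, which average whichever
facilities were assessed each round. Sidedness is two-sided by convention
(improvement is the expected direction but is not assumed); p-values are
reported uncorrected, matching the conventional presentation, with an
opt-in Bonferroni flag across the six dimensions in `trend_tests()`.
Degenerate difference vectors are handled explicitly rather than left to
`t.test()` (which errors on constant data): all-zero differences give
t = 0, p = 1; identical nonzero differences give an infinite t with the
p-value floored at the smallest positive double, both flagged
`zero_variance`.

## The synthetic-data generator

`sim_config()` + `generate_register()` / `generate_round()` /
`generate_dataset()` produce register and response files in exactly the
formats the assessment reader consumes, so every pipeline stage is testable
without field data. The response model: in round $r$, each answer to a
criterion of dimension $d$ is yes with probability
$q_d + (r-1)\,\delta_d$, independently per criterion and respondent,
overridden to NA with probability `na_prob`; respondent counts are drawn
uniformly within the instrument's respondent rule for the facility type;
each clinical scenario is observed with probability `scenario_prob`.
Ownership categories are allocated by largest remainder (ties by the
canonical category order) and assigned in seeded random order, so counts
are exact and datasets byte-reproducible under a fixed seed.

Default parameters are the package's choice of a realistic mid-range
council: $q = (0.70, 0.55, 0.70, 0.70, 0.40, 0.80)$ — client satisfaction
highest and staff motivation lowest, the pattern such assessments typically
find at baseline — $\delta_d = 0.03$ per round, 5 % NA answers, 80 %
scenario observation.

What the generator deliberately does *not* emulate: correlation between
criteria of one facility (the default model is fully independent given
$q_d$), assessor effects, item-specific difficulty, and informative
missingness (NA is applied uniformly). An optional facility-level random
effect (`facility_sd > 0`) draws each facility's dimension probability
from a beta distribution with mean $q_d$, adding between-facility
heterogeneity; it is off by default to keep calibration checks exact.
Passing tests on synthetic data therefore validate the *arithmetic* of the
engine — parameter recovery, power, invariances — not the behaviour of the
instrument on real facilities, where clustering and item heterogeneity
would widen uncertainty.

## Numerical choices and problem sizes

* All scores are computed in double precision; rounding (default one
  decimal) happens only in output writers and print methods.
* The 75 % classification boundary is a strict less-than; 75.0 itself is
  satisfactory.
* Ties in strength/weakness rankings and in largest-remainder allocation
  break deterministically (criterion id order; ownership category order).
* Un-scorable sub-tools signal a typed condition
  (`etiqh_error_no_defined_criteria`); `facility_score()` converts it into
  an undefined dimension so a partially assessed facility still gets an
  overall score over its defined dimensions, with
  `n_dimensions_defined` recording how many.
* Validation runs at volumes chosen to keep the default suite fast while
  exercising the claims: randomized property suites at 200 cases per
  property (1,000 in the end-to-end suite), exhaustive oracle comparison
  on small answer grids, parameter recovery on a 200-facility council
  against the full-scale reference instrument (tolerance ±1.5 percentage
  points), and paired-test power over 1,000 replicates of 40 pairs with a
  true shift of 5 points and difference SD 5.

## Known limitations

* The reference instrument's criterion texts are placeholders; analyses of
  real assessments need the actual instrument definition file.
* Scores are facility means with no case-mix or measurement-error
  adjustment; inter-rater reliability is out of scope.
* The paired t-test treats facility scores as approximately normal
  differences; with very small councils (< 2 complete pairs) no test is
  attempted, and counts that small are common for hospitals.
* Round labels are opaque and ordered lexicographically by default; supply
  `round_order` where labels do not sort chronologically.
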