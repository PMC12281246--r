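---
title: "Disproportionality screening methods in pvscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening methods in pvscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvscreen)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS accumulate
millions of individual case safety reports. They have no denominator — no
count of patients exposed — so incidence cannot be estimated. What can be
estimated is *disproportionality*: whether a drug–event pair is reported
more often than the independence of drug and event across the whole
database would predict. pvscreen implements this screening design for the
motivating application — antidepressant-associated seizures — but the
machinery (case assembly, vocabularies, 2×2 construction, signal
statistics, confounder sensitivity reanalysis) is generic.

## From raw tables to cases

A quarter arrives as four `$`-separated tables: DEMO (one row per report
version, demographics), DRUG (drug entries with a role code: PS primary
suspect, SS secondary suspect, C concomitant, I interacting), REAC
(adverse-event preferred terms, PTs) and INDI (indication PTs). Assembly
joins the three satellite tables onto DEMO by `primaryid`. A report without
any adverse event, or without any drug entry, is not a valid safety report
and is excluded with a logged count; rows whose `primaryid` has no DEMO row
are counted as orphans. Malformed lines (wrong field count) go to a rejects
table rather than being silently dropped.

**Deduplication.** A case (identified by `caseid`) may appear as several
report versions. We keep the version with the highest `caseversion`
(receipt sequence), breaking ties by the lexicographically highest
`primaryid` so the rule is deterministic; all older versions are discarded
rather than merged. This is the conventional treatment of quarterly
cumulative files: the latest version supersedes the earlier ones. The
operation is idempotent and its removal count is logged.

**Demographic decoding.** Sex: `F`/`M`, anything else unknown. Reporter:
`MD`, `PH`, `OT`, `HP` are health professionals; `CN`, `LW` are not;
missing is unknown. Region comes from a shipped country-to-continent
lookup; unlisted countries decode to unknown. Age is converted to years
from its unit code — `YR` ×1, `DEC` ×10 (a decade is ten years), `MON` /12,
`WK` /52, `DY` /365.25 — and implausible values (negative or ≥ 150) become
missing. Age bands are `<18` (age < 18), `18–65` (18 ≤ age < 65) and `≥65`
(age ≥ 65): the published band labels do not state where 65 itself falls,
so we adopt the half-open convention and document it here; a case with
missing age is its own stratum.

## Vocabularies

Drugs are mapped to WHO ATC codes by exact lookup after normalization
(case-folding, punctuation stripping, whitespace collapsing). There is
deliberately no fuzzy matching: edit-distance mappings are irreproducible
and the gain is marginal when a curated synonym table is available. The
packaged dictionary covers the 65 drugs of the antidepressant class N06A
plus common brand synonyms.

Events are matched against *term sets*: named PT sets with explicit
inclusion and exclusion lists, the shape of a curated SMQ. The packaged
seizure set is a **synthetic skeleton**: MedDRA PT lists are licensed and
cannot be redistributed, so we ship placeholder codes with the correct
arithmetic — 84 candidate terms, 43 excluded as unequivocally not
drug-induced (e.g. post-stroke seizure, post-traumatic epilepsy), 41
retained. Users with a MedDRA licence load their own export through
`load_term_set()`; everything downstream is agnostic to the actual codes.
The confounder catalog skeleton follows the same logic with five categories
of seizure-prone co-existing conditions (81/30/215/115/181 PTs).

## The 2×2 table and its conventions

For drug \(D\) and event set \(E\), every deduplicated report falls in
exactly one cell:

|            | event in \(E\) | no event in \(E\) |
|------------|:---:|:---:|
| has \(D\)  | a | b |
| no \(D\)   | c | d |

Three conventions matter and are fixed here:

* **Unit of counting is the report.** A report listing two seizure PTs
  counts once in `a`; within-report multiplicity must not inflate
  disproportionality.
* **Exposure means a primary-suspect entry** by default (`roles = "PS"`),
  configurable to any subset of the four role codes.
* **The comparator is the whole database** — every deduplicated report,
  not only reports of the drug class under study. This is the standard
  full-database design; restricting the background to the class would
  change the estimand and shrink `c`+`d` drastically.

Every build asserts the partition `a+b+c+d = n`.

## Signal statistics

**Reporting odds ratio.** \(\mathrm{ROR} = (a/b)/(c/d)\) with the
Woolf/Wald 95% interval
\(\exp\!\big(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\big)\).
The constant 1.96 is used literally, the universal convention in this
literature. With a zero cell the point estimate follows the arithmetic and
the interval is undefined (`NA`); an optional Haldane–Anscombe correction
(+0.5 to all cells, applied only when some cell is zero) yields finite
bounds. It is off by default: the joint criterion requires `a ≥ 3`, so
zero-cell pairs can never signal anyway.

**Information component.** The IC is a shrunk log2 observed/expected
measure,
\[
\mathrm{IC} = \log_2 \frac{a + 0.5}{E + 0.5}, \qquad
E = \frac{(a+b)(a+c)}{n},
\]
with closed-form 95% credibility bounds
\(\mathrm{IC}_{025} = \mathrm{IC} - 3.3\,(a{+}0.5)^{-1/2} - 2\,(a{+}0.5)^{-3/2}\)
and
\(\mathrm{IC}_{975} = \mathrm{IC} + 2.4\,(a{+}0.5)^{-1/2} - 0.5\,(a{+}0.5)^{-3/2}\).
This deterministic shrinkage form was chosen over the original gamma-mixture
BCPNN formulation because it is closed-form and exactly testable; the
estimator sits behind a single function (`ic_shrinkage()`) so the gamma
variant could be added without touching the screen. The +0.5 pulls
small-count estimates toward zero and vanishes asymptotically: at fixed
\(O/E\) the IC converges to \(\log_2 O/E\), and when \(a = E\) the IC is
exactly zero.

**Joint criterion.** A pair is a signal only when all of the following
hold strictly: \(a \ge 3\), ROR lower bound \(> 1\), \(\mathrm{IC} > 0\),
\(\mathrm{IC}_{025} > 0\). Missing bounds fail the criterion. Pairing the
frequentist ROR with the shrunk IC trades a little sensitivity for
stability on rare events; the case-count floor suppresses single-report
artefacts. Screens are ranked by descending ROR with ties broken by drug
label, so output is deterministic.

## Confounder sensitivity reanalysis

Confounding by indication is the dominant artefact in this design: a drug
prescribed to patients with a seizure-prone condition will co-report
seizures regardless of causality. The reanalysis flags every report whose
event *or indication* PTs intersect any catalog category — indications are
consulted because that is exactly where the confounding mechanism
manifests — and re-runs the screen on the remaining reports. Two scope
decisions are deliberate:

* A flagged report is removed from the **entire analysis**, all four
  cells. Removing it only from `a` would deflate the exposed cells while
  leaving the background inflated, biasing the adjusted ROR upward.
* The verdict is per drug: `robust_signal` when the primary signal
  survives adjustment, `false_signal` when it disappears,
  `no_primary_signal` otherwise.

## The synthetic generator

Real spontaneous-report data cannot ship with the package, so validation
rests on a generator whose ground truth is known analytically. Each case
draws demographics from configurable strata (the defaults reproduce the
published seizure-cohort mix: 54.5% female, 49.5% aged 18–65, 70% reported
by health professionals, 67.1% with unknown region), one primary-suspect
drug from a background frequency table, and the index event with
probability \(p\,\lambda_D\) (base rate \(p = 0.02\) by default; planted
relative rates \(\lambda\) default to a landscape with one strong signal
drug near 8.6, a band of moderate drugs between 1.3 and 4.7 and the rest
null, mirroring the magnitude spread a screen of this class encounters).
Every case also carries at least one background (filler) event PT — so no
invalid empty reports arise — and a benign indication. With probability
`duplicate_rate` (default 0.1) a case emits a stale earlier version sharing
its `caseid`, which deduplication must discard. A confounding mechanism
optionally injects, with per-drug probability, a seizure-history indication
PT *together with* an index event PT.

Because each case carries exactly one drug, the implied population odds
ratio is closed-form: with background weights \(w\) and per-drug event
probability
\(s_D = 1 - (1 - \min(p\lambda_D, 1))\prod_k (1 - q_{Dk})\)
(the \(q_{Dk}\) being the drug's confounded-pair probabilities),

\[
\mathrm{OR}_D =
\frac{w_D s_D \sum_{D' \ne D} w_{D'}(1 - s_{D'})}
     {w_D (1 - s_D) \sum_{D' \ne D} w_{D'} s_{D'}}.
\]

`expected_ror()` evaluates this; the test suite verifies it against a
Monte-Carlo estimate and uses it as the recovery target. One drug per case
is the default deliberately — multi-drug cases (co-reporting) would make
the estimand a mixture without a closed form; the generator is a validation
instrument, not a FAERS emulator.

**What the generator does not emulate.** Free-text drug-name noise,
reporting trends over time, dose/formulation fields, multi-drug
polypharmacy, correlated demographics (e.g. age-dependent drug choice), and
event-dependent reporting propensity. Passing the simulation suite
therefore demonstrates that the statistical machinery is correct under the
stated generative model, not that any particular real-data finding is
reproduced.

## Numerical and validation choices

* **Rounding** of reported percentages and ratios is half-up (away from
  zero), one decimal for demographic percentages, two for constituent
  ratios and the sex ratio. Half-up is what reproduces published
  count-to-percentage tables exactly; IEEE half-even does not.
* **Validation problem sizes.** The suite exercises: an exhaustive grid of
  all 2×2 tables with cells 1–30 against direct-arithmetic oracles
  (relative error < 1e−12); null calibration with 20 seeded cohorts of
  50,000 cases, requiring the signal fraction among truly null drugs to
  stay within the nominal budget (≤ 5% + 2 points); parameter recovery with
  planted \(\lambda \in \{2, 4, 8\}\) in 20 seeded cohorts of 200,000
  cases, requiring ≥ 90% empirical coverage of the analytic odds ratio by
  the Wald interval over all planted-pair × replicate checks; and a
  confounding scenario (one purely confounded drug, one genuinely elevated)
  in 20 seeded cohorts of 20,000 cases, requiring the correct verdict in at
  least 18.
* **Determinism.** All simulation draws derive from one root seed; screens
  and pipeline outputs are byte-reproducible given identical inputs.

## Limitations

Disproportionality is a hypothesis-generating screen, not an incidence or
risk estimate: reporting odds ratios inherit every reporting bias in the
stream (stimulated reporting, channeling, notoriety effects). The
confounder reanalysis removes reports carrying *coded* co-existing
conditions; conditions present but not coded remain. The shipped term sets
are skeletons — real analyses must supply licensed MedDRA exports. And the
pipeline deliberately implements no multiplicity adjustment across drugs,
matching standard practice for this screen; users comparing many classes
should impose their own error control.
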