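---
title: "Methods: disproportionality signal detection on FAERS-style reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on FAERS-style reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect voluntary post-marketing reports of suspected adverse drug
events. Each quarterly release is a set of `"$"`-delimited ASCII datasets —
demographics (DEMO), drugs (DRUG), reactions coded as MedDRA preferred terms
(REAC), therapy dates (THER), outcomes (OUTC), indications (INDI). The data
are noisy in characteristic ways: the same case appears as multiple report
versions across quarters, drug names are free text, and dates are frequently
partial or absent.

`faersignal` implements the standard pharmacovigilance workflow over such
data for an *index drug* (by default bevacizumab, synonyms "Bevacizumab" and
"Avastin", biosimilar suffixed names excluded) and a *target event* set (by
default the preferred terms "Pulmonary haemorrhage" and "Haemoptysis"):
deduplicate, select index reports, classify each into a treatment-regimen
subgroup, quantify disproportionate reporting with the reporting odds ratio
(ROR), and describe time to onset and cohort characteristics.

## Deduplication

Following the FDA-recommended rule, within a CASEID the report version with
the latest FDA receipt date (FDA_DT) is kept; ties are broken by the highest
PRIMARYID. Two choices the rule itself leaves open:

* **PRIMARYID comparator** — numeric when every id in the table parses as a
  number (the realistic case: FAERS PRIMARYIDs are numeric strings), else
  lexicographic.
* **Missing FDA_DT** — a record whose FDA_DT does not yield at least a year
  is kept only if its CASEID has no dated version, and such keeps are
  flagged in the decision log. Dropping them outright would silently lose
  cases that were reported only once.

Only exact CASEID matches are merged; probabilistic matching of similar
reports filed under different CASEIDs is out of scope, so some true
duplicates will survive — as they do in any analysis using this rule.

## Regimen classification

Drug names are normalized (trimmed, whitespace-collapsed, case-folded) and
matched **exactly** against a configurable lexicon of chemotherapy, immune
checkpoint inhibitor (ICI) and targeted-therapy names. Substring matching is
deliberately avoided: it conflates distinct molecules (consider platinum
salt names that contain one another). The packaged lexicon reproduces the
published bevacizumab regimen table.

Reports are assigned to exactly one of `MONO`, `PLUS_CHEMO`, `PLUS_ICI`,
`PLUS_TARGETED`. When several co-medication categories co-occur, precedence
is `PLUS_CHEMO > PLUS_ICI > PLUS_TARGETED`: chemotherapy is the usual
backbone of bevacizumab combinations, so a chemo+ICI report is counted as a
chemotherapy combination. The order is configurable and recorded in the run
manifest; classification is invariant to drug order within a report and the
four classes always partition the index cohort. Drug role codes (suspect /
concomitant) do not restrict membership by default, since the analysis we
mirror does not mention roles; a role filter is available.

## Disproportionality

For a drug group against the full deduplicated database, the 2×2 table
counts unique reports:

|                | target event | other events |
|----------------|--------------|--------------|
| group          | a            | b            |
| all other drugs| c            | d            |

$$\mathrm{ROR} = \frac{a\,d}{b\,c},\qquad
95\%\ \mathrm{CI} = \exp\!\Big(\ln \mathrm{ROR} \pm
1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big)$$

A *positive signal of disproportionate reporting* requires the lower CI
limit to exceed 1 **and** at least three cases (`a >= 3`). Numerical
choices:

* `z = 1.96` exactly, the conventionally printed constant, not
  `qnorm(0.975)`.
* Any zero cell makes the result **non-estimable** rather than corrected —
  the signal rule requires three cases anyway, so a continuity correction
  would only manufacture estimates nobody acts on. The Haldane–Anscombe
  +0.5 correction is available behind a flag for sensitivity work.
* The counting unit is the unique deduplicated **report** for every cell.
  Report-level and drug–event-pair-level counts differ in FAERS summaries;
  report counting is internally consistent (cells sum to the population)
  and is what the signal rule's case count means. A pair-level mode
  (`unit = "pair"`) is provided for sensitivity analysis.

Subgroups are compared with a Pearson chi-square test (1 df) on the
event/non-event split of the two groups, without Yates correction by
default (the correction is an option); an expected cell below 1 attaches a
warning to the result.

## Time to onset

Onset is `EVENT_DT - START_DT` in calendar days, where `START_DT` is the
earliest *fully dated* therapy start of an index-drug entry. Both dates must
be complete; exclusions are recorded as data with exactly one reason each,
applied in order: partial/missing event date, partial/missing start date,
event before start (an input error). Same-day onset is 0 days. When a
report has several index therapy rows, the earliest full start is used —
onset since first exposure.

Medians and quartiles use linear interpolation between order statistics
(`quantile type 7`, R's default; the convention is recorded in the summary
object since published IQRs rarely state theirs). The cumulative curve is
the empirical CDF, and a binned percentage table (0–30, 31–60, 61–90,
91–180, 181–360, >360 days, configurable) is produced. Reporting year is
taken from FDA_DT — receipt year is what "reporting year" means and
EVENT_DT is too often missing. Age is carried but not summarized beyond
missingness, matching the near-total absence of age in the motivating
cohort.

## The synthetic world

`faers_simulate()` / `faers_generate()` emit FAERS-shaped data with known
ground truth so every stage is testable without a download. A report
carries each configured drug group independently with its marginal
probability; its target-event odds are the baseline odds times the product
of the multipliers of the groups it carries (groups at multiplier 1 — the
default for everything but the index group — leave the odds untouched, so
the index group's marginal odds ratio equals its configured multiplier).
Defaults state the world the analysis is designed for:

* 5,000 unique reports, baseline event probability 0.02, an index group at
  marginal 0.10 with multiplier 4 — the order of magnitude of association
  the published analysis detects;
* duplicate rate 0.15 — roughly the share of FAERS report versions that
  deduplication removes (19.5M → 16.5M);
* 30% partial dates and 30% missing event dates — about half of real
  target-event reports lack a computable onset;
* onset drawn log-normal with median 43 days and geometric dispersion 4.5,
  matching a right-skewed onset whose quartile ratio is near 8.

Duplicates are re-emitted with the same CASEID and content, a later FDA_DT
and a higher PRIMARYID — exactly the duplicates the dedup rule removes, so
post-dedup counts equal ground truth by construction. Drug names get random
case and occasional trailing whitespace to exercise normalization. Dates
are internally consistent (FDA_DT lies in its file's quarter).

What the generator does **not** emulate: drug co-prescription correlation,
the MedDRA hierarchy (PTs are flat strings), reporting-rate drift over
calendar time, and informative missingness. A green calibration test
therefore establishes that the statistics are computed correctly on data
with FAERS's *structural* quirks — not that the pipeline is robust to every
epidemiological bias in real spontaneous reports (notably, confounding and
reporting bias are properties of the world, not of the arithmetic).

Calibration facts the test suite verifies: under a null multiplier the
positive-signal rate stays below ~7% and the 95% CI covers the true odds
ratio in 90–98% of replicates; under multiplier 5 with an expected `a`
above 20, power exceeds 95%; the pipeline's ROR equals the realized odds
ratio of the generated reports exactly, end to end.

## Degenerate inputs and determinism

Empty groups yield (0, 0, c, d) tables and non-estimable RORs; an empty
target cohort flows through to explicit zero-count outputs rather than an
error. `faers_parse_date()` is total — garbage yields an absent date, never
an exception. All randomness flows from the simulation config's single
seed; a fixed config reproduces byte-identical files and the run manifest
suffices to re-run a simulate-mode analysis bit-identically.

## Known limitations

Only the PRIMARYID-era FAERS schema is read (legacy ISR-keyed files are
rejected by omission, not mis-parsed). Indication mapping is a keyword map
over free-text preferred terms and will misfile exotic phrasings into
`Others`. The ROR quantifies disproportionate *reporting*; it is not a risk
estimate and carries no causal content.
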