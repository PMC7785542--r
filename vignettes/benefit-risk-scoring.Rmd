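---
title: "A quantitative benefit-risk scoring model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantitative benefit-risk scoring model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brscore)
```

## The model

`brscore` treats a regulatory benefit-risk table as structured categorical
data and scores it with transactional accounting: a gross benefit balance,
deductions for each risk, credits for risk management, and a net position.

**Benefit.** Four parameters describe the benefit case — severity of the
condition, prevalence of the condition, availability of alternative
treatments, and durability (robustness) of the efficacy evidence — each on a
three-level categorical scale. Every level has a numeric value on a 5-point
range and the Gross Benefit Score is the *product* of the four values,
multiplied by an orphan emphasis factor when the product carries an orphan
designation, then capped at a ceiling. The product form (rather than a sum)
makes the parameters interact: a severe, untreatable rare disease with solid
evidence scores two orders of magnitude above a mild condition with many
alternatives, which matches how sharply approval stringency varies across
those situations. The cap encodes a behavioural assumption: beyond some
point, additional benefit cannot buy tolerance for more risk.

**Risk.** Risk analysis factors likelihood against severity of harm. Each
coded adverse event contributes `RS = v(severity) × v(frequency band)`.
Severity is anchored to CTCAE grades (1–2 mild, 3 moderate, 4–5 severe);
frequency is banded low / medium / high. A declared severity that disagrees
with its grade requires an explicit `severity_override` flag — we deliberately
support overrides as data rather than inferring them from descriptive text,
for reproducibility.

**Mitigation.** Each mitigation activity has an implementation-burden value
from 0 (routine pharmacovigilance, which every sponsor must do anyway and so
earns no credit) to 5 (REMS). The per-risk credit is the *sum* of its
mitigation values — the cap applies to the sum, not to individual items —
and is capped so that credit can never exceed the risk score it offsets.
Unless a risk is explicitly `resolved_no_risk`, a residual floor (default 1)
keeps a mentioned risk from being mitigated to exactly zero: if a risk was
worth mentioning in a review, some residual risk remains possible.

**Summary statistics.** With `RRS` the sum of per-risk residuals,

- `NBS = GBS − RRS` — positive means benefits outweigh residual risks;
- `BRR = GBS / RRS` — favorable above 1.0; undefined (sentinel
  `"undefined_all_risk_mitigated"`) when `RRS = 0`.

Both are reported with coarse interpretation bands (negative / marginal-low /
medium / high) because the coding process has limited precision; the bands,
not the exact values, are the intended unit of interpretation.

## Parameters and defaults

The source framework publishes its structure — 3-level scales, 5-point
values, a benefit ceiling, the mitigation cap, orphan emphasis — but not its
numeric tables. The defaults here are therefore a design choice, fixed once:

| parameter | default | rationale |
|---|---|---|
| benefit level values | 1 / 3 / 5 per parameter (prevalence 2 / 3 / 5) | ends and middle of the 5-point range; prevalence keeps a non-trivial lowest level because a "population subset" is still a real population |
| orphan multiplier | 1.25 | emphasis without letting the flag dominate a 5-point scale |
| GBS ceiling | 100 | a maximal benefit case (5·5·5·5 = 625) lands exactly on the cap, consistent with the highest division-average GBS of 100 in the reference table |
| risk severity / frequency values | 1 / 3 / 5 each | symmetric with benefit; RS spans 1–25 |
| mitigation burden values | routine 0, label W&P 1, boxed warning 2, monitored administration 3, registry 4, REMS 5 | ordered by public-health implementation burden |
| residual floor | 1 | smallest positive value on the scale: a mentioned risk is never fully erased |
| NBS band thresholds | 0 / 25 / 60 | 0 is the approvability sign rule; 25 and 60 split the observable 0–100 range into low/medium/high thirds weighted toward the reference rows' 35–95 spread |
| BRR band thresholds | 1 / 3 / 10 | 1 is the favorability rule; 3 and 10 separate single-digit from order-of-magnitude dominance of benefit over risk |
| BRR reporting precision | 2 decimals, half-up | reproduces the printed reference ratios (100/31 → 3.23) |

All of these are overridable through `default_config()` arguments or a YAML
file (`read_config()` / `write_config()`; the canonical document ships as
`inst/extdata/default_config.yaml`).

Two genuinely open points were decided as follows. *Ceiling vs. orphan
order*: the multiplier applies first, then the cap — emphasis should help
mid-range orphan products, while a maximal case is already at the ceiling.
*Floor vs. full mitigation*: the framework's prose both allows mitigation to
"reduce a risk score to zero" and insists residual risk persists "unless
otherwise described as no risk"; we resolve in favour of the floor, with
`resolved_no_risk` as the explicit escape hatch.

## Numerical conventions

- **Frequency band boundaries.** The printed bands ("0 to 5 %", "5.1 % to
  40 %", "40.1 % to 100 %") leave gaps for real-valued percentages; they are
  implemented as the half-open partition [0, 5], (5, 40], (40, 100], so
  5.0 % is low and 5.05 % is medium.
- **Banding intervals.** Interpretation bands use half-open intervals
  `(t_i, t_{i+1}]`, so NBS = 0 and BRR = 1 are both `negative` — consistent
  with the strict inequalities in the approvability rule.
- **Rounding.** All internal arithmetic is unrounded; rounding (half-up, via
  an explicit `trunc(x·10^d + 0.5)` rather than banker's `round()`) applies
  only at the reporting surface.
- **Division summaries.** `nbs_of_means` is computed from *unrounded*
  division means and rounded only for display, and the division-average BRR
  is the arithmetic mean of per-product ratios, not the ratio of mean
  scores — the reference table's all-products row (81, −16, BRR 13.26 ≠
  81/16) forces the mean-of-ratios reading, and its rows are internally
  inconsistent about rounded-vs-unrounded NBS arithmetic, so one convention
  had to be fixed.
- **Degenerate inputs.** Zero-risk products are permitted: NBS = GBS and the
  BRR carries the sentinel with a warning; division summaries exclude such
  products from the mean ratio and report the excluded count. Empty
  portfolios are an error for summaries and an empty sum (RRS = 0) inside a
  product.
- **Calibration tie-breaks.** `calibrate()` enumerates the candidate grid
  lexicographically in the canonical parameter order of
  `default_search_space()` (earlier parameters vary slowest) and returns the
  *first* feasible configuration; infeasible searches return the candidate
  with fewest violations, ties broken by enumeration order. Grids above the
  evaluation budget are subsampled reproducibly from the given seed, always
  retaining the lexicographic head. Candidates violating value-map
  monotonicity are skipped, so the search can never emit an inconsistent
  configuration. The search is over discrete integer grids in keeping with
  the 5-point scales; continuous optimisation would suggest a precision the
  coding process does not have.

## What the synthetic generator emulates — and what it does not

`generate_portfolio()` draws coded profiles, not documents. Its defaults
emulate a five-year novel-approval portfolio: the division mix follows the
published per-division product counts; benefit parameters lean toward severe
conditions with limited alternatives and robust evidence (division-average
GBS near the top of the scale, as in the reference rows); every product has
at least one risk (a review always lists a risk, or the default routine
pharmacovigilance), with 1 + Poisson(1.5) risks per product and
Poisson(0.8) mitigations per risk; `enforce_approvability` rejection-samples
each product to NBS > 0 under a reference configuration, mirroring the fact
that a retrospective approved-products portfolio satisfies the approvability
constraint by construction.

The generator does **not** emulate: correlation between a division and its
typical risk profile (oncology's high-grade toxicities vs. dermatology's
tolerability issues), correlation between benefit parameters and risk counts
within a product, verbatim-text noise and coder disagreement, or the
year-to-year drift of review formats. Passing property tests on generated
portfolios therefore demonstrates the *arithmetic and its invariants* —
sign equivalence, monotonicity, cap/floor saturation, idempotent
normalization — on widely varied coded inputs; it does not validate the
default value tables against real FDA outcomes, which would require the
unpublished coded database of actual reviews.

## Problem sizes

The shipped checks use fixed sizes chosen to exercise the claims at
statistical resolution appropriate for categorical arithmetic: property
sweeps over 1000 unconstrained random profiles; exhaustive enumeration of
all 162 benefit combinations and 9 risk cells against a straight-line
arithmetic oracle; calibration recovery over 100 seeded trials of
100-product portfolios; round-trip and determinism checks on 25–50-product
portfolios. Distributional sanity of the generator is checked at n = 600
within 3.5 standard errors.

## Limitations

- The numeric value tables are not pinned down by published information; the
  division-average reference rows are means over unpublished per-product
  scores and cannot identify the weights uniquely. Conclusions should rest
  on configurable re-scoring, not on the defaults being "the" weights.
- The built-in risk-term lexicon is a small synonym table; real coding work
  should supply a dictionary-derived lexicon (e.g. MedDRA, licence
  permitting) through the `lexicon` hook.
- Only the coded BRT content is modelled. Prose integrated assessments,
  CMC issues and post-approval label changes are out of scope, as is any
  probabilistic or preference-based benefit-risk model: this is a
  deterministic codification-and-accounting scheme.
- Scores of products from different divisions share a scale only to the
  extent the coding is consistent across review cultures; the division
  summary exists precisely because division-level patterning is expected.
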