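# brscore

Quantitative benefit–risk scoring for regulatory product approvals.

FDA's Benefit–Risk Framework summarises why a drug or biologic was approved,
but it is descriptive: the benefit–risk table (BRT) lists the condition, the
treatment options, the benefits and the risks with their risk management, and
leaves the trade-off to qualitative judgement. `brscore` implements a
quantitative version of that framework for regulatory scientists, sponsors and
decision analysts: it codifies a product's BRT content onto fixed categorical
scales and collapses it to a single-value summary of the trade-off — a
Net-Benefit Score and a Benefit–Risk Ratio — that can be compared across
products, divisions and development milestones.

## The model

Each product is coded as four benefit parameters, a list of risks and their
mitigations:

- **Benefit** — condition severity, condition prevalence, treatment
  availability and durability of the efficacy evidence, each on a 3-level
  scale mapped to values on a 5-point range. The **Gross Benefit Score** is
  their product, emphasised by an orphan multiplier for orphan-designated
  products, and capped at a ceiling (default 100) so that no benefit case can
  overwhelm unlimited risk:

  `GBS = min(ceiling, orphan_factor × v_sev × v_prev × v_avail × v_dur)`

- **Risk** — each adverse event is coded by severity (CTCAE-anchored:
  grades 1–2 mild, 3 moderate, 4–5 severe) and frequency band (low 0–5 %,
  medium >5–40 %, high >40 %). The per-risk **Risk Score** is
  `RS = v_severity × v_frequency`.

- **Mitigation** — each mitigation activity carries a burden value 0–5
  (routine pharmacovigilance 0, label warning 1, … REMS 5). The per-risk
  **Risk Mitigation Score** is their sum, capped so credit can never exceed
  the risk it mitigates; a mentioned risk keeps a residual floor (default 1)
  unless explicitly resolved. Summing the per-risk residuals `RS − RMS` gives
  the **Residual Risk Score** (RRS).

- **Summary** — `NBS = GBS − RRS` (positive ⇔ benefits outweigh residual
  risks) and `BRR = GBS / RRS` (favorable above 1.0), both banded as
  negative / marginal-low / medium / high. Every value table, cap, floor and
  band threshold lives in a YAML-serialisable configuration
  (`default_config()`), and `calibrate()` searches configuration grids
  against the constraint that approved products must score NBS > 0 and
  BRR > 1.

## Worked example

```r
library(brscore)

profile <- product_profile(
  "EX-001", "examplinib", 2018, "DHOT",
  benefit = benefit_assessment("severe", "rare_orphan", "none_exist",
                               "consistent_substantial", orphan_designation = TRUE),
  risks = list(
    risk_entry(risk_item("neutropenia", ctcae_grade = 4, frequency_percent = 55)),
    risk_entry(risk_item("infusion reaction", "moderate", frequency_band = "medium"),
               list(mitigation_item("boxed_warning"),
                    mitigation_item("label_warning_precaution")))),
  designations = "orphan")

breakdown <- score_product(profile)
breakdown
#> <score_breakdown> EX-001
#>   GBS 100 | RRS 31 (signed -31) | NBS 69 (high) | BRR 3.23 (medium)
#>   2 risk(s); residuals: 25, 6
breakdown$risks
#>                term rs rms_raw rms_capped residual
#> 1       neutropenia 25       0          0       25
#> 2 infusion_reaction  9       3          3        6
```

The benefit case is maximal (severe, rare condition with no alternatives and
robust evidence: 5×5×5×5 = 625, ×1.25 orphan emphasis, capped at 100).
Grade-4 neutropenia at 55 % codes as severe/high (RS 25) with only default
routine pharmacovigilance (credit 0), so its full 25 remains; the
moderate/medium infusion reaction (RS 9) earns 3 points of mitigation credit,
leaving 6. NBS = 100 − 31 = 69 and BRR = 100/31 = 3.23: a strongly positive
net benefit, i.e. the profile predicts approval.

Portfolios aggregate the same arithmetic:

```r
portfolio <- generate_portfolio(simulation_spec(seed = 1, n_products = 50))
format_division_table(summarize_by_division(portfolio))
```

and `render_report(profile)` prints the updated framework layout (four
benefit rows, one "Risk and Mitigations #i" row per risk, a net-benefit row).

A command-line surface wraps the same functions:

```sh
BRSCORE=$(Rscript -e 'cat(system.file("cli/brscore.R", package = "brscore"))')
Rscript $BRSCORE simulate --seed 1 --n 50 --out portfolio.json
Rscript $BRSCORE score portfolio.json --out scores.csv
Rscript $BRSCORE summarize portfolio.json --out divisions.csv
```

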