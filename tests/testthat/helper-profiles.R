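# fixture builders and an independent straight-line arithmetic oracle.
# The oracle re-derives every score from the value-table definitions with
# plain arithmetic and shares no code path with the package implementation.

max_benefit <- function(orphan = TRUE) {
  benefit_assessment("severe", "rare_orphan", "none_exist", "consistent_substantial",
                     orphan_designation = orphan)
}

daaap_like_profile <- function() {
  product_profile(
    "FIX-DAAAP-1", "synthetic-daaap-like", 2017, "DAAAP",
    benefit = max_benefit(),
    risks = list(risk_entry(
      risk_item("hepatotoxicity", "severe", frequency_band = "high"),
      list(mitigation_item("rems"), mitigation_item("postmarketing_study_registry")))),
    designations = "orphan", indication = "chronic_pain")
}

dhot_like_profile <- function() {
  product_profile(
    "FIX-DHOT-1", "synthetic-dhot-like", 2018, "DHOT",
    benefit = max_benefit(),
    risks = list(
      risk_entry(risk_item("neutropenia", "severe", frequency_band = "high")),
      risk_entry(risk_item("infusion reaction", "moderate", frequency_band = "medium"),
                 list(mitigation_item("boxed_warning"),
                      mitigation_item("label_warning_precaution")))),
    designations = "orphan", indication = "hematologic_malignancy")
}

# ---- oracle ----------------------------------------------------------------

oracle_tables <- list(
  severity = c(mild = 1, moderate = 3, severe = 5),
  prevalence = c(population_subset = 2, general_population = 3, rare_orphan = 5),
  availability = c(many_4_plus = 1, some_1_to_3 = 3, none_exist = 5),
  durability = c(not_consistent = 1, likely_semi_robust = 3, consistent_substantial = 5),
  risk_severity = c(mild = 1, moderate = 3, severe = 5),
  risk_frequency = c(low = 1, medium = 3, high = 5),
  mitigation = c(routine_pharmacovigilance = 0, label_warning_precaution = 1,
                 boxed_warning = 2, monitored_administration = 3,
                 postmarketing_study_registry = 4, rems = 5)
)

oracle_gbs <- function(sev, prev, avail, dur, orphan) {
  t <- oracle_tables
  raw <- t$severity[[sev]] * t$prevalence[[prev]] * t$availability[[avail]] * t$durability[[dur]]
  if (orphan) raw <- raw * 1.25
  if (raw > 100) 100 else raw
}

oracle_rs <- function(sev, freq) {
  oracle_tables$risk_severity[[sev]] * oracle_tables$risk_frequency[[freq]]
}

# rs, mitigation kinds, resolved flag -> residual after cap and floor
oracle_residual <- function(rs, kinds, resolved = FALSE) {
  raw <- sum(oracle_tables$mitigation[kinds])
  floor_val <- if (resolved) 0 else min(1, rs)
  capped <- min(raw, rs - floor_val)
  if (capped < 0) capped <- 0
  rs - capped
}

# full product rescore from a normalized profile, plain arithmetic throughout
oracle_breakdown <- function(profile) {
  b <- profile$benefit
  gbs <- oracle_gbs(b$condition_severity, b$condition_prevalence,
                    b$treatment_availability, b$durability, b$orphan_designation)
  residuals <- vapply(profile$risks, function(e) {
    kinds <- vapply(e$mitigations, function(m) m$kind, character(1))
    oracle_residual(oracle_rs(e$risk$severity, e$risk$frequency_band), kinds,
                    e$risk$resolved_no_risk)
  }, numeric(1))
  rrs <- sum(residuals)
  list(gbs = gbs, residuals = residuals, rrs = rrs, nbs = gbs - rrs,
       brr = if (rrs > 0) gbs / rrs else NA_real_)
}

# shared pool of unconstrained randomized profiles (properties must also hold
# in the negative-NBS region, so approvability is not enforced)
random_pool <- local({
  pool <- NULL
  function(n = 1000, seed = 42) {
    if (is.null(pool)) {
      pool <<- generate_portfolio(simulation_spec(
        seed = seed, n_products = n, enforce_approvability = FALSE))
    }
    pool
  }
})
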