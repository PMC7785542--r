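cfg <- default_config()

test_that("the gross benefit score is the capped product of parameter values", {
  expect_equal(score_benefit(max_benefit(orphan = TRUE), cfg), 100)   # 625 * 1.25, capped
  expect_equal(score_benefit(max_benefit(orphan = FALSE), cfg), 100)  # 625, capped
  low <- benefit_assessment("mild", "population_subset", "many_4_plus", "not_consistent")
  expect_equal(score_benefit(low, cfg), 2)  # 1 * 2 * 1 * 1
  ones <- default_config()
  for (nm in names(ones$benefit_values)) ones$benefit_values[[nm]][] <- 1
  expect_equal(score_benefit(low, ones), 1)
  # orphan emphasis below the ceiling
  mid <- benefit_assessment("moderate", "rare_orphan", "some_1_to_3", "not_consistent",
                            orphan_designation = TRUE)
  expect_equal(score_benefit(mid, cfg), 3 * 5 * 3 * 1 * 1.25)  # 56.25, below the ceiling
  # missing level -> configuration error
  broken <- default_config()
  broken$benefit_values$durability <- broken$benefit_values$durability[-1]
  expect_error(score_benefit(low, broken), class = "brscore_config_error")
})

test_that("the risk score is severity value times frequency value", {
  expect_equal(score_risk(risk_item("x", "severe", frequency_band = "high"), cfg), 25)
  expect_equal(score_risk(risk_item("x", "mild", frequency_band = "low"), cfg), 1)
  expect_equal(score_risk(risk_item("x", "moderate", frequency_band = "medium"), cfg), 9)
  zero <- default_config()
  zero$risk_severity_values[] <- 0
  expect_equal(score_risk(risk_item("x", "severe", frequency_band = "high"), zero), 0)
  expect_error(score_risk(risk_item("x"), cfg), class = "brscore_config_error")
})

test_that("mitigation credit is summed, capped at the risk score, and floored", {
  e <- risk_entry(risk_item("x", "severe", frequency_band = "high"),
                  list(mitigation_item("rems"), mitigation_item("postmarketing_study_registry")))
  expect_equal(score_mitigations(e, 25, cfg), list(rms_raw = 9, rms_capped = 9, residual = 16))
  # cap binds: credit cannot push the residual below the floor
  e2 <- risk_entry(risk_item("x", "mild", frequency_band = "medium"),
                   list(mitigation_item("rems")))
  expect_equal(score_mitigations(e2, 3, cfg), list(rms_raw = 5, rms_capped = 2, residual = 1))
  # routine pharmacovigilance alone earns nothing
  e3 <- risk_entry(risk_item("x", "severe", frequency_band = "high"),
                   list(mitigation_item("routine_pharmacovigilance")))
  expect_equal(score_mitigations(e3, 25, cfg), list(rms_raw = 0, rms_capped = 0, residual = 25))
  # an explicitly resolved risk may be mitigated all the way to zero
  e4 <- risk_entry(risk_item("x", "mild", frequency_band = "low", resolved_no_risk = TRUE),
                   list(mitigation_item("boxed_warning")))
  expect_equal(score_mitigations(e4, 1, cfg)$residual, 0)
})

test_that("residual, net-benefit and ratio arithmetic matches the definitions", {
  expect_equal(residual_risk_score(c(16, 1)), 17)
  expect_equal(residual_risk_score(numeric()), 0)
  expect_equal(residual_risk_score(7), 7)
  expect_error(residual_risk_score(-1), class = "brscore_domain_error")

  expect_equal(net_benefit_score(100, 16), 84)
  expect_equal(net_benefit_score(100, 31), 69)
  expect_equal(net_benefit_score(42, 42), 0)

  expect_equal(benefit_risk_ratio(100, 16), 6.25)
  # independent long-division check: 100/31 = 3.2258..., half-up at 2 dp -> 3.23
  expect_equal(floor(100 / 31 * 100 + 0.5) / 100, 3.23)
  expect_equal(benefit_risk_ratio(100, 31), 3.23)
  expect_equal(benefit_risk_ratio(42, 42), 1)
  expect_warning(s <- benefit_risk_ratio(50, 0), "undefined")
  expect_equal(s, BRR_UNDEFINED)
  expect_error(benefit_risk_ratio(10, -1), class = "brscore_domain_error")
})

test_that("interpretation bands use half-open intervals with the sign rules", {
  expect_equal(categorize(-5, cfg$nbs_bands), "negative")
  expect_equal(categorize(0, cfg$nbs_bands), "negative")
  expect_equal(categorize(0.9, cfg$brr_bands), "negative")
  expect_equal(categorize(1, cfg$brr_bands), "negative")
  expect_equal(categorize(1.2, cfg$brr_bands), "marginal_low")
  expect_equal(categorize(c(10, 84), cfg$nbs_bands), c("marginal_low", "high"))
  expect_error(categorize(1, list(thresholds = c(1, 1), labels = c("a", "b", "c"))),
               class = "brscore_config_error")
})

test_that("score_product equals the component composition and the straight-line oracle", {
  b <- score_product(daaap_like_profile(), cfg)
  expect_equal(b$gbs, 100)
  expect_equal(b$rrs, 16)
  expect_equal(b$nbs, 84)
  expect_equal(b$brr, 6.25)
  expect_equal(b$nbs_band, "high")

  pool <- random_pool()
  for (p in pool[seq(1, length(pool), by = 10)]) {
    got <- suppressWarnings(score_product(p, cfg))
    want <- oracle_breakdown(normalize_profile(p))
    expect_equal(got$gbs, want$gbs)
    expect_equal(got$risks$residual, want$residuals)
    expect_equal(got$rrs, want$rrs)
    expect_equal(got$nbs, want$nbs)
    if (identical(got$brr_status, "ok")) {
      expect_equal(got$gbs / got$rrs, want$brr, tolerance = 1e-12)
    }
  }
})

test_that("a zero-valued benefit config cannot produce a positive net benefit", {
  zero <- default_config()
  for (nm in names(zero$benefit_values)) zero$benefit_values[[nm]][] <- 0
  b <- score_product(daaap_like_profile(), zero)
  expect_equal(b$gbs, 0)
  expect_lte(b$nbs, 0)
  expect_equal(b$nbs_band, "negative")
})
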