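test_that("CTCAE grades map onto the three severity levels monotonically", {
  expect_equal(classify_severity_from_grade(1:5),
               c("mild", "mild", "moderate", "severe", "severe"))
  ranks <- match(classify_severity_from_grade(1:5), c("mild", "moderate", "severe"))
  expect_true(all(diff(ranks) >= 0))
  expect_error(classify_severity_from_grade(0), class = "brscore_invalid_grade")
  expect_error(classify_severity_from_grade(6), class = "brscore_invalid_grade")
  expect_error(classify_severity_from_grade(2.5), class = "brscore_invalid_grade")
})

test_that("frequency banding partitions [0, 100] with half-open boundaries", {
  expect_equal(classify_frequency(c(0, 3, 5)), rep("low", 3))
  expect_equal(classify_frequency(c(5.05, 20, 40)), rep("medium", 3))
  expect_equal(classify_frequency(c(40.05, 41, 100)), rep("high", 3))
  # every percent maps to exactly one band, monotone in the band order
  set.seed(11)
  pct <- sort(c(runif(500, 0, 100), 0, 5, 40, 100, 4.999, 5.001, 39.999, 40.001))
  bands <- classify_frequency(pct)
  expect_true(all(bands %in% c("low", "medium", "high")))
  expect_true(all(diff(match(bands, c("low", "medium", "high"))) >= 0))
  expect_error(classify_frequency(-1), class = "brscore_invalid_frequency")
  expect_error(classify_frequency(101), class = "brscore_invalid_frequency")
})

test_that("risk terms normalize and resolve through the synonym lexicon", {
  expect_equal(as.character(code_risk_term("Hepatotoxicity")), "hepatotoxicity")
  expect_equal(as.character(code_risk_term("liver toxicity")), "hepatotoxicity")
  expect_equal(as.character(code_risk_term("QT prolongation ")), "qt_prolongation")
  out <- code_risk_term(c("liver toxicity", "spontaneous combustion"))
  expect_equal(attr(out, "mapped"), c(TRUE, FALSE))
  expect_equal(as.character(out)[2], "spontaneous_combustion")
  expect_error(code_risk_term(""), class = "brscore_invalid_term")
  expect_error(code_risk_term("   "), class = "brscore_invalid_term")
  # custom lexicon hook
  lex <- data.frame(verbatim_pattern = "widget_failure", normalized_term = "device_defect")
  expect_equal(as.character(code_risk_term("Widget failure", lex)), "device_defect")
})

test_that("normalization inserts default pharmacovigilance, fills derived fields, and is idempotent", {
  p <- product_profile("P1", "x", 2018, "DNP", benefit = max_benefit(orphan = FALSE),
                       risks = list(
                         risk_entry(risk_item("nausea", ctcae_grade = 4,
                                              frequency_percent = 12)),
                         risk_entry(risk_item("rash", "mild", frequency_band = "low"),
                                    list(mitigation_item("label_warning_precaution")))))
  n1 <- normalize_profile(p)
  # empty mitigation list gains exactly one routine pharmacovigilance item
  expect_length(n1$risks[[1]]$mitigations, 1)
  expect_equal(n1$risks[[1]]$mitigations[[1]]$kind, "routine_pharmacovigilance")
  expect_equal(n1$risks[[1]]$mitigations[[1]]$burden_value, 0L)
  # grade 4 -> severe, 12% -> medium
  expect_equal(n1$risks[[1]]$risk$severity, "severe")
  expect_equal(n1$risks[[1]]$risk$frequency_band, "medium")
  # verbatim provenance preserved
  expect_equal(n1$risks[[1]]$risk$verbatim, "nausea")
  # idempotence
  expect_equal(normalize_profile(n1), n1)
  expect_equal(nrow(validate_profile(n1)), 0)
})

test_that("normalization reconciles orphan designation and rejects contradictory coding", {
  p <- product_profile("P2", "x", 2019, "DHP",
                       benefit = benefit_assessment("severe", "general_population",
                                                    "none_exist", "consistent_substantial",
                                                    orphan_designation = TRUE),
                       risks = list(risk_entry(risk_item("nausea", "mild",
                                                         frequency_band = "low"))))
  expect_warning(n <- normalize_profile(p), "rare_orphan")
  expect_equal(n$benefit$condition_prevalence, "rare_orphan")

  bad <- product_profile("P3", "x", 2019, "DHP", benefit = max_benefit(FALSE),
                         risks = list(risk_entry(risk_item("nausea", "mild",
                                                           ctcae_grade = 5,
                                                           frequency_band = "low"))))
  expect_error(normalize_profile(bad), class = "brscore_consistency_error")
  # the explicit override keeps the declared severity
  ok <- bad
  ok$risks[[1]]$risk$severity_override <- TRUE
  n <- normalize_profile(ok)
  expect_equal(n$risks[[1]]$risk$severity, "mild")

  nonclin <- product_profile("P4", "x", 2019, "DHP", benefit = max_benefit(FALSE),
                             risks = list(risk_entry(risk_item("qt prolongation", "moderate",
                                                               nonclinical_only = TRUE))))
  expect_equal(normalize_profile(nonclin)$risks[[1]]$risk$frequency_band, "low")
})

test_that("validation reports invariant violations as data, not errors", {
  good <- normalize_profile(daaap_like_profile())
  expect_equal(nrow(validate_profile(good)), 0)

  bad_band <- product_profile("P5", "x", 2018, "DOP1", benefit = max_benefit(FALSE),
                              risks = list(risk_entry(risk_item("nausea", "mild",
                                                                frequency_band = "low",
                                                                frequency_percent = 50))))
  rep <- validate_profile(bad_band)
  expect_equal(sum(rep$level == "error"), 1)
  expect_match(rep$message[rep$level == "error"], "banding rule")

  bad_orphan <- product_profile("P6", "x", 2018, "DOP1",
                                benefit = benefit_assessment("severe", "general_population",
                                                             "none_exist", "consistent_substantial",
                                                             orphan_designation = TRUE),
                                risks = list())
  rep <- validate_profile(bad_orphan)
  expect_true(any(grepl("rare_orphan", rep$message)))

  unknown_div <- product_profile("P7", "x", 2018, "DXXX", benefit = max_benefit(FALSE),
                                 risks = list())
  rep <- validate_profile(unknown_div)
  expect_equal(rep$level, "warning")

  dup <- list(good, good)
  rep <- validate_portfolio(dup)
  expect_true(any(rep$message == "duplicated product_id within portfolio"))
})
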