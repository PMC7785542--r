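#' Gross Benefit Score
#'
#' The Gross Benefit Score (GBS) is the raw, pre-deduction value of a
#' product's benefit case: the product of the quantitative equivalents of the
#' four coded benefit parameters (condition severity, condition prevalence,
#' treatment availability, durability of the efficacy evidence), multiplied
#' by the orphan emphasis factor when the product carries an orphan
#' designation, then capped at the configured ceiling. The ceiling prevents
#' an excessive benefit case from overwhelming any amount of risk.
#'
#' @param benefit A [benefit_assessment()].
#' @param config A [default_config()]-style `score_config`.
#' @return Non-negative number, at most `config$gbs_ceiling`.
#' @export
#' @examples
#' b <- benefit_assessment("severe", "rare_orphan", "none_exist",
#'                         "consistent_substantial", orphan_designation = TRUE)
#' score_benefit(b, default_config())  # 5*5*5*5 = 625, x1.25, capped at 100
score_benefit <- function(benefit, config = default_config()) {
  vals <- vapply(names(.monotone_orders), function(param) {
    map <- config$benefit_values[[param]]
    level <- benefit[[param]]
    if (!(level %in% names(map))) {
      stop_brscore(sprintf("no configured value for %s level '%s'", param, level),
                   "brscore_config_error")
    }
    map[[level]]
  }, numeric(1))
  orphan_factor <- if (benefit$orphan_designation) config$orphan_multiplier else 1
  min(config$gbs_ceiling, orphan_factor * prod(vals))
}

#' Risk Score for a single coded risk
#'
#' Risk analysis factors the likelihood of occurrence against the severity
#' of the harm: RS = severity value x frequency value.
#'
#' @param risk A [risk_item()] with severity and frequency band coded.
#' @inheritParams score_benefit
#' @return Non-negative number.
#' @export
#' @examples
#' score_risk(risk_item("hepatotoxicity", "severe", frequency_band = "high"))
score_risk <- function(risk, config = default_config()) {
  if (is.na(risk$severity) || is.na(risk$frequency_band)) {
    stop_brscore(sprintf("risk '%s' is not fully coded (normalize the profile first)",
                         risk$term), "brscore_config_error")
  }
  sv <- config$risk_severity_values
  fv <- config$risk_frequency_values
  if (!(risk$severity %in% names(sv)) || !(risk$frequency_band %in% names(fv))) {
    stop_brscore(sprintf("no configured value for severity '%s' / frequency '%s'",
                         risk$severity, risk$frequency_band), "brscore_config_error")
  }
  sv[[risk$severity]] * fv[[risk$frequency_band]]
}

#' Mitigation scoring for one risk entry
#'
#' Sums the burden values of the mitigation activities attached to a risk
#' (the raw Risk Mitigation Score), then caps the sum so mitigation credit
#' can never exceed the score of the risk it is meant to mitigate, less the
#' residual floor: a mentioned risk always leaves some residual risk unless
#' the review explicitly resolved it (`resolved_no_risk`). Routine
#' pharmacovigilance is valued 0 by construction.
#'
#' @param entry A [risk_entry()].
#' @param rs The entry's Risk Score, from [score_risk()].
#' @inheritParams score_benefit
#' @return List with `rms_raw`, `rms_capped`, `residual`.
#' @export
#' @examples
#' e <- risk_entry(risk_item("x", "severe", frequency_band = "high"),
#'                 list(mitigation_item("rems"),
#'                      mitigation_item("postmarketing_study_registry")))
#' score_mitigations(e, rs = 25)  # raw 9, cap not binding, residual 16
score_mitigations <- function(entry, rs, config = default_config()) {
  mv <- config$mitigation_values
  rms_raw <- 0
  for (m in entry$mitigations) {
    if (!(m$kind %in% names(mv))) {
      stop_brscore(sprintf("no configured value for mitigation kind '%s'", m$kind),
                   "brscore_config_error")
    }
    rms_raw <- rms_raw + if (!is.na(m$burden_value)) m$burden_value else mv[[m$kind]]
  }
  floor_val <- if (entry$risk$resolved_no_risk) 0 else min(config$residual_floor, rs)
  rms_capped <- max(0, min(rms_raw, rs - floor_val))
  list(rms_raw = rms_raw, rms_capped = rms_capped, residual = rs - rms_capped)
}

#' Residual Risk Score
#'
#' The portfolio of a product's risks after mitigation: the sum of per-risk
#' residuals — the risk that may still occur despite all mitigation efforts.
#' Stored as a non-negative magnitude; reports render it with a leading
#' minus sign.
#'
#' @param residuals Numeric vector of per-risk residuals (each >= 0).
#' @return Non-negative number; 0 for an empty vector.
#' @export
residual_risk_score <- function(residuals) {
  if (length(residuals) == 0) return(0)
  if (any(residuals < 0)) stop_brscore("residuals must be non-negative", "brscore_domain_error")
  sum(residuals)
}

#' Net-Benefit Score
#'
#' NBS = GBS - RRS. A positive NBS signals that benefits outweigh the
#' residual risks (the approvability condition); a negative NBS signals the
#' reverse.
#'
#' @param gbs Gross Benefit Score.
#' @param rrs Residual Risk Score magnitude (>= 0).
#' @return Number.
#' @export
#' @examples
#' net_benefit_score(100, 16)  # 84
net_benefit_score <- function(gbs, rrs) {
  if (any(rrs < 0)) stop_brscore("rrs must be non-negative", "brscore_domain_error")
  gbs - rrs
}

#' Sentinel value returned when all residual risk is mitigated away
#' @export
BRR_UNDEFINED <- "undefined_all_risk_mitigated"

#' Benefit-Risk Ratio
#'
#' BRR = GBS / RRS, reported rounded half-up to `decimals` places. Values
#' above 1 are favorable. When RRS is exactly 0 the ratio is undefined; the
#' sentinel string `"undefined_all_risk_mitigated"` is returned with a
#' warning (such products are favorable whenever GBS > 0 but carry no finite
#' ratio).
#'
#' @inheritParams net_benefit_score
#' @param decimals Reporting precision (default from the config convention).
#' @return Number, or the sentinel string when `rrs == 0`.
#' @export
#' @examples
#' benefit_risk_ratio(100, 16)  # 6.25
#' benefit_risk_ratio(100, 31)  # 3.23
benefit_risk_ratio <- function(gbs, rrs, decimals = 2L) {
  if (any(gbs < 0)) stop_brscore("gbs must be non-negative", "brscore_domain_error")
  if (any(rrs < 0)) stop_brscore("rrs must be non-negative", "brscore_domain_error")
  if (rrs == 0) {
    warning("all residual risk mitigated: benefit-risk ratio undefined", call. = FALSE)
    return(BRR_UNDEFINED)
  }
  round_half_up(gbs / rrs, decimals)
}

#' Assign an interpretation band
#'
#' Maps a Net-Benefit Score or Benefit-Risk Ratio onto the coarse
#' interpretation categories negative / marginal_low / medium / high using
#' half-open intervals `(-Inf, t1], (t1, t2], (t2, t3], (t3, Inf)`. With the
#' default thresholds, any non-positive NBS and any BRR <= 1 fall in the
#' `negative` band.
#'
#' @param value Numeric value(s) to band.
#' @param bands List with strictly increasing `thresholds` and one more
#'   `labels` than thresholds.
#' @return Character band label(s).
#' @export
#' @examples
#' categorize(-5, default_config()$nbs_bands)
#' categorize(1.2, default_config()$brr_bands)
categorize <- function(value, bands) {
  if (is.null(bands$thresholds) || is.null(bands$labels) ||
      length(bands$labels) != length(bands$thresholds) + 1L ||
      any(diff(bands$thresholds) <= 0)) {
    stop_brscore("bands need strictly increasing thresholds and k+1 labels",
                 "brscore_config_error")
  }
  bands$labels[findInterval(value, bands$thresholds, left.open = TRUE) + 1L]
}

#' Score a product profile
#'
#' Runs the full scoring pipeline on one product: Gross Benefit Score from
#' the benefit assessment, per-risk Risk Scores and capped Risk Mitigation
#' Scores, Residual Risk Score, Net-Benefit Score, Benefit-Risk Ratio and
#' interpretation bands. The profile is normalized first (idempotent), so
#' grade/percent-coded risks and missing default mitigations are handled.
#'
#' @param profile A [product_profile()].
#' @inheritParams score_benefit
#' @return A `score_breakdown` object: list with `product_id`, `gbs`,
#'   `risks` (data.frame: term, rs, rms_raw, rms_capped, residual), `rrs`,
#'   `rrs_signed`, `nbs`, `brr` (numeric, `NA` when undefined), `brr_status`
#'   (`"ok"` or the sentinel), `nbs_band`, `brr_band`.
#' @export
score_product <- function(profile, config = default_config()) {
  profile <- normalize_profile(profile)
  gbs <- score_benefit(profile$benefit, config)

  n <- length(profile$risks)
  risk_tab <- data.frame(term = character(n), rs = numeric(n), rms_raw = numeric(n),
                         rms_capped = numeric(n), residual = numeric(n),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    entry <- profile$risks[[i]]
    rs <- tryCatch(score_risk(entry$risk, config), error = function(e) {
      stop_brscore(sprintf("product %s, risk %d ('%s'): %s", profile$product_id, i,
                           entry$risk$term, conditionMessage(e)),
                   class(e)[1])
    })
    ms <- score_mitigations(entry, rs, config)
    risk_tab$term[i] <- entry$risk$term
    risk_tab$rs[i] <- rs
    risk_tab$rms_raw[i] <- ms$rms_raw
    risk_tab$rms_capped[i] <- ms$rms_capped
    risk_tab$residual[i] <- ms$residual
  }

  rrs <- residual_risk_score(risk_tab$residual)
  nbs <- net_benefit_score(gbs, rrs)
  if (rrs > 0) {
    brr <- benefit_risk_ratio(gbs, rrs, config$brr_decimals)
    brr_status <- "ok"
    brr_band <- categorize(gbs / rrs, config$brr_bands)
  } else {
    brr <- NA_real_
    brr_status <- BRR_UNDEFINED
    brr_band <- NA_character_
  }

  structure(list(
    product_id = profile$product_id,
    gbs = gbs,
    risks = risk_tab,
    rrs = rrs,
    rrs_signed = -rrs,
    nbs = nbs,
    brr = if (is.character(brr)) NA_real_ else brr,
    brr_status = brr_status,
    nbs_band = categorize(nbs, config$nbs_bands),
    brr_band = brr_band
  ), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  brr_txt <- if (identical(x$brr_status, "ok")) format(x$brr) else x$brr_status
  cat(sprintf("<score_breakdown> %s\n", x$product_id))
  cat(sprintf("  GBS %g | RRS %g (signed %g) | NBS %g (%s) | BRR %s (%s)\n",
              x$gbs, x$rrs, x$rrs_signed, x$nbs, x$nbs_band, brr_txt,
              if (is.na(x$brr_band)) "-" else x$brr_band))
  if (nrow(x$risks) > 0) {
    cat(sprintf("  %d risk(s); residuals: %s\n", nrow(x$risks),
                paste(x$risks$residual, collapse = ", ")))
  }
  invisible(x)
}

#' Score every product in a portfolio
#'
#' @param profiles List of [product_profile()]s.
#' @inheritParams score_benefit
#' @return List of `score_breakdown`s, named by product id.
#' @export
score_portfolio <- function(profiles, config = default_config()) {
  out <- lapply(profiles, score_product, config = config)
  names(out) <- vapply(out, function(b) b$product_id, character(1))
  out
}

#' Tidy one-row-per-product score table
#'
#' @param breakdowns List of `score_breakdown`s (from [score_portfolio()]).
#' @return data.frame with columns `product_id`, `gbs`, `rrs_signed`, `nbs`,
#'   `brr`, `nbs_band`, `brr_band`, `brr_status`, `n_risks`.
#' @export
breakdown_table <- function(breakdowns) {
  do.call(rbind, lapply(breakdowns, function(b) {
    data.frame(product_id = b$product_id, gbs = b$gbs, rrs_signed = b$rrs_signed,
               nbs = b$nbs, brr = b$brr, nbs_band = b$nbs_band,
               brr_band = if (is.na(b$brr_band)) NA_character_ else b$brr_band,
               brr_status = b$brr_status, n_risks = nrow(b$risks),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
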