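#' Default scoring configuration
#'
#' All numeric value tables, caps, floors and band thresholds used by the
#' scoring engine. Every categorical level carries a value on a 5-point
#' scale; the value maps are required to be monotone in the category order
#' (more severe, more frequent, less available, more durable evidence, rarer
#' condition all score at least as high).
#'
#' Defaults: benefit and risk levels map to 1/3/5 (the middle of each
#' 3-level scale gets the middle of the 5-point value range), prevalence to
#' 2/3/5, orphan products get a 1.25 multiplier, the Gross Benefit Score is
#' capped at a ceiling of 100 (a maximal-benefit product hits exactly the
#' cap), each mitigation kind carries a burden value 0-5 ordered by
#' implementation burden, and the residual-risk floor is 1 (a mentioned risk
#' always leaves residual risk unless explicitly resolved). Band thresholds
#' split the Net-Benefit Score at 0/25/60 and the Benefit-Risk Ratio at
#' 1/3/10 into negative, marginal_low, medium and high.
#'
#' @param ... Named overrides for any top-level field.
#' @return A `score_config` object (validated).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$gbs_ceiling
#' default_config(residual_floor = 0)$residual_floor
default_config <- function(...) {
  cfg <- structure(list(
    version = "1.0",
    benefit_values = list(
      condition_severity     = c(mild = 1, moderate = 3, severe = 5),
      condition_prevalence   = c(population_subset = 2, general_population = 3, rare_orphan = 5),
      treatment_availability = c(many_4_plus = 1, some_1_to_3 = 3, none_exist = 5),
      durability             = c(not_consistent = 1, likely_semi_robust = 3,
                                 consistent_substantial = 5)
    ),
    orphan_multiplier = 1.25,
    gbs_ceiling = 100,
    risk_severity_values  = c(mild = 1, moderate = 3, severe = 5),
    risk_frequency_values = c(low = 1, medium = 3, high = 5),
    mitigation_values = c(routine_pharmacovigilance = 0, label_warning_precaution = 1,
                          boxed_warning = 2, monitored_administration = 3,
                          postmarketing_study_registry = 4, rems = 5),
    residual_floor = 1,
    nbs_bands = list(thresholds = c(0, 25, 60),
                     labels = c("negative", "marginal_low", "medium", "high")),
    brr_bands = list(thresholds = c(1, 3, 10),
                     labels = c("negative", "marginal_low", "medium", "high")),
    brr_decimals = 2L
  ), class = "score_config")
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) > 0) {
      stop_brscore(paste("unknown config field:", paste(bad, collapse = ", ")),
                   "brscore_config_error")
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  cfg
}

# category orders in which each value map must be non-decreasing
.monotone_orders <- list(
  condition_severity = SEVERITY_LEVELS,
  condition_prevalence = PREVALENCE_LEVELS,
  treatment_availability = AVAILABILITY_LEVELS,
  durability = DURABILITY_LEVELS
)

#' Validate a scoring configuration
#'
#' Checks structural completeness, monotonicity of every value map in its
#' category order, the zero value for routine pharmacovigilance, and strictly
#' increasing band thresholds. Errors with class `brscore_config_error`.
#'
#' @param config A `score_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(msg) stop_brscore(msg, "brscore_config_error")
  need <- c("benefit_values", "orphan_multiplier", "gbs_ceiling",
            "risk_severity_values", "risk_frequency_values", "mitigation_values",
            "residual_floor", "nbs_bands", "brr_bands", "brr_decimals")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) fail(paste("config missing field(s):", paste(missing, collapse = ", ")))

  for (param in names(.monotone_orders)) {
    vals <- config$benefit_values[[param]]
    ord <- .monotone_orders[[param]]
    if (is.null(vals) || !all(ord %in% names(vals))) {
      fail(sprintf("benefit_values$%s must cover levels {%s}", param, paste(ord, collapse = ", ")))
    }
    if (any(vals < 0)) fail(sprintf("benefit_values$%s must be non-negative", param))
    if (is.unsorted(vals[ord])) {
      fail(sprintf("benefit_values$%s must be monotone over %s", param, paste(ord, collapse = " <= ")))
    }
  }
  if (!is_num1(config$orphan_multiplier) || config$orphan_multiplier < 1) {
    fail("orphan_multiplier must be a number >= 1")
  }
  if (!is_num1(config$gbs_ceiling) || config$gbs_ceiling <= 0) fail("gbs_ceiling must be positive")

  for (nm in c("risk_severity_values", "risk_frequency_values")) {
    vals <- config[[nm]]
    ord <- if (nm == "risk_severity_values") SEVERITY_LEVELS else FREQUENCY_LEVELS
    if (!all(ord %in% names(vals))) fail(sprintf("%s must cover {%s}", nm, paste(ord, collapse = ", ")))
    if (any(vals < 0)) fail(sprintf("%s must be non-negative", nm))
    if (is.unsorted(vals[ord])) fail(sprintf("%s must be monotone over %s", nm, paste(ord, collapse = " <= ")))
  }
  mv <- config$mitigation_values
  if (!all(MITIGATION_KINDS %in% names(mv))) {
    fail(paste("mitigation_values must cover", paste(MITIGATION_KINDS, collapse = ", ")))
  }
  if (mv[["routine_pharmacovigilance"]] != 0) fail("routine pharmacovigilance must be valued 0")
  if (any(mv < 0 | mv > 5)) fail("mitigation values must lie in 0..5")
  if (!is_num1(config$residual_floor) || config$residual_floor < 0) {
    fail("residual_floor must be non-negative")
  }
  for (nm in c("nbs_bands", "brr_bands")) {
    b <- config[[nm]]
    if (is.null(b$thresholds) || is.null(b$labels) ||
        length(b$labels) != length(b$thresholds) + 1L) {
      fail(sprintf("%s needs k thresholds and k+1 labels", nm))
    }
    if (any(diff(b$thresholds) <= 0)) fail(sprintf("%s thresholds must be strictly increasing", nm))
  }
  if (!is.numeric(config$brr_decimals) || config$brr_decimals < 0) {
    fail("brr_decimals must be a non-negative integer")
  }
  invisible(config)
}

#' Read / write a scoring configuration
#'
#' Configurations are stored as YAML (or JSON) documents mirroring the
#' structure of [default_config()]; a canonical, version-stamped
#' `default_config.yaml` ships with the package under `extdata`.
#'
#' @param path File path; format inferred from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `read_config()`: a validated `score_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  for (nm in intersect(names(raw), names(cfg))) {
    val <- raw[[nm]]
    if (nm %in% c("risk_severity_values", "risk_frequency_values", "mitigation_values")) {
      val <- unlist(val)
    } else if (nm == "benefit_values") {
      val <- lapply(val, unlist)
    } else if (nm %in% c("nbs_bands", "brr_bands")) {
      val <- list(thresholds = as.numeric(unlist(val$thresholds)),
                  labels = as.character(unlist(val$labels)))
    }
    cfg[[nm]] <- val
  }
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config A `score_config` to serialize.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$benefit_values <- lapply(x$benefit_values, as.list)
  x$risk_severity_values <- as.list(x$risk_severity_values)
  x$risk_frequency_values <- as.list(x$risk_frequency_values)
  x$mitigation_values <- as.list(x$mitigation_values)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.score_config <- function(x, ...) {
  cat(sprintf("<score_config v%s> ceiling %g, orphan x%g, floor %g\n",
              x$version, x$gbs_ceiling, x$orphan_multiplier, x$residual_floor))
  cat("  benefit values:\n")
  for (nm in names(x$benefit_values)) {
    v <- x$benefit_values[[nm]]
    cat(sprintf("    %-22s %s\n", nm, paste(sprintf("%s=%g", names(v), v), collapse = " ")))
  }
  cat(sprintf("  risk: severity %s | frequency %s\n",
              paste(x$risk_severity_values, collapse = "/"),
              paste(x$risk_frequency_values, collapse = "/")))
  invisible(x)
}
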