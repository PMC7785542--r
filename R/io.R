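PROFILE_SCHEMA_VERSION <- "1.0"

# ---- profile <-> plain list (JSON shape) -----------------------------------

profile_to_list <- function(p) {
  ben <- p$benefit
  list(
    product_id = p$product_id, name = p$name, approval_year = p$approval_year,
    review_division = p$review_division,
    designations = as.list(p$designations),
    indication = p$indication,
    benefit = list(
      condition_severity = ben$condition_severity,
      condition_prevalence = ben$condition_prevalence,
      treatment_availability = ben$treatment_availability,
      durability = ben$durability,
      orphan_designation = ben$orphan_designation,
      verbatim = if (is.null(ben$verbatim)) NULL else as.list(ben$verbatim)
    ),
    risks = lapply(p$risks, function(e) {
      r <- e$risk
      list(
        risk = list(term = r$term, severity = r$severity, ctcae_grade = r$ctcae_grade,
                    frequency_band = r$frequency_band,
                    frequency_percent = r$frequency_percent,
                    nonclinical_only = r$nonclinical_only,
                    resolved_no_risk = r$resolved_no_risk,
                    severity_override = r$severity_override, verbatim = r$verbatim),
        mitigations = lapply(e$mitigations, function(m) {
          list(kind = m$kind, burden_value = m$burden_value, verbatim = m$verbatim)
        })
      )
    })
  )
}

list_to_profile <- function(x, where = "") {
  need <- c("product_id", "name", "approval_year", "review_division", "benefit", "risks")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop_brscore(sprintf("%s: missing field(s) %s", where, paste(missing, collapse = ", ")),
                 "brscore_parse_error")
  }
  b <- x$benefit
  verb <- if (is.null(b$verbatim)) NULL else unlist(b$verbatim)
  benefit <- benefit_assessment(b$condition_severity, b$condition_prevalence,
                                b$treatment_availability, b$durability,
                                isTRUE(b$orphan_designation), verbatim = verb)
  risks <- lapply(x$risks, function(e) {
    r <- e$risk
    risk_entry(
      risk_item(term = r$term,
                severity = r$severity %||% NA_character_,
                ctcae_grade = r$ctcae_grade %||% NA_integer_,
                frequency_band = r$frequency_band %||% NA_character_,
                frequency_percent = r$frequency_percent %||% NA_real_,
                nonclinical_only = isTRUE(r$nonclinical_only),
                resolved_no_risk = isTRUE(r$resolved_no_risk),
                severity_override = isTRUE(r$severity_override),
                verbatim = r$verbatim %||% NA_character_),
      mitigations = lapply(e$mitigations, function(m) {
        mitigation_item(m$kind, m$burden_value %||% NA_integer_,
                        m$verbatim %||% NA_character_)
      })
    )
  })
  product_profile(x$product_id, x$name, x$approval_year, x$review_division,
                  benefit = benefit, risks = risks,
                  designations = as.character(unlist(x$designations)),
                  indication = x$indication %||% NA_character_)
}

# ---- JSON / CSV readers and writers ----------------------------------------

#' Read and write product profiles
#'
#' Two on-disk representations of a portfolio:
#' \describe{
#'   \item{JSON}{a versioned document `{schema_version, profiles: [...]}`
#'     with field names exactly matching the profile constructors;}
#'   \item{CSV}{a flat UTF-8, RFC-4180 table with one row per
#'     (product, risk, mitigation) and the product/benefit columns repeated
#'     on every row.}
#' }
#' `write_profiles()` then `read_profiles()` is the identity on normalized
#' profiles. Schema violations are reported with record locators; unknown
#' division codes pass through with a warning; an empty file yields an empty
#' portfolio with a warning.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; inferred from the extension when
#'   missing.
#' @return `read_profiles()`: list of [product_profile()]s.
#' @export
read_profiles <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) stop_brscore(paste("no such file:", path), "brscore_parse_error")
  if (file.size(path) == 0 || all(!nzchar(trimws(readLines(path, warn = FALSE))))) {
    warning("empty profile file: returning an empty portfolio", call. = FALSE)
    return(list())
  }
  profiles <- if (format == "json") read_profiles_json(path) else read_profiles_csv(path)
  unknown <- setdiff(vapply(profiles, function(p) p$review_division, character(1)),
                     division_codes())
  if (length(unknown) > 0) {
    warning(paste("division code(s) outside the controlled vocabulary:",
                  paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  profiles
}

read_profiles_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_brscore(
                    sprintf("%s: not valid JSON (%s)", path, conditionMessage(e)),
                    "brscore_parse_error"))
  if (is.null(doc$schema_version)) {
    stop_brscore(sprintf("%s: missing schema_version", path), "brscore_parse_error")
  }
  if (!identical(doc$schema_version, PROFILE_SCHEMA_VERSION)) {
    stop_brscore(sprintf("%s: unsupported schema version '%s' (supported: %s)",
                         path, doc$schema_version, PROFILE_SCHEMA_VERSION),
                 "brscore_version_error")
  }
  lapply(seq_along(doc$profiles), function(i) {
    list_to_profile(doc$profiles[[i]], where = sprintf("%s: profiles[%d]", path, i))
  })
}

#' @rdname read_profiles
#' @param profiles List of [product_profile()]s.
#' @export
write_profiles <- function(profiles, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    doc <- list(schema_version = PROFILE_SCHEMA_VERSION,
                profiles = lapply(profiles, profile_to_list))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  } else {
    utils::write.csv(profiles_to_flat(profiles), path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

# one row per (product, risk, mitigation); risk-less products get one row of NAs
profiles_to_flat <- function(profiles) {
  rows <- list()
  for (p in profiles) {
    ben <- p$benefit
    base <- data.frame(
      product_id = p$product_id, name = p$name, approval_year = p$approval_year,
      review_division = p$review_division,
      designations = paste(p$designations, collapse = ";"),
      indication = p$indication,
      condition_severity = ben$condition_severity,
      condition_prevalence = ben$condition_prevalence,
      treatment_availability = ben$treatment_availability,
      durability = ben$durability,
      orphan_designation = ben$orphan_designation,
      stringsAsFactors = FALSE
    )
    emit <- function(ri, r, mi, m) {
      rows[[length(rows) + 1L]] <<- cbind(base, data.frame(
        risk_index = ri,
        risk_term = if (is.null(r)) NA_character_ else r$term,
        risk_severity = if (is.null(r)) NA_character_ else r$severity,
        risk_ctcae_grade = if (is.null(r)) NA_integer_ else r$ctcae_grade,
        risk_frequency_band = if (is.null(r)) NA_character_ else r$frequency_band,
        risk_frequency_percent = if (is.null(r)) NA_real_ else r$frequency_percent,
        risk_nonclinical_only = if (is.null(r)) NA else r$nonclinical_only,
        risk_resolved_no_risk = if (is.null(r)) NA else r$resolved_no_risk,
        risk_severity_override = if (is.null(r)) NA else r$severity_override,
        risk_verbatim = if (is.null(r)) NA_character_ else r$verbatim,
        mitigation_index = mi,
        mitigation_kind = if (is.null(m)) NA_character_ else m$kind,
        mitigation_burden = if (is.null(m)) NA_integer_ else m$burden_value,
        mitigation_verbatim = if (is.null(m)) NA_character_ else m$verbatim,
        stringsAsFactors = FALSE
      ))
    }
    if (length(p$risks) == 0) {
      emit(NA_integer_, NULL, NA_integer_, NULL)
    } else {
      for (i in seq_along(p$risks)) {
        e <- p$risks[[i]]
        if (length(e$mitigations) == 0) {
          emit(i, e$risk, NA_integer_, NULL)
        } else {
          for (j in seq_along(e$mitigations)) emit(i, e$risk, j, e$mitigations[[j]])
        }
      }
    }
  }
  do.call(rbind, rows)
}

read_profiles_csv <- function(path) {
  flat <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                                   na.strings = ""),
                   error = function(e) stop_brscore(
                     sprintf("%s: not valid CSV (%s)", path, conditionMessage(e)),
                     "brscore_parse_error"))
  need <- c("product_id", "condition_severity", "condition_prevalence",
            "treatment_availability", "durability", "orphan_designation")
  missing <- setdiff(need, names(flat))
  if (length(missing) > 0) {
    stop_brscore(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")),
                 "brscore_parse_error")
  }
  lapply(unique(flat$product_id), function(id) {
    g <- flat[flat$product_id == id, , drop = FALSE]
    h <- g[1, ]
    desigs <- if (is.na(h$designations) || !nzchar(h$designations)) character() else
      strsplit(h$designations, ";", fixed = TRUE)[[1]]
    benefit <- benefit_assessment(h$condition_severity, h$condition_prevalence,
                                  h$treatment_availability, h$durability,
                                  isTRUE(h$orphan_designation))
    risk_idx <- sort(unique(g$risk_index[!is.na(g$risk_index)]))
    risks <- lapply(risk_idx, function(i) {
      gr <- g[!is.na(g$risk_index) & g$risk_index == i, , drop = FALSE]
      r1 <- gr[1, ]
      mit_rows <- gr[!is.na(gr$mitigation_index), , drop = FALSE]
      mit_rows <- mit_rows[order(mit_rows$mitigation_index), , drop = FALSE]
      risk_entry(
        risk_item(term = r1$risk_term,
                  severity = r1$risk_severity %||% NA_character_,
                  ctcae_grade = r1$risk_ctcae_grade,
                  frequency_band = r1$risk_frequency_band,
                  frequency_percent = r1$risk_frequency_percent,
                  nonclinical_only = isTRUE(r1$risk_nonclinical_only),
                  resolved_no_risk = isTRUE(r1$risk_resolved_no_risk),
                  severity_override = isTRUE(r1$risk_severity_override),
                  verbatim = r1$risk_verbatim),
        mitigations = lapply(seq_len(nrow(mit_rows)), function(j) {
          mitigation_item(mit_rows$mitigation_kind[j], mit_rows$mitigation_burden[j],
                          mit_rows$mitigation_verbatim[j])
        })
      )
    })
    product_profile(id, h$name, h$approval_year, h$review_division,
                    benefit = benefit, risks = risks, designations = desigs,
                    indication = h$indication %||% NA_character_)
  })
}

#' Write per-product score breakdowns
#'
#' CSV: one row per product (`product_id`, `gbs`, `rrs_signed`, `nbs`,
#' `brr`, bands). JSON: the full per-risk breakdowns.
#'
#' @param breakdowns List of `score_breakdown`s.
#' @param path Output path (`.csv` or `.json`).
#' @export
write_breakdowns <- function(breakdowns, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(breakdowns, unclass), path, auto_unbox = TRUE,
                         digits = NA, na = "null", dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(breakdown_table(breakdowns), path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}
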