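#' Coded categorical levels of the benefit-risk model
#'
#' The benefit-risk table of an FDA product review is codified onto fixed
#' three-level categorical scales. These constants define the level sets and
#' their order (worst-for-benefit / least-for-risk first), which the scoring
#' configuration must respect monotonically.
#'
#' @name br-levels
#' @keywords internal
NULL

SEVERITY_LEVELS     <- c("mild", "moderate", "severe")
PREVALENCE_LEVELS   <- c("population_subset", "general_population", "rare_orphan")
AVAILABILITY_LEVELS <- c("many_4_plus", "some_1_to_3", "none_exist")
DURABILITY_LEVELS   <- c("not_consistent", "likely_semi_robust", "consistent_substantial")
FREQUENCY_LEVELS    <- c("low", "medium", "high")
MITIGATION_KINDS    <- c("routine_pharmacovigilance", "label_warning_precaution",
                         "boxed_warning", "monitored_administration",
                         "postmarketing_study_registry", "rems")
DESIGNATION_FLAGS   <- c("orphan", "fast_track", "priority", "accelerated", "breakthrough")

#' Default controlled vocabulary of FDA review division codes
#'
#' The seventeen drug review division codes used in the division-level summary
#' of the 2015-2019 novel-approval portfolio. The vocabulary is configurable:
#' [validate_profile()] accepts any vector of codes via its `divisions`
#' argument; unknown codes raise a warning, not an error.
#'
#' @return Character vector of division codes.
#' @export
#' @examples
#' division_codes()
division_codes <- function() {
  c("DAAAP", "DAIP", "DAVP", "DBRUP", "DCaRP", "DDDP", "DGIEP", "DHOT",
    "DHP", "DMIP", "DMEP", "DNP", "DOP1", "DOP2", "DPP", "DPARP", "DTOP")
}

#' Map a CTCAE grade to a coded severity level
#'
#' Adverse-event severity is coded on a three-level scale anchored to CTCAE
#' grades: grades 1-2 are mild (reversible, brief), grade 3 moderate
#' (potential lasting effect), grades 4-5 severe (life-threatening or death).
#'
#' @param grade Integer CTCAE grade in 1..5 (vectorised).
#' @return Character vector of severity levels.
#' @export
#' @examples
#' classify_severity_from_grade(1:5)
classify_severity_from_grade <- function(grade) {
  if (length(grade) == 0 || anyNA(grade) || !is.numeric(grade) ||
      any(grade != as.integer(grade)) || any(grade < 1) || any(grade > 5)) {
    stop_brscore("CTCAE grade must be an integer in 1..5", "brscore_invalid_grade")
  }
  c("mild", "mild", "moderate", "severe", "severe")[as.integer(grade)]
}

#' Map an observed event frequency to a coded frequency band
#'
#' Frequencies are banded as low (0-5%), medium (>5-40%) and high (>40-100%).
#' The bands are half-open on the left so that every real-valued percentage
#' in \[0, 100\] falls in exactly one band.
#'
#' @param percent Numeric percentage in \[0, 100\] (vectorised).
#' @return Character vector of frequency bands.
#' @export
#' @examples
#' classify_frequency(c(3, 20, 41))
classify_frequency <- function(percent) {
  if (length(percent) == 0 || anyNA(percent) || !is.numeric(percent) ||
      any(percent < 0) || any(percent > 100)) {
    stop_brscore("frequency percent must be in [0, 100]", "brscore_invalid_frequency")
  }
  FREQUENCY_LEVELS[findInterval(percent, c(5, 40), left.open = TRUE) + 1L]
}

#' Normalize a verbatim risk description to a lexicon term
#'
#' Lowercases, trims and collapses whitespace, replaces punctuation with
#' underscores, then looks the result up in a synonym lexicon (see
#' [default_lexicon()]). Terms absent from the lexicon pass through in
#' normalized form and are flagged via the `mapped` attribute.
#'
#' @param verbatim Non-empty character string (vectorised).
#' @param lexicon Two-column data.frame (`verbatim_pattern`, `normalized_term`);
#'   defaults to the built-in lexicon. Supply your own (e.g. a MedDRA-derived
#'   table read with [read_lexicon()]) to widen coverage.
#' @return Character vector of normalized terms, with a logical `mapped`
#'   attribute marking terms found in the lexicon.
#' @export
#' @examples
#' code_risk_term(c("Hepatotoxicity", "liver toxicity", "QT prolongation "))
code_risk_term <- function(verbatim, lexicon = default_lexicon()) {
  if (length(verbatim) == 0 || !is.character(verbatim) || anyNA(verbatim) ||
      any(!nzchar(trimws(verbatim)))) {
    stop_brscore("risk term must be non-empty text", "brscore_invalid_term")
  }
  norm <- tolower(trimws(verbatim))
  norm <- gsub("[^a-z0-9]+", "_", norm)
  norm <- gsub("^_+|_+$", "", norm)
  idx <- match(norm, lexicon$verbatim_pattern)
  out <- ifelse(is.na(idx), norm, lexicon$normalized_term[idx])
  # a term that already IS a normalized lexicon target counts as mapped
  mapped <- !is.na(idx) | out %in% lexicon$normalized_term
  attr(out, "mapped") <- mapped
  out
}

#' Built-in risk-term synonym lexicon
#'
#' A small versioned synonym table mapping common verbatim adverse-event
#' phrasings to canonical terms. It is deliberately minimal: production use
#' should supply a dictionary-derived lexicon through the `lexicon` argument
#' of [code_risk_term()] or a file via [read_lexicon()].
#'
#' @return data.frame with columns `verbatim_pattern`, `normalized_term`.
#' @export
default_lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "lexicon.csv", package = "brscore")
      cache <<- read_lexicon(path)
    }
    cache
  }
})

#' Read a lexicon CSV
#'
#' @param path UTF-8 CSV with columns `verbatim_pattern`, `normalized_term`.
#' @return data.frame lexicon.
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("verbatim_pattern", "normalized_term") %in% names(lex))) {
    stop_brscore("lexicon must have columns verbatim_pattern, normalized_term",
                 "brscore_parse_error")
  }
  lex
}

# ---- constructors ----------------------------------------------------------

#' Construct a benefit assessment
#'
#' The four benefit parameters of the coded benefit-risk table: severity and
#' prevalence of the condition, availability of alternative treatments, and
#' durability (robustness) of the efficacy evidence, plus the orphan
#' designation flag. An orphan designation forces prevalence to `rare_orphan`
#' (the formal regulatory designation wins over ad-hoc coding).
#'
#' @param condition_severity One of `mild`, `moderate`, `severe`.
#' @param condition_prevalence One of `general_population`, `rare_orphan`,
#'   `population_subset`.
#' @param treatment_availability One of `none_exist`, `some_1_to_3`,
#'   `many_4_plus`.
#' @param durability One of `consistent_substantial`, `likely_semi_robust`,
#'   `not_consistent`.
#' @param orphan_designation Logical flag.
#' @param verbatim Optional named character vector preserving the source text
#'   for each parameter (provenance record).
#' @return A `benefit_assessment` object.
#' @export
#' @examples
#' benefit_assessment("severe", "rare_orphan", "none_exist",
#'                    "consistent_substantial", orphan_designation = TRUE)
benefit_assessment <- function(condition_severity, condition_prevalence,
                               treatment_availability, durability,
                               orphan_designation = FALSE, verbatim = NULL) {
  structure(list(
    condition_severity = as.character(condition_severity),
    condition_prevalence = as.character(condition_prevalence),
    treatment_availability = as.character(treatment_availability),
    durability = as.character(durability),
    orphan_designation = isTRUE(orphan_designation),
    verbatim = verbatim
  ), class = "benefit_assessment")
}

#' Construct a coded risk item
#'
#' One adverse-event risk coded by severity and frequency. Severity may be
#' given directly or derived from a CTCAE grade; the frequency band may be
#' given directly or derived from an observed percentage.
#' [normalize_profile()] fills the derived fields and checks consistency.
#'
#' @param term Risk term (verbatim or already normalized); normalized through
#'   the lexicon during profile normalization.
#' @param severity `mild`/`moderate`/`severe`, or `NA` to derive from grade.
#' @param ctcae_grade Optional integer 1-5.
#' @param frequency_band `low`/`medium`/`high`, or `NA` to derive from percent.
#' @param frequency_percent Optional numeric in \[0, 100\].
#' @param nonclinical_only Signal seen only in non-clinical studies; forces
#'   the frequency band to `low` (the risk exists but was not demonstrated in
#'   humans).
#' @param resolved_no_risk The review explicitly concluded no residual risk;
#'   removes the residual-risk floor in scoring.
#' @param severity_override Set `TRUE` to keep a declared severity that
#'   disagrees with the grade mapping (explicit, reproducible override in
#'   place of text heuristics).
#' @param verbatim Optional source text.
#' @return A `risk_item` object.
#' @export
risk_item <- function(term, severity = NA_character_, ctcae_grade = NA_integer_,
                      frequency_band = NA_character_,
                      frequency_percent = NA_real_,
                      nonclinical_only = FALSE, resolved_no_risk = FALSE,
                      severity_override = FALSE, verbatim = NA_character_) {
  structure(list(
    term = as.character(term),
    severity = as.character(severity),
    ctcae_grade = as.integer(ctcae_grade),
    frequency_band = as.character(frequency_band),
    frequency_percent = as.numeric(frequency_percent),
    nonclinical_only = isTRUE(nonclinical_only),
    resolved_no_risk = isTRUE(resolved_no_risk),
    severity_override = isTRUE(severity_override),
    verbatim = as.character(verbatim)
  ), class = "risk_item")
}

#' Construct a risk mitigation item
#'
#' A mitigation activity attached to a risk, coded by kind. Each kind carries
#' a public-health implementation burden value (0-5) resolved from the
#' scoring configuration; routine pharmacovigilance is always worth 0 because
#' every sponsor is obliged to perform it.
#'
#' @param kind One of `routine_pharmacovigilance`, `label_warning_precaution`,
#'   `boxed_warning`, `monitored_administration`,
#'   `postmarketing_study_registry`, `rems`.
#' @param burden_value Optional integer 0-5 overriding the configured value
#'   (forced to 0 for routine pharmacovigilance).
#' @param verbatim Optional source text.
#' @return A `mitigation_item` object.
#' @export
mitigation_item <- function(kind, burden_value = NA_integer_, verbatim = NA_character_) {
  kind <- as.character(kind)
  bv <- as.integer(burden_value)
  if (identical(kind, "routine_pharmacovigilance")) bv <- 0L
  structure(list(kind = kind, burden_value = bv, verbatim = as.character(verbatim)),
            class = "mitigation_item")
}

#' Construct a risk entry (risk plus its mitigations)
#'
#' @param risk A [risk_item()].
#' @param mitigations List of [mitigation_item()]s; may be empty before
#'   normalization, after which routine pharmacovigilance is inserted as the
#'   default.
#' @return A `risk_entry` object.
#' @export
risk_entry <- function(risk, mitigations = list()) {
  stopifnot(inherits(risk, "risk_item"))
  structure(list(risk = risk, mitigations = mitigations), class = "risk_entry")
}

#' Construct a product profile
#'
#' A product's full coded benefit-risk table content plus review metadata.
#'
#' @param product_id Unique identifier within a portfolio.
#' @param name Product name.
#' @param approval_year Integer year.
#' @param review_division Division code (see [division_codes()]); unknown
#'   codes are allowed with a validation warning.
#' @param benefit A [benefit_assessment()].
#' @param risks List of [risk_entry()]s.
#' @param designations Character subset of
#'   `orphan`, `fast_track`, `priority`, `accelerated`, `breakthrough`.
#' @param indication Optional indication label (used by [scatter_data()]).
#' @return A `product_profile` object.
#' @export
product_profile <- function(product_id, name, approval_year, review_division,
                            benefit, risks = list(), designations = character(),
                            indication = NA_character_) {
  stopifnot(inherits(benefit, "benefit_assessment"))
  structure(list(
    product_id = as.character(product_id),
    name = as.character(name),
    approval_year = as.integer(approval_year),
    review_division = as.character(review_division),
    designations = as.character(designations),
    indication = as.character(indication),
    benefit = benefit,
    risks = risks
  ), class = "product_profile")
}

#' @export
print.product_profile <- function(x, ...) {
  cat(sprintf("<product_profile> %s (%s, %s, %d)\n", x$product_id, x$name,
              x$review_division, x$approval_year))
  cat(sprintf("  benefit: %s / %s / %s / %s%s\n",
              x$benefit$condition_severity, x$benefit$condition_prevalence,
              x$benefit$treatment_availability, x$benefit$durability,
              if (x$benefit$orphan_designation) " [orphan]" else ""))
  cat(sprintf("  risks: %d\n", length(x$risks)))
  invisible(x)
}

# ---- normalization ---------------------------------------------------------

#' Normalize a product profile
#'
#' Applies the default-coding rules so that a profile is ready for scoring:
#' \itemize{
#'   \item risks with no documented mitigation gain a routine
#'     pharmacovigilance item (burden 0) -- the baseline regulatory
#'     requirement every sponsor must meet;
#'   \item severity is filled from the CTCAE grade and the frequency band
#'     from the observed percentage where those source values are present;
#'   \item non-clinical-only signals get frequency band `low`;
#'   \item an orphan designation forces prevalence to `rare_orphan`
#'     (with a warning when it changes the coded value);
#'   \item risk terms are normalized through the lexicon
#'     (verbatim text is preserved).
#' }
#' Normalization is idempotent and never removes information. Declared values
#' that contradict their source fields (e.g. grade 5 coded `mild` without
#' `severity_override`) raise a consistency error listing every violation.
#'
#' @param profile A [product_profile()].
#' @param lexicon Synonym table for term normalization.
#' @return The normalized `product_profile`.
#' @export
normalize_profile <- function(profile, lexicon = default_lexicon()) {
  stopifnot(inherits(profile, "product_profile"))
  problems <- character()

  ben <- profile$benefit
  if ((ben$orphan_designation || "orphan" %in% profile$designations) &&
      !identical(ben$condition_prevalence, "rare_orphan")) {
    warning(sprintf("profile %s: orphan designation forces prevalence to rare_orphan",
                    profile$product_id), call. = FALSE)
    ben$condition_prevalence <- "rare_orphan"
  }
  if ("orphan" %in% profile$designations) ben$orphan_designation <- TRUE
  if (ben$orphan_designation && !("orphan" %in% profile$designations)) {
    profile$designations <- union(profile$designations, "orphan")
  }
  profile$benefit <- ben

  profile$risks <- lapply(profile$risks, function(entry) {
    r <- entry$risk
    if (!is.na(r$ctcae_grade)) {
      derived <- classify_severity_from_grade(r$ctcae_grade)
      if (is.na(r$severity)) {
        r$severity <- derived
      } else if (!identical(r$severity, derived) && !r$severity_override) {
        problems <<- c(problems, sprintf(
          "risk '%s': declared severity '%s' contradicts CTCAE grade %d ('%s') without severity_override",
          r$term, r$severity, r$ctcae_grade, derived))
      }
    }
    if (r$nonclinical_only) {
      if (is.na(r$frequency_band)) r$frequency_band <- "low"
      else if (!identical(r$frequency_band, "low")) {
        problems <<- c(problems, sprintf(
          "risk '%s': nonclinical_only requires frequency band 'low', got '%s'",
          r$term, r$frequency_band))
      }
    } else if (!is.na(r$frequency_percent)) {
      derived <- classify_frequency(r$frequency_percent)
      if (is.na(r$frequency_band)) {
        r$frequency_band <- derived
      } else if (!identical(r$frequency_band, derived)) {
        problems <<- c(problems, sprintf(
          "risk '%s': declared frequency band '%s' contradicts %.3g%% ('%s')",
          r$term, r$frequency_band, r$frequency_percent, derived))
      }
    }
    if (is.na(r$verbatim)) r$verbatim <- r$term
    coded <- code_risk_term(r$verbatim, lexicon)
    r$term <- as.character(coded)
    if (length(entry$mitigations) == 0) {
      entry$mitigations <- list(mitigation_item("routine_pharmacovigilance"))
    }
    entry$risk <- r
    entry
  })

  if (length(problems) > 0) {
    stop_brscore(paste0("inconsistent coding in profile ", profile$product_id, ":\n  ",
                        paste(problems, collapse = "\n  ")),
                 "brscore_consistency_error", violations = problems)
  }
  profile
}

# ---- validation ------------------------------------------------------------

#' Validate a product profile against the coding invariants
#'
#' Checks every type invariant of the coded model and returns the violations
#' as data (a data.frame), not as an error: an empty report means the profile
#' passes. Unknown division codes produce a `warning`-level row; everything
#' else is `error`-level.
#'
#' @param profile A [product_profile()].
#' @param divisions Controlled vocabulary of division codes.
#' @return data.frame with columns `level`, `field`, `message`; zero rows if
#'   the profile is fully consistent.
#' @export
validate_profile <- function(profile, divisions = division_codes()) {
  out <- list()
  add <- function(level, field, message) {
    out[[length(out) + 1L]] <<- data.frame(level = level, field = field,
                                           message = message, stringsAsFactors = FALSE)
  }
  if (!inherits(profile, "product_profile")) {
    add("error", "profile", "not a product_profile object")
    return(do.call(rbind, out))
  }
  if (!is_scalar_chr(profile$product_id) || !nzchar(profile$product_id)) {
    add("error", "product_id", "product_id must be a non-empty string")
  }
  if (!(profile$review_division %in% divisions)) {
    add("warning", "review_division",
        sprintf("division code '%s' not in the controlled vocabulary", profile$review_division))
  }
  bad_flags <- setdiff(profile$designations, DESIGNATION_FLAGS)
  if (length(bad_flags) > 0) {
    add("error", "designations", paste("unknown designation flag:", paste(bad_flags, collapse = ", ")))
  }

  ben <- profile$benefit
  chk_level <- function(value, levels, field) {
    if (!(length(value) == 1L && value %in% levels)) {
      add("error", field, sprintf("'%s' is not one of {%s}", value, paste(levels, collapse = ", ")))
    }
  }
  chk_level(ben$condition_severity, SEVERITY_LEVELS, "condition_severity")
  chk_level(ben$condition_prevalence, PREVALENCE_LEVELS, "condition_prevalence")
  chk_level(ben$treatment_availability, AVAILABILITY_LEVELS, "treatment_availability")
  chk_level(ben$durability, DURABILITY_LEVELS, "durability")
  if (ben$orphan_designation && !identical(ben$condition_prevalence, "rare_orphan")) {
    add("error", "condition_prevalence",
        "orphan_designation = TRUE requires condition_prevalence = rare_orphan")
  }

  for (i in seq_along(profile$risks)) {
    entry <- profile$risks[[i]]
    r <- entry$risk
    fld <- function(f) sprintf("risks[%d].%s", i, f)
    if (!is.na(r$severity)) chk_level(r$severity, SEVERITY_LEVELS, fld("severity"))
    if (!is.na(r$frequency_band)) chk_level(r$frequency_band, FREQUENCY_LEVELS, fld("frequency_band"))
    if (is.na(r$severity) && is.na(r$ctcae_grade)) {
      add("error", fld("severity"), "risk needs a severity or a CTCAE grade")
    }
    if (is.na(r$frequency_band) && is.na(r$frequency_percent) && !r$nonclinical_only) {
      add("error", fld("frequency_band"), "risk needs a frequency band or percent")
    }
    if (!is.na(r$ctcae_grade)) {
      if (!(r$ctcae_grade %in% 1:5)) {
        add("error", fld("ctcae_grade"), sprintf("grade %s outside 1..5", r$ctcae_grade))
      } else if (!is.na(r$severity) && !r$severity_override &&
                 !identical(r$severity, classify_severity_from_grade(r$ctcae_grade))) {
        add("error", fld("severity"),
            sprintf("severity '%s' contradicts the grade-%d mapping '%s'",
                    r$severity, r$ctcae_grade, classify_severity_from_grade(r$ctcae_grade)))
      }
    }
    if (!is.na(r$frequency_percent)) {
      if (r$frequency_percent < 0 || r$frequency_percent > 100) {
        add("error", fld("frequency_percent"), "frequency percent outside [0, 100]")
      } else if (!is.na(r$frequency_band) && !r$nonclinical_only &&
                 !identical(r$frequency_band, classify_frequency(r$frequency_percent))) {
        add("error", fld("frequency_band"),
            sprintf("band '%s' contradicts the %.3g%% banding rule ('%s')",
                    r$frequency_band, r$frequency_percent,
                    classify_frequency(r$frequency_percent)))
      }
    }
    if (r$nonclinical_only && !is.na(r$frequency_band) && !identical(r$frequency_band, "low")) {
      add("error", fld("frequency_band"), "nonclinical_only implies frequency_band = low")
    }
    for (j in seq_along(entry$mitigations)) {
      m <- entry$mitigations[[j]]
      mfld <- sprintf("risks[%d].mitigations[%d]", i, j)
      if (!(m$kind %in% MITIGATION_KINDS)) {
        add("error", mfld, sprintf("unknown mitigation kind '%s'", m$kind))
      }
      if (!is.na(m$burden_value) && (m$burden_value < 0 || m$burden_value > 5)) {
        add("error", mfld, "burden_value outside 0..5")
      }
      if (identical(m$kind, "routine_pharmacovigilance") &&
          !is.na(m$burden_value) && m$burden_value != 0) {
        add("error", mfld, "routine pharmacovigilance must have burden 0")
      }
    }
  }
  if (length(out) == 0) {
    data.frame(level = character(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Validate a portfolio (list of profiles)
#'
#' Runs [validate_profile()] on each profile and additionally checks that
#' product ids are unique within the portfolio.
#'
#' @param profiles List of [product_profile()]s.
#' @inheritParams validate_profile
#' @return data.frame with columns `product_id`, `level`, `field`, `message`.
#' @export
validate_portfolio <- function(profiles, divisions = division_codes()) {
  reports <- lapply(profiles, function(p) {
    rep <- validate_profile(p, divisions)
    if (nrow(rep) > 0) cbind(product_id = p$product_id, rep) else NULL
  })
  ids <- vapply(profiles, function(p) p$product_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    reports[[length(reports) + 1L]] <- data.frame(
      product_id = dup, level = "error", field = "product_id",
      message = "duplicated product_id within portfolio", stringsAsFactors = FALSE)
  }
  reports <- Filter(Negate(is.null), reports)
  if (length(reports) == 0) {
    data.frame(product_id = character(), level = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, reports)
  }
}
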