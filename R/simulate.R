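#' Specification for a synthetic coded portfolio
#'
#' Defines the sampling distributions for a seeded synthetic portfolio of
#' coded product profiles. The defaults emulate a five-year novel-approval
#' portfolio: the division mix is weighted by the published per-division
#' product counts; benefit parameters lean towards serious conditions with
#' limited treatment options and robust evidence (consistent with
#' division-average Gross Benefit Scores around 80 on a 100-point cap);
#' each product carries at least one risk (a reviewed benefit-risk table
#' always lists a risk or the default routine pharmacovigilance), with
#' 1 + Poisson(1.5) risks per product; mitigation counts per risk are
#' 0 + Poisson(0.8) (an empty list becomes routine pharmacovigilance during
#' normalization). `enforce_approvability` rejection-samples each product
#' until it scores NBS > 0 under the reference config, matching the
#' retrospective constraint that every portfolio member was approved.
#'
#' @param seed Integer RNG seed.
#' @param n_products Number of products (>= 1).
#' @param division_weights Named non-negative weights over division codes.
#' @param p_severity,p_prevalence,p_availability,p_durability Probability
#'   vectors over the benefit levels (in scale order, least to most
#'   beneficial coding).
#' @param p_orphan Probability of orphan designation.
#' @param risk_rate Poisson mean for additional risks beyond the first.
#' @param p_risk_severity,p_risk_frequency Probability vectors over risk
#'   severity / frequency levels.
#' @param mitigation_rate Poisson mean of mitigation count per risk.
#' @param p_mitigation_kind Probability vector over the non-routine
#'   mitigation kinds.
#' @param enforce_approvability Rejection-sample to NBS > 0 under
#'   `reference_config`.
#' @param reference_config Config used by the approvability filter.
#' @param max_reject Per-product rejection cap.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(seed = 1L, n_products = 50L,
                            division_weights = NULL,
                            p_severity = c(mild = 0.10, moderate = 0.35, severe = 0.55),
                            p_prevalence = c(population_subset = 0.25,
                                             general_population = 0.45, rare_orphan = 0.30),
                            p_availability = c(many_4_plus = 0.20, some_1_to_3 = 0.40,
                                               none_exist = 0.40),
                            p_durability = c(not_consistent = 0.15, likely_semi_robust = 0.40,
                                             consistent_substantial = 0.45),
                            p_orphan = 0.25,
                            risk_rate = 1.5,
                            p_risk_severity = c(mild = 0.35, moderate = 0.40, severe = 0.25),
                            p_risk_frequency = c(low = 0.45, medium = 0.35, high = 0.20),
                            mitigation_rate = 0.8,
                            p_mitigation_kind = c(label_warning_precaution = 0.45,
                                                  boxed_warning = 0.15,
                                                  monitored_administration = 0.12,
                                                  postmarketing_study_registry = 0.16,
                                                  rems = 0.12),
                            enforce_approvability = TRUE,
                            reference_config = default_config(),
                            max_reject = 1000L) {
  if (is.null(division_weights)) {
    ref <- division_summary_reference()
    ref <- ref[ref$division != "All products", ]
    division_weights <- stats::setNames(ref$n_products, ref$division)
  }
  if (any(division_weights < 0) || sum(division_weights) <= 0) {
    stop_brscore("division weights must be non-negative and not all zero",
                 "brscore_config_error")
  }
  if (n_products < 1) stop_brscore("n_products must be >= 1", "brscore_config_error")
  structure(list(
    seed = as.integer(seed), n_products = as.integer(n_products),
    division_weights = division_weights,
    p_severity = p_severity, p_prevalence = p_prevalence,
    p_availability = p_availability, p_durability = p_durability,
    p_orphan = p_orphan, risk_rate = risk_rate,
    p_risk_severity = p_risk_severity, p_risk_frequency = p_risk_frequency,
    mitigation_rate = mitigation_rate, p_mitigation_kind = p_mitigation_kind,
    enforce_approvability = isTRUE(enforce_approvability),
    reference_config = reference_config,
    max_reject = as.integer(max_reject)
  ), class = "simulation_spec")
}

# risk terms drawn for synthetic profiles; all resolve through the lexicon
.synthetic_terms <- c("hepatotoxicity", "qt_prolongation", "neutropenia",
                      "thrombocytopenia", "hypersensitivity", "infusion_reaction",
                      "embryofetal_toxicity", "nephrotoxicity", "neurotoxicity",
                      "cardiotoxicity", "serious_infection", "immunogenicity",
                      "suicidality", "somnolence", "hypertension", "diarrhea",
                      "nausea", "rash", "headache")

#' Generate a seeded synthetic portfolio of coded product profiles
#'
#' Draws `spec$n_products` normalized, valid product profiles from the
#' categorical distributions in `spec`, fully reproducibly from `spec$seed`
#' (the global RNG state is untouched). With `enforce_approvability`, each
#' product is resampled until it scores NBS > 0 under the reference config;
#' exceeding the per-product rejection cap raises an infeasible-spec error
#' naming the constraint.
#'
#' @param spec A [simulation_spec()].
#' @return List of normalized [product_profile()]s.
#' @export
#' @examples
#' p <- generate_portfolio(simulation_spec(seed = 7, n_products = 3))
#' length(p)
generate_portfolio <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    draw <- function(p) sample(names(p), 1L, prob = p)
    make_product <- function(i) {
      for (attempt in seq_len(spec$max_reject)) {
        orphan <- stats::runif(1) < spec$p_orphan
        ben <- benefit_assessment(
          condition_severity = draw(spec$p_severity),
          condition_prevalence = if (orphan) "rare_orphan" else draw(spec$p_prevalence),
          treatment_availability = draw(spec$p_availability),
          durability = draw(spec$p_durability),
          orphan_designation = orphan
        )
        n_risk <- 1L + stats::rpois(1, spec$risk_rate)
        terms <- sample(.synthetic_terms, n_risk, replace = n_risk > length(.synthetic_terms))
        risks <- lapply(seq_len(n_risk), function(j) {
          n_mit <- stats::rpois(1, spec$mitigation_rate)
          mits <- lapply(seq_len(n_mit), function(k) {
            mitigation_item(draw(spec$p_mitigation_kind))
          })
          risk_entry(
            risk_item(terms[j],
                      severity = draw(spec$p_risk_severity),
                      frequency_band = draw(spec$p_risk_frequency)),
            mitigations = mits
          )
        })
        desigs <- if (orphan) "orphan" else character()
        if (stats::runif(1) < 0.3) desigs <- c(desigs, "priority")
        prof <- product_profile(
          product_id = sprintf("SYN-%04d", i),
          name = sprintf("synthetic-%04d", i),
          approval_year = sample(2015:2019, 1L),
          review_division = draw(spec$division_weights / sum(spec$division_weights)),
          benefit = ben, risks = risks, designations = desigs,
          indication = paste0("indication_", sample(1:8, 1L))
        )
        prof <- normalize_profile(prof)
        if (!spec$enforce_approvability) return(prof)
        b <- suppressWarnings(score_product(prof, spec$reference_config))
        if (b$nbs > 0) return(prof)
      }
      stop_brscore(sprintf(
        "could not draw product %d with NBS > 0 under the reference config within %d attempts",
        i, spec$max_reject), "brscore_infeasible_spec")
    }
    lapply(seq_len(spec$n_products), make_product)
  })
}
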