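#' Check a portfolio of approved products against the approvability constraint
#'
#' The scoring system is reverse-engineered from approval decisions, so a
#' correctly calibrated configuration must give every approved product a
#' positive Net-Benefit Score and a Benefit-Risk Ratio above 1. This check
#' rescores the portfolio under `config` and reports every approved product
#' that violates the constraint. Products whose residual risk is fully
#' mitigated (RRS = 0, BRR undefined) are listed separately in `sentinel`;
#' they violate the constraint only if their NBS is non-positive.
#'
#' @param portfolio List of [product_profile()]s; all treated as approved
#'   unless `approved` says otherwise.
#' @param config A `score_config`.
#' @param approved Logical vector (recycled scalar allowed) labeling each
#'   product; `NA` labels raise a labeling error. Non-approved products are
#'   exempt from the constraint.
#' @return A `calibration_result`: list with `feasible`, `config`,
#'   `violations` (data.frame product_id, nbs, brr), `sentinel`
#'   (character product ids), `n_evaluated`, `seed`.
#' @export
check_portfolio_consistency <- function(portfolio, config = default_config(),
                                        approved = TRUE) {
  approved <- rep_len(approved, length(portfolio))
  if (anyNA(approved)) {
    stop_brscore("every product needs an approval label", "brscore_labeling_error")
  }
  rows <- list()
  sentinel <- character()
  for (i in seq_along(portfolio)) {
    if (!approved[i]) next
    b <- suppressWarnings(score_product(portfolio[[i]], config))
    if (identical(b$brr_status, "ok")) {
      if (b$nbs <= 0 || b$gbs / b$rrs <= 1) {
        rows[[length(rows) + 1L]] <- data.frame(product_id = b$product_id,
                                                nbs = b$nbs, brr = b$brr,
                                                stringsAsFactors = FALSE)
      }
    } else {
      sentinel <- c(sentinel, b$product_id)
      if (b$nbs <= 0) {
        rows[[length(rows) + 1L]] <- data.frame(product_id = b$product_id,
                                                nbs = b$nbs, brr = NA_real_,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(rows) == 0) {
    data.frame(product_id = character(), nbs = numeric(), brr = numeric(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  structure(list(
    feasible = nrow(violations) == 0,
    config = if (nrow(violations) == 0) config else NULL,
    violations = violations,
    sentinel = sentinel,
    n_evaluated = 1L,
    seed = NA_integer_
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s (%d candidate config(s) evaluated)\n",
              if (x$feasible) "feasible" else "infeasible", x$n_evaluated))
  if (!x$feasible && nrow(x$violations) > 0) {
    cat(sprintf("  %d violating product(s), e.g. %s (nbs %g)\n", nrow(x$violations),
                x$violations$product_id[1], x$violations$nbs[1]))
  }
  invisible(x)
}

#' Default calibration search space
#'
#' Candidate value tables for the grid search in [calibrate()]: each entry is
#' a list of candidate vectors for one configuration parameter, honoring the
#' 5-point integer scales. The default config's tables appear in each list.
#'
#' @return Named list of candidate lists, in the canonical search order.
#' @export
default_search_space <- function() {
  triples <- list(c(1, 3, 5), c(1, 2, 3), c(2, 3, 5), c(1, 2, 5))
  list(
    benefit_severity = triples,
    benefit_prevalence = list(c(2, 3, 5), c(1, 3, 5), c(1, 2, 3)),
    benefit_availability = triples,
    benefit_durability = triples,
    orphan_multiplier = list(1.25, 1, 1.5),
    gbs_ceiling = list(100, 125),
    risk_severity = triples,
    risk_frequency = triples,
    residual_floor = list(1, 0)
  )
}

# map a candidate tuple onto a full score_config; NULL if non-monotone
.candidate_config <- function(cand, base) {
  cfg <- base
  set3 <- function(vals, levels) stats::setNames(as.numeric(vals), levels)
  if (!is.null(cand$benefit_severity))
    cfg$benefit_values$condition_severity <- set3(cand$benefit_severity, SEVERITY_LEVELS)
  if (!is.null(cand$benefit_prevalence))
    cfg$benefit_values$condition_prevalence <- set3(cand$benefit_prevalence, PREVALENCE_LEVELS)
  if (!is.null(cand$benefit_availability))
    cfg$benefit_values$treatment_availability <- set3(cand$benefit_availability, AVAILABILITY_LEVELS)
  if (!is.null(cand$benefit_durability))
    cfg$benefit_values$durability <- set3(cand$benefit_durability, DURABILITY_LEVELS)
  if (!is.null(cand$orphan_multiplier)) cfg$orphan_multiplier <- cand$orphan_multiplier
  if (!is.null(cand$gbs_ceiling)) cfg$gbs_ceiling <- cand$gbs_ceiling
  if (!is.null(cand$risk_severity))
    cfg$risk_severity_values <- set3(cand$risk_severity, SEVERITY_LEVELS)
  if (!is.null(cand$risk_frequency))
    cfg$risk_frequency_values <- set3(cand$risk_frequency, FREQUENCY_LEVELS)
  if (!is.null(cand$residual_floor)) cfg$residual_floor <- cand$residual_floor
  ok <- tryCatch({ validate_config(cfg); TRUE }, brscore_config_error = function(e) FALSE)
  if (ok) cfg else NULL
}

#' Search a configuration grid for an approvability-consistent config
#'
#' Deterministic grid search over per-parameter candidate value lists: the
#' canonical parameter ordering is the order of `search_space`, candidates
#' are enumerated lexicographically (the first candidate of every parameter
#' first), non-monotone combinations are discarded, and the first feasible
#' configuration (every approved product with NBS > 0 and BRR > 1) is
#' returned. If the grid exceeds `max_evaluations` combinations, a seeded
#' random subset of that size is drawn (still including the lexicographic
#' head) — hence `seed`. If no candidate is feasible the best one (fewest
#' violations, ties broken by enumeration order) is reported with its
#' violations.
#'
#' @inheritParams check_portfolio_consistency
#' @param search_space Named list of per-parameter candidate lists, as in
#'   [default_search_space()]; parameters omitted keep the base config value.
#' @param seed Integer seed for subsampling large grids.
#' @param base_config Config supplying every parameter not searched.
#' @param max_evaluations Evaluation budget.
#' @return A `calibration_result`.
#' @export
calibrate <- function(portfolio, search_space = default_search_space(),
                      seed = 1L, approved = TRUE,
                      base_config = default_config(), max_evaluations = 2000L) {
  if (length(search_space) == 0 || any(lengths(search_space) == 0)) {
    stop_brscore("search space must have at least one candidate per parameter",
                 "brscore_config_error")
  }
  sizes <- lengths(search_space)
  total <- prod(sizes)
  # lexicographic enumeration: earlier parameters vary slowest
  idx_of <- function(k) {  # k in 0..total-1 -> index vector
    out <- integer(length(sizes))
    for (j in rev(seq_along(sizes))) {
      out[j] <- k %% sizes[j]
      k <- k %/% sizes[j]
    }
    out + 1L
  }
  ks <- if (total <= max_evaluations) {
    seq_len(total) - 1L
  } else {
    head_n <- min(100L, max_evaluations)
    extra <- with_seed(seed, sample.int(total - head_n, max_evaluations - head_n)) + head_n - 1L
    c(seq_len(head_n) - 1L, sort(unique(extra)))
  }

  best <- NULL
  n_eval <- 0L
  for (k in ks) {
    idx <- idx_of(k)
    cand <- stats::setNames(
      lapply(seq_along(search_space), function(j) search_space[[j]][[idx[j]]]),
      names(search_space))
    cfg <- .candidate_config(cand, base_config)
    if (is.null(cfg)) next  # violates monotonicity; not a legal config
    n_eval <- n_eval + 1L
    res <- check_portfolio_consistency(portfolio, cfg, approved)
    if (res$feasible) {
      res$n_evaluated <- n_eval
      res$seed <- as.integer(seed)
      return(res)
    }
    if (is.null(best) || nrow(res$violations) < nrow(best$violations)) {
      best <- res
      best$best_config <- cfg
    }
  }
  if (is.null(best)) {
    stop_brscore("search space contains no monotonicity-respecting configuration",
                 "brscore_config_error")
  }
  best$n_evaluated <- n_eval
  best$seed <- as.integer(seed)
  best
}
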