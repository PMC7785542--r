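#' Division-level summary table
#'
#' Aggregates scored products into one row per review division plus an
#' "All products" row, in the layout of the published division summary:
#' product count, average Gross Benefit Score, average (signed) Residual
#' Risk Score, Net-Benefit Score of the division means, and the average
#' Benefit-Risk Ratio. Conventions (fixed because printed summaries are
#' ambiguous about them):
#' \itemize{
#'   \item `nbs_of_means = mean_gbs + mean_rrs_signed`, computed on the
#'     unrounded means; rounding is applied only for display by
#'     [format_division_table()];
#'   \item `mean_brr` is the arithmetic mean of per-product ratios, not the
#'     ratio of the mean scores;
#'   \item products with an undefined ratio (all risk mitigated) are
#'     excluded from `mean_brr` and counted in `n_brr_excluded`.
#' }
#'
#' @param profiles List of [product_profile()]s.
#' @param breakdowns Matching list of `score_breakdown`s; computed with
#'   `config` if omitted.
#' @param config Used only when `breakdowns` is missing.
#' @return data.frame with columns `division`, `n_products`, `mean_gbs`,
#'   `mean_rrs_signed`, `nbs_of_means`, `mean_brr`, `n_brr_excluded`;
#'   divisions sorted alphabetically, "All products" last.
#' @export
summarize_by_division <- function(profiles, breakdowns = NULL, config = default_config()) {
  if (length(profiles) == 0) stop_brscore("empty portfolio", "brscore_domain_error")
  if (is.null(breakdowns)) breakdowns <- score_portfolio(profiles, config)
  tab <- breakdown_table(breakdowns)
  tab$division <- vapply(profiles, function(p) p$review_division, character(1))

  one_row <- function(d, rows) {
    ok <- rows$brr_status == "ok"
    data.frame(
      division = d,
      n_products = nrow(rows),
      mean_gbs = mean(rows$gbs),
      mean_rrs_signed = mean(rows$rrs_signed),
      nbs_of_means = mean(rows$gbs) + mean(rows$rrs_signed),
      mean_brr = if (any(ok)) mean(rows$brr[ok]) else NA_real_,
      n_brr_excluded = sum(!ok),
      stringsAsFactors = FALSE
    )
  }
  divisions <- sort(unique(tab$division))
  out <- do.call(rbind, lapply(divisions, function(d) one_row(d, tab[tab$division == d, ])))
  rbind(out, one_row("All products", tab))
}

#' Round a division summary for display
#'
#' Score means are displayed to the nearest integer and the mean ratio to
#' two decimals (half-up), matching the printed table convention. Column
#' names follow the CSV contract: `division`, `n_products`, `avg_gbs`,
#' `avg_rrs`, `nbs`, `brr`.
#'
#' @param summary Output of [summarize_by_division()].
#' @return data.frame rounded for display.
#' @export
format_division_table <- function(summary) {
  data.frame(
    division = summary$division,
    n_products = summary$n_products,
    avg_gbs = round_half_up(summary$mean_gbs),
    avg_rrs = round_half_up(summary$mean_rrs_signed),
    nbs = round_half_up(summary$nbs_of_means),
    brr = round_half_up(summary$mean_brr, 2),
    stringsAsFactors = FALSE
  )
}

#' Division-level reference averages, FDA novel approvals 2015-2019
#'
#' The reported division-level averages (one row per review division plus an
#' all-products row) for the five-year portfolio of new molecular entities
#' and new biologics scored with this framework: product count, average GBS,
#' average signed RRS, NBS and BRR. `arithmetic_consistent` marks the rows
#' whose printed NBS equals `avg_gbs + avg_rrs` exactly; the remaining rows
#' carry printed rounding inconsistencies and cannot be reproduced by
#' identity arithmetic.
#'
#' @return data.frame with columns `division`, `n_products`, `avg_gbs`,
#'   `avg_rrs`, `nbs`, `brr`, `arithmetic_consistent`.
#' @export
division_summary_reference <- function() {
  tab <- data.frame(
    division = c("DAAAP", "DAIP", "DAVP", "DBRUP", "DCaRP", "DDDP", "DGIEP", "DHOT",
                 "DHP", "DMIP", "DMEP", "DNP", "DOP1", "DOP2", "DPP", "DPARP", "DTOP",
                 "All products"),
    n_products = c(1, 18, 10, 6, 5, 11, 12, 1, 37, 5, 6, 23, 14, 13, 7, 9, 7, 185),
    avg_gbs = c(100, 71, 92, 67, 78, 43, 75, 100, 93, 96, 80, 72, 98, 100, 78, 72, 63, 81),
    avg_rrs = c(-16, -13, -11, -18, -7, -6, -8, -31, -24, -49, -13, -16, -29, -19, -18, -10, -6, -16),
    nbs = c(84, 59, 81, 49, 71, 37, 67, 69, 69, 35, 68, 57, 70, 81, 60, 62, 58, 65),
    brr = c(6.25, 9.59, 19.69, 4.58, 30.86, 12.58, 14.11, 3.23, 13.87, 4.32, 7.02,
            7.79, 8.80, 10.40, 9.78, 15.23, 16.44, 13.26),
    stringsAsFactors = FALSE
  )
  tab$arithmetic_consistent <- tab$avg_gbs + tab$avg_rrs == tab$nbs
  tab
}

#' Scatter-plot data by indication or division
#'
#' One (NBS, BRR) point per scored product, grouped for a single scatter
#' view of a treatment landscape. Points with an undefined ratio are kept
#' and flagged (`brr` is `NA`). Ordering is deterministic: by group, then
#' product id.
#'
#' @inheritParams summarize_by_division
#' @param group_by `"division"` or `"indication"`.
#' @return data.frame with columns `group`, `product_id`, `nbs`, `brr`,
#'   `brr_defined`.
#' @export
scatter_data <- function(profiles, breakdowns = NULL, group_by = c("division", "indication"),
                         config = default_config()) {
  group_by <- match.arg(group_by)
  if (is.null(breakdowns)) breakdowns <- score_portfolio(profiles, config)
  tab <- breakdown_table(breakdowns)
  tab$group <- vapply(profiles, function(p) {
    g <- if (group_by == "division") p$review_division else p$indication
    if (is.na(g)) "unspecified" else g
  }, character(1))
  out <- data.frame(group = tab$group, product_id = tab$product_id,
                    nbs = tab$nbs, brr = tab$brr,
                    brr_defined = tab$brr_status == "ok",
                    stringsAsFactors = FALSE)
  out[order(out$group, out$product_id), , drop = FALSE]
}

#' Approval-likelihood trajectory over development milestones
#'
#' Scores a time-ordered series of profile snapshots of one product (e.g.
#' successive safety-update benefit-risk tables) to map how the net-benefit
#' position evolves towards (or away from) approvability.
#'
#' @param snapshots Time-ordered list of [product_profile()]s, all with the
#'   same `product_id`.
#' @param config A `score_config`.
#' @param labels Optional milestone labels (default `"t1"`, `"t2"`, ...).
#' @return data.frame with columns `milestone`, `nbs`, `brr`, `nbs_band`,
#'   `brr_band`, in input order.
#' @export
approval_trajectory <- function(snapshots, config = default_config(), labels = NULL) {
  if (length(snapshots) == 0) stop_brscore("need at least one snapshot", "brscore_domain_error")
  ids <- unique(vapply(snapshots, function(p) p$product_id, character(1)))
  if (length(ids) != 1L) {
    stop_brscore(paste("snapshots mix product ids:", paste(ids, collapse = ", ")),
                 "brscore_domain_error")
  }
  if (is.null(labels)) labels <- paste0("t", seq_along(snapshots))
  stopifnot(length(labels) == length(snapshots))
  bks <- lapply(snapshots, function(s) suppressWarnings(score_product(s, config)))
  data.frame(
    milestone = as.character(labels),
    nbs = vapply(bks, function(b) b$nbs, numeric(1)),
    brr = vapply(bks, function(b) b$brr, numeric(1)),
    nbs_band = vapply(bks, function(b) b$nbs_band, character(1)),
    brr_band = vapply(bks, function(b) if (is.na(b$brr_band)) NA_character_ else b$brr_band,
                      character(1)),
    stringsAsFactors = FALSE
  )
}

#' Structured benefit-risk report for one product
#'
#' Renders the updated benefit-risk framework layout: one row per benefit
#' decision factor, one "Risk and Mitigations #i" row per risk with its
#' residual score, and a closing net-benefit row carrying NBS, BRR and their
#' interpretation bands. Verbatim evidence text from the coded profile is
#' carried into the evidence column.
#'
#' @param profile A [product_profile()] (normalized internally).
#' @param breakdown Its `score_breakdown`; computed with `config` if omitted.
#' @param config Used only when `breakdown` is missing.
#' @return A `br_report`: list with `product_id`, `name` and a `rows`
#'   data.frame (`section`, `decision_factor`, `evidence`, `score`).
#' @export
render_report <- function(profile, breakdown = NULL, config = default_config()) {
  profile <- normalize_profile(profile)
  if (is.null(breakdown)) breakdown <- suppressWarnings(score_product(profile, config))
  ben <- profile$benefit
  verb <- function(field) {
    v <- ben$verbatim[field]
    if (is.null(ben$verbatim) || is.na(v)) "" else unname(v)
  }
  rows <- data.frame(
    section = "Benefit",
    decision_factor = c("Condition Severity", "Condition Prevalence",
                        "Availability of Options", "Durability of Results"),
    evidence = vapply(c("condition_severity", "condition_prevalence",
                        "treatment_availability", "durability"), verb, character(1)),
    score = c(ben$condition_severity, ben$condition_prevalence,
              ben$treatment_availability, ben$durability),
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in seq_along(profile$risks)) {
    r <- profile$risks[[i]]$risk
    mit <- paste(vapply(profile$risks[[i]]$mitigations, function(m) m$kind, character(1)),
                 collapse = "; ")
    ev <- if (is.na(r$verbatim)) r$term else r$verbatim
    rows <- rbind(rows, data.frame(
      section = "Risk",
      decision_factor = sprintf("Risk and Mitigations #%d", i),
      evidence = sprintf("%s [%s/%s]; mitigations: %s", ev, r$severity, r$frequency_band, mit),
      score = sprintf("residual %g", breakdown$risks$residual[i]),
      stringsAsFactors = FALSE
    ))
  }
  brr_txt <- if (identical(breakdown$brr_status, "ok")) {
    sprintf("%.*f (%s)", default_config()$brr_decimals, breakdown$brr, breakdown$brr_band)
  } else breakdown$brr_status
  rows <- rbind(rows, data.frame(
    section = "Net benefit",
    decision_factor = "Net benefit",
    evidence = sprintf("GBS %g; RRS %g", breakdown$gbs, breakdown$rrs),
    score = sprintf("NBS %g (%s); BRR %s", breakdown$nbs, breakdown$nbs_band, brr_txt),
    stringsAsFactors = FALSE
  ))
  structure(list(product_id = profile$product_id, name = profile$name, rows = rows),
            class = "br_report")
}

#' @export
print.br_report <- function(x, ...) {
  cat(report_markdown(x))
  invisible(x)
}

#' Render a report as Markdown
#'
#' @param report A `br_report` from [render_report()].
#' @return Single Markdown string.
#' @export
report_markdown <- function(report) {
  lines <- c(
    sprintf("# Benefit-Risk Report: %s (%s)", report$name, report$product_id),
    "",
    "| Decision factors | Evidence and Conclusions | Score |",
    "|---|---|---|",
    sprintf("| %s | %s | %s |", report$rows$decision_factor,
            gsub("\\|", "/", report$rows$evidence), report$rows$score),
    ""
  )
  paste(lines, collapse = "\n")
}

#' Serialize / parse a report as JSON
#'
#' `report_json()` and `parse_report_json()` are exact inverses on the
#' report content.
#'
#' @param report A `br_report`.
#' @param path Optional file path; when given, JSON is written there.
#' @return `report_json()`: JSON string (invisibly the path when written);
#'   `parse_report_json()`: a `br_report`.
#' @export
report_json <- function(report, path = NULL) {
  x <- list(product_id = report$product_id, name = report$name, rows = report$rows)
  js <- jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  as.character(js)
}

#' @rdname report_json
#' @param json JSON string or file path to parse.
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  structure(list(product_id = x$product_id, name = x$name,
                 rows = as.data.frame(x$rows, stringsAsFactors = FALSE)),
            class = "br_report")
}
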