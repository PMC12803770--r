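#' Retrospective policy evaluation
#'
#' Re-assesses every visit in a dataset under the alternative deferral rule
#' and summarises the policy change. Visits with too little history
#' (`not_assessed`) are excluded from every count and denominator. The
#' summary mirrors the standard reporting layout:
#' deferral rate under the current policy, deferral rate under the
#' alternative rule, percent change in deferrals, the share of currently
#' accepted donations that the alternative rule would defer, the net percent
#' change in donations, and the mean historical mean Hb of newly eligible
#' donations per sex.
#'
#' Note the differing denominators: deferral rates and the newly-deferred
#' share are percentages of all assessed visits, while the change in
#' donations is a percentage of current donations (assessed visits minus
#' current deferrals).
#'
#' @param visits A visits tibble ([read_visits()] / [simulate_population()]).
#' @param sigma An `hb_sigma` table or named numeric; see [assess_visits()].
#' @param policy An [policy_config()] object.
#' @return An object of class `hb_policy_eval`: a list with `report`
#'   (one-row tibble, see [compute_report_metrics()] plus
#'   `mean_hist_hb_newly_eligible_male`/`_female`), `assessments` (the
#'   per-visit table) and the `policy` and `sigma` used. [glance()] returns
#'   the report row, [tidy()] the per-visit assessments.
#' @examples
#' pop <- simulate_population(sim_config(n_donors = 100, seed = 11))
#' ev <- evaluate_policy(pop, estimate_sigma(pop))
#' glance(ev)
#' @export
evaluate_policy <- function(visits, sigma, policy = policy_config()) {
  assessments <- assess_visits(visits, sigma, policy)
  a <- assessments |> dplyr::filter(.data$alt_decision != "not_assessed")
  if (nrow(a) == 0L) {
    stop("No assessable visits: every visit has fewer than ",
         policy$min_prior_measurements, " prior measurements.", call. = FALSE)
  }
  alt_defer <- a$alt_decision %in% c("defer_A", "defer_B")
  cur_defer <- a$current_decision == "defer"
  d_cur <- sum(cur_defer)
  d_alt <- sum(alt_defer)
  newly_deferred <- sum(!cur_defer & alt_defer)
  newly_eligible <- sum(cur_defer & a$alt_decision == "eligible")

  report <- compute_report_metrics(
    d_cur = d_cur, d_alt = d_alt,
    newly_deferred = newly_deferred, newly_eligible = newly_eligible,
    n_visits_assessed = nrow(a)
  )
  ne <- a |> dplyr::filter(cur_defer & .data$alt_decision == "eligible")
  mean_ne <- function(s) {
    v <- ne$hist_mean[ne$sex == s]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  report <- report |>
    dplyr::mutate(
      n_donors = dplyr::n_distinct(assessments$donor_id),
      mean_hist_hb_newly_eligible_male = mean_ne("male"),
      mean_hist_hb_newly_eligible_female = mean_ne("female"),
      alpha_mean = policy$alpha_mean,
      alpha_outlier = policy$alpha_outlier
    )

  structure(
    list(report = report, assessments = assessments,
         policy = policy, sigma = sigma),
    class = "hb_policy_eval"
  )
}

#' Policy-change percentages from decision counts
#'
#' Computes the reporting percentages from the four decision counts among
#' assessed visits, enforcing the accounting identity
#' `d_alt - d_cur == newly_deferred - newly_eligible` (every flip from
#' donation to deferral or back is counted exactly once). Rounding is left
#' to presentation; all values are exact here.
#'
#' @param d_cur Current-policy deferrals among assessed visits.
#' @param d_alt Alternative-policy deferrals among assessed visits.
#' @param newly_deferred Visits donated currently but deferred by the
#'   alternative rule.
#' @param newly_eligible Visits deferred currently but eligible under the
#'   alternative rule.
#' @param n_visits_assessed Number of assessed visits (denominator of the
#'   rates).
#' @return One-row tibble: the five counts plus `rate_cur`, `rate_alt`
#'   (percent of assessed visits), `pct_change_deferrals`
#'   (`NA` when `d_cur == 0`), `pct_newly_deferred` (percent of assessed
#'   visits) and `pct_change_donations` (percent of current donations,
#'   `n_visits_assessed - d_cur`).
#' @examples
#' compute_report_metrics(d_cur = 52200, d_alt = 24900, newly_deferred = 0,
#'                        newly_eligible = 27300, n_visits_assessed = 1e6)
#' @export
compute_report_metrics <- function(d_cur, d_alt, newly_deferred,
                                   newly_eligible, n_visits_assessed) {
  counts <- c(d_cur, d_alt, newly_deferred, newly_eligible, n_visits_assessed)
  stopifnot(is.numeric(counts), all(counts >= 0),
            n_visits_assessed >= 1)
  if ((d_alt - d_cur) != (newly_deferred - newly_eligible)) {
    stop("Accounting identity violated: d_alt - d_cur must equal ",
         "newly_deferred - newly_eligible. This signals an upstream bug.",
         call. = FALSE)
  }
  tibble::tibble(
    n_visits_assessed = n_visits_assessed,
    d_cur = d_cur,
    d_alt = d_alt,
    newly_deferred = newly_deferred,
    newly_eligible = newly_eligible,
    rate_cur = 100 * d_cur / n_visits_assessed,
    rate_alt = 100 * d_alt / n_visits_assessed,
    pct_change_deferrals =
      if (d_cur > 0) 100 * (d_alt - d_cur) / d_cur else NA_real_,
    pct_newly_deferred = 100 * newly_deferred / n_visits_assessed,
    pct_change_donations =
      100 * (newly_eligible - newly_deferred) / (n_visits_assessed - d_cur)
  )
}

#' Sweep the policy's confidence parameters
#'
#' Evaluates the policy over a grid of `alpha_mean` x `alpha_outlier` values
#' and returns one report row per pair. The default grid spans the
#' operationally interesting range: 21 evenly spaced `alpha_mean` values over
#' [-0.999, 0.999] crossed with `alpha_outlier` 0.99, 0.999 and 0.9999.
#'
#' @inheritParams evaluate_policy
#' @param base_policy Policy whose non-swept settings are held fixed.
#' @param alpha_mean_grid Numeric vector of `alpha_mean` values.
#' @param alpha_outlier_set Numeric vector of `alpha_outlier` values.
#' @return A tibble of class `hb_sweep`: one row per (`alpha_mean`,
#'   `alpha_outlier`) with the [compute_report_metrics()] columns.
#'   [autoplot()] draws the deferral-rate and donation-change profiles.
#' @examples
#' pop <- simulate_population(sim_config(n_donors = 100, seed = 11))
#' sweep_parameters(pop, estimate_sigma(pop),
#'                  alpha_mean_grid = c(-0.9, 0, 0.9),
#'                  alpha_outlier_set = 0.999)
#' @export
sweep_parameters <- function(visits, sigma, base_policy = policy_config(),
                             alpha_mean_grid = seq(-0.999, 0.999,
                                                   length.out = 21),
                             alpha_outlier_set = c(0.99, 0.999, 0.9999)) {
  stopifnot(length(alpha_mean_grid) > 0, length(alpha_outlier_set) > 0)
  grid <- tidyr::expand_grid(alpha_mean = alpha_mean_grid,
                             alpha_outlier = alpha_outlier_set)
  out <- purrr::pmap(grid, function(alpha_mean, alpha_outlier) {
    pol <- base_policy
    pol$alpha_mean <- alpha_mean
    pol$alpha_outlier <- alpha_outlier
    # revalidate through the constructor to keep invariants enforced
    pol <- do.call(policy_config, pol[setdiff(names(pol), "preset")])
    evaluate_policy(visits, sigma, pol)$report
  }) |> dplyr::bind_rows()
  out <- out |> dplyr::select(dplyr::all_of(c("alpha_mean", "alpha_outlier")),
                              dplyr::everything())
  class(out) <- c("hb_sweep", class(out))
  out
}

#' Drop donors with a recent flagged donation
#'
#' Sensitivity-analysis hook: removes all visits of donors who have at least
#' one visit with `exclude_flag == TRUE` within `window_days` of the
#' dataset's most recent visit date (e.g. donors with a recent double
#' red-cell donation, whose Hb dynamics differ). If the input has no
#' `exclude_flag` column the function warns and returns the data unchanged.
#'
#' @param visits A visits tibble, optionally with a logical `exclude_flag`.
#' @param window_days Length of the look-back window in days (default 365).
#' @return The filtered visits tibble; the number of removed donors and rows
#'   is attached as attribute `"filter_counts"`.
#' @export
filter_recent_other_donations <- function(visits, window_days = 365) {
  stopifnot(is.data.frame(visits), window_days >= 0)
  if (!"exclude_flag" %in% names(visits)) {
    warning("No `exclude_flag` column present; returning data unchanged.",
            call. = FALSE)
    return(visits)
  }
  cutoff <- max(visits$visit_date) - window_days
  bad <- visits |>
    dplyr::filter(.data$exclude_flag & .data$visit_date >= cutoff) |>
    dplyr::pull(.data$donor_id) |>
    unique()
  out <- visits |> dplyr::filter(!.data$donor_id %in% bad)
  attr(out, "filter_counts") <- list(donors_removed = length(bad),
                                     rows_removed = nrow(visits) - nrow(out))
  out
}
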