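#' Standard normal quantile
#'
#' The value `z` with `pnorm(z) = p`, used to turn the policy's confidence
#' parameters into Hb cutoffs. Validates its argument and otherwise defers to
#' [stats::qnorm()].
#'
#' @param p Probability strictly between 0 and 1 (vectorised).
#' @return Numeric vector of quantiles.
#' @examples
#' normal_quantile(0.999)
#' @export
normal_quantile <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly between 0 and 1.", call. = FALSE)
  }
  qnorm(p)
}

#' Confidence bound on the historical mean compared to the threshold
#'
#' The bound of the two-sided `|alpha_mean| * 100` percent confidence
#' interval for the donor's mean Hb that the policy compares to the deferral
#' threshold:
#' \deqn{bound = \bar{x} + sign(\alpha)\, z_{(1+|\alpha|)/2}\, \sigma/\sqrt{n}.}
#' With `alpha_mean = 0` the bound is the historical mean itself; negative
#' values select the lower bound (conservative), positive values the upper
#' bound (lenient). The caller declares a reason-A deferral when the returned
#' bound is below the threshold.
#'
#' @param hist_mean Historical mean Hb (g/dL); vectorised.
#' @param n_prior Number of measurements in the mean (>= 2); vectorised.
#' @param sigma Measurement SD (g/dL, >= 0); vectorised.
#' @param alpha_mean Policy parameter in (-1, 1); scalar.
#' @return The bound in g/dL.
#' @examples
#' mean_bound(13.6, 4, 0.7, -0.95) # lower 95% bound: 12.914
#' @export
mean_bound <- function(hist_mean, n_prior, sigma, alpha_mean) {
  if (abs(alpha_mean) >= 1) {
    stop("`alpha_mean` must lie strictly between -1 and 1.", call. = FALSE)
  }
  if (alpha_mean == 0) return(hist_mean)
  z <- normal_quantile((1 + abs(alpha_mean)) / 2)
  hist_mean + sign(alpha_mean) * z * sigma / sqrt(n_prior)
}

#' Low-outlier cutoff for a single measurement
#'
#' The Hb value below which a single measurement is classified as a low
#' outlier with respect to the donor's historical mean:
#' \deqn{cutoff = \bar{x} - z_{\alpha_{outlier}}\, \sigma \, a,}
#' where `a = sqrt(1 + 1/n_prior)` if `prediction_adjustment` is on (making
#' the false-positive rate exactly `1 - alpha_outlier` at finite history
#' length) and `a = 1` otherwise.
#'
#' @param hist_mean Historical mean Hb (g/dL); vectorised.
#' @param sigma Measurement SD (g/dL, >= 0); vectorised.
#' @param alpha_outlier Probability level in (0.5, 1); scalar.
#' @param n_prior Number of historical measurements; used only when
#'   `prediction_adjustment` is `TRUE`.
#' @param prediction_adjustment Widen the cutoff for estimation error in the
#'   mean? Default `FALSE`.
#' @return The cutoff in g/dL; a measurement is a low outlier iff it is
#'   strictly below this value.
#' @examples
#' outlier_cutoff(15, 0.7, 0.999) # 12.837
#' @export
outlier_cutoff <- function(hist_mean, sigma, alpha_outlier, n_prior = NULL,
                           prediction_adjustment = FALSE) {
  if (alpha_outlier <= 0.5 || alpha_outlier >= 1) {
    stop("`alpha_outlier` must lie strictly between 0.5 and 1.", call. = FALSE)
  }
  a <- 1
  if (isTRUE(prediction_adjustment)) {
    if (is.null(n_prior)) stop("`n_prior` is required when ",
                               "`prediction_adjustment` is TRUE.", call. = FALSE)
    a <- sqrt(1 + 1 / n_prior)
  }
  hist_mean - normal_quantile(alpha_outlier) * sigma * a
}

#' Assess a single visit against the alternative deferral rule
#'
#' Scalar reference implementation of the per-visit decision. Given the
#' donor's prior measurements, the rule (in order):
#' 1. too little history (`n_prior < min_prior_measurements`): `not_assessed`;
#' 2. reason A: the [mean_bound()] of the prior measurements is below the
#'    sex-specific threshold: `defer_A`;
#' 3. reason B: the current measurement is below the [outlier_cutoff()]
#'    (and, in strict mode, below the threshold): `defer_B`;
#' 4. otherwise `eligible`.
#'
#' The historical mean is formed from *prior* measurements only; the current
#' measurement never enters its own reference mean. The current policy's
#' decision (`defer` iff `hb` strictly below threshold, equality is eligible)
#' is reported alongside.
#'
#' @param prior_hbs Numeric vector of the donor's prior Hb measurements in
#'   chronological order (g/dL).
#' @param hb Current measurement (g/dL).
#' @param sex `"male"` or `"female"`.
#' @param sigma Measurement SD for this sex (g/dL).
#' @param policy An [policy_config()] object.
#' @return One-row tibble with `n_prior`, `hist_mean`, `ci_bound`,
#'   `outlier_cutoff`, `current_decision` (`donate`/`defer`), `alt_decision`
#'   (`eligible`/`defer_A`/`defer_B`/`not_assessed`) and `reason`
#'   (`A`/`B`/`none`/`NA`).
#' @examples
#' assess_visit(c(13, 13), hb = 13.7, sex = "male", sigma = 0.7,
#'              policy = policy_config())
#' @export
assess_visit <- function(prior_hbs, hb, sex, sigma, policy = policy_config()) {
  stopifnot(inherits(policy, "hb_policy"), sex %in% c("male", "female"),
            is.numeric(hb), length(hb) == 1L, is.numeric(sigma), sigma >= 0)
  thr <- threshold_for(sex, policy)
  if (is.finite(policy$max_history_length) &&
      length(prior_hbs) > policy$max_history_length) {
    prior_hbs <- utils::tail(prior_hbs, policy$max_history_length)
  }
  n_prior <- length(prior_hbs)
  current <- if (hb < thr) "defer" else "donate"

  if (n_prior < policy$min_prior_measurements) {
    return(tibble::tibble(
      n_prior = n_prior, hist_mean = NA_real_, ci_bound = NA_real_,
      outlier_cutoff = NA_real_, current_decision = current,
      alt_decision = "not_assessed", reason = "NA"
    ))
  }
  hm <- mean(prior_hbs)
  bound <- mean_bound(hm, n_prior, sigma, policy$alpha_mean)
  cutoff <- outlier_cutoff(hm, sigma, policy$alpha_outlier, n_prior,
                           policy$prediction_adjustment)
  alt <- if (bound < thr) {
    "defer_A"
  } else if (hb < cutoff &&
             (!policy$outlier_requires_below_threshold || hb < thr)) {
    "defer_B"
  } else {
    "eligible"
  }
  tibble::tibble(
    n_prior = n_prior, hist_mean = hm, ci_bound = bound,
    outlier_cutoff = cutoff, current_decision = current,
    alt_decision = alt,
    reason = c(defer_A = "A", defer_B = "B", eligible = "none")[[alt]]
  )
}

#' Assess every visit in a dataset
#'
#' Vectorised chronological assessment of all donors' visits. For visit `k`
#' of a donor, the historical mean is formed from visits `1..k-1` (restricted
#' to current-policy donations when `policy$history_scope ==
#' "donations_only"`, and to the most recent `policy$max_history_length`
#' measurements when that is finite). The assessment is static: alternative
#' decisions do not change which measurements enter later histories.
#'
#' @param visits A visits tibble ([read_visits()] / [simulate_population()]).
#' @param sigma An `hb_sigma` table ([estimate_sigma()] / [sigma_override()])
#'   or a named numeric `c(male = , female = )`.
#' @param policy An [policy_config()] object.
#' @return A tibble with one row per visit: the visit columns plus
#'   `n_prior`, `hist_mean`, `ci_bound`, `outlier_cutoff`,
#'   `current_decision`, `alt_decision`, `reason`.
#' @examples
#' pop <- simulate_population(sim_config(n_donors = 20, seed = 5))
#' assess_visits(pop, sigma_override(male = 0.7, female = 0.67))
#' @export
assess_visits <- function(visits, sigma, policy = policy_config()) {
  stopifnot(is.data.frame(visits), inherits(policy, "hb_policy"))
  need <- c("donor_id", "sex", "visit_date", "hb")
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols) > 0) {
    stop("`visits` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sg <- sigma_lookup(sigma, visits$sex)
  thr <- threshold_for(visits$sex, policy)

  out <- visits |>
    dplyr::mutate(.sigma = sg, .thr = thr) |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::arrange(.data$visit_date, .by_group = TRUE) |>
    dplyr::mutate(
      current_decision = ifelse(.data$hb < .data$.thr, "defer", "donate"),
      .incl = if (policy$history_scope == "donations_only")
        .data$current_decision == "donate" else TRUE,
      n_prior = history_n(.data$.incl, policy$max_history_length),
      hist_mean = history_mean(.data$hb, .data$.incl, policy$max_history_length)
    ) |>
    dplyr::ungroup()

  assessed <- out$n_prior >= policy$min_prior_measurements
  bound <- cutoff <- rep(NA_real_, nrow(out))
  if (any(assessed)) {
    bound[assessed] <- mean_bound(out$hist_mean[assessed],
                                  out$n_prior[assessed],
                                  out$.sigma[assessed], policy$alpha_mean)
    cutoff[assessed] <- outlier_cutoff(out$hist_mean[assessed],
                                       out$.sigma[assessed],
                                       policy$alpha_outlier,
                                       out$n_prior[assessed],
                                       policy$prediction_adjustment)
  }
  out$ci_bound <- bound
  out$outlier_cutoff <- cutoff
  out$hist_mean[!assessed] <- NA_real_
  out$alt_decision <- dplyr::case_when(
    !assessed ~ "not_assessed",
    bound < out$.thr ~ "defer_A",
    out$hb < cutoff &
      (!policy$outlier_requires_below_threshold | out$hb < out$.thr) ~ "defer_B",
    TRUE ~ "eligible"
  )
  out$reason <- c(not_assessed = "NA", defer_A = "A", defer_B = "B",
                  eligible = "none")[out$alt_decision]
  out |>
    dplyr::select(-dplyr::all_of(c(".sigma", ".thr", ".incl"))) |>
    dplyr::arrange(.data$donor_id, .data$visit_date)
}

#' Assess a single donor's chronology
#'
#' Convenience wrapper around [assess_visits()] for one donor's history.
#'
#' @param history Visits tibble containing exactly one `donor_id`.
#' @inheritParams assess_visits
#' @return As [assess_visits()].
#' @export
assess_donor <- function(history, sigma, policy = policy_config()) {
  stopifnot(is.data.frame(history))
  if (length(unique(history$donor_id)) != 1L) {
    stop("`history` must contain exactly one donor.", call. = FALSE)
  }
  assess_visits(history, sigma, policy)
}

# count of prior included measurements (capped at max_len) for each position
history_n <- function(incl, max_len) {
  prior <- dplyr::lag(cumsum(incl), default = 0L)
  if (is.finite(max_len)) pmin(prior, as.integer(max_len)) else prior
}

# mean of the (last max_len) prior included measurements for each position
history_mean <- function(hb, incl, max_len) {
  csum <- dplyr::lag(cumsum(hb * incl), default = 0)
  cnt <- dplyr::lag(cumsum(incl), default = 0L)
  if (!is.finite(max_len)) {
    return(ifelse(cnt > 0, csum / cnt, NA_real_))
  }
  # rolling window over included values only
  k <- as.integer(max_len)
  vals <- hb[incl]
  vsum <- c(0, cumsum(vals))
  hi <- cnt                      # included values strictly before position
  lo <- pmax(0L, hi - k)
  n_used <- hi - lo
  ifelse(n_used > 0, (vsum[hi + 1L] - vsum[lo + 1L]) / n_used, NA_real_)
}
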