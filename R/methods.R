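#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.hb_policy_eval <- function(x, ...) {
  r <- x$report
  cat("<hb_policy_eval>\n")
  cat(sprintf("  donors: %d   assessed visits: %d\n",
              r$n_donors, r$n_visits_assessed))
  cat(sprintf("  deferral rate: current %.2f%%  alternative %.2f%%  (change %s%%)\n",
              r$rate_cur, r$rate_alt,
              ifelse(is.na(r$pct_change_deferrals), "NA",
                     sprintf("%+.1f", r$pct_change_deferrals))))
  cat(sprintf("  newly deferred: %.2f%% of assessed visits   net change in donations: %+.2f%%\n",
              r$pct_newly_deferred, r$pct_change_donations))
  cat(sprintf("  mean historical Hb of newly eligible donations (g/dL): male %s, female %s\n",
              ifelse(is.na(r$mean_hist_hb_newly_eligible_male), "-",
                     sprintf("%.2f", r$mean_hist_hb_newly_eligible_male)),
              ifelse(is.na(r$mean_hist_hb_newly_eligible_female), "-",
                     sprintf("%.2f", r$mean_hist_hb_newly_eligible_female))))
  invisible(x)
}

#' Tidy the per-visit assessments of a policy evaluation
#'
#' @param x An `hb_policy_eval` from [evaluate_policy()].
#' @param ... Unused.
#' @return The per-visit assessment tibble.
#' @export
tidy.hb_policy_eval <- function(x, ...) x$assessments

#' One-row summary of a policy evaluation
#'
#' @param x An `hb_policy_eval` from [evaluate_policy()].
#' @param ... Unused.
#' @return The one-row report tibble.
#' @export
glance.hb_policy_eval <- function(x, ...) x$report

#' Plot deferral-rate and donation-change profiles of a parameter sweep
#'
#' @param object An `hb_sweep` tibble from [sweep_parameters()].
#' @param ... Unused.
#' @return A ggplot: alternative deferral rate and net donation change
#'   against `alpha_mean`, one line per `alpha_outlier`.
#' @export
autoplot.hb_sweep <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c("rate_alt", "pct_change_donations")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = dplyr::recode(
      .data$metric,
      rate_alt = "Alternative deferral rate (%)",
      pct_change_donations = "Net change in donations (%)"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha_mean, y = .data$value,
                                  colour = factor(.data$alpha_outlier))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(alpha["mean"]), y = NULL,
                  colour = expression(alpha["outlier"])) +
    ggplot2::theme_minimal()
}

#' Donor career plot in control-chart style
#'
#' Shows one donor's Hb measurements over time, shaped by the current
#' policy's decision and coloured by the alternative rule's decision, with
#' the running historical mean, the confidence bound compared to the
#' threshold, the low-outlier cutoff and the legal threshold.
#'
#' @param assessments Assessment tibble from [assess_visits()] (or
#'   [tidy()] of an evaluation).
#' @param donor_id The donor to plot.
#' @param policy The [policy_config()] used, for the threshold line.
#' @return A ggplot object.
#' @export
plot_donor_career <- function(assessments, donor_id,
                              policy = policy_config()) {
  d <- assessments[assessments$donor_id == donor_id, ]
  if (nrow(d) == 0) stop("Donor not found: ", donor_id, call. = FALSE)
  thr <- threshold_for(d$sex[1], policy)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$visit_date)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hist_mean), colour = "grey40",
                       na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$outlier_cutoff),
                       colour = "grey40", linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$hb,
                                     shape = .data$current_decision,
                                     colour = .data$alt_decision), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(donate = 16, defer = 17)) +
    ggplot2::labs(x = NULL, y = "Hb (g/dL)",
                  shape = "Current policy", colour = "Alternative rule",
                  title = paste("Donor", donor_id)) +
    ggplot2::theme_minimal()
}

#' @export
print.hb_sigma <- function(x, ...) {
  cat("<hb_sigma> measurement variability (successive-difference estimator)\n")
  NextMethod()
}
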