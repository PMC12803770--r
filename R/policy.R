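#' Deferral policy configuration
#'
#' Constructs and validates the configuration of the historical-mean deferral
#' rule. The two confidence parameters control how conservative the rule is:
#'
#' * `alpha_mean` in (-1, 1) sets the two-sided confidence level
#'   (`|alpha_mean| * 100` percent) of the interval around the donor's
#'   historical mean Hb. With a negative value the *lower* bound of the
#'   interval is compared to the deferral threshold (conservative: defer when
#'   the mean might plausibly be below threshold); with `alpha_mean = 0` the
#'   historical mean itself is compared; with a positive value the *upper*
#'   bound is compared (lenient: defer only when the mean is demonstrably
#'   below threshold).
#' * `alpha_outlier` in (0.5, 1) sets the probability level of the low-outlier
#'   test on the current measurement: a measurement below
#'   `hist_mean - z(alpha_outlier) * sigma` is flagged. At 0.999 roughly 1 in
#'   1000 measurements from an in-control donor is flagged by chance.
#'
#' @param threshold_male,threshold_female Sex-specific legal deferral
#'   thresholds in g/dL. Defaults are the EU values 13.5 / 12.5.
#' @param alpha_mean Confidence parameter for the historical-mean test,
#'   in (-1, 1). Default 0 (compare the mean itself to the threshold).
#' @param alpha_outlier Probability level of the low-outlier test,
#'   in (0.5, 1). Default 0.999. Values at or below 0.5 would place the
#'   low-outlier cutoff at or above the mean and are rejected.
#' @param min_prior_measurements Minimum number of historical measurements
#'   before the rule can be applied; earlier visits are `not_assessed`.
#'   Default 2 (the rule cannot be applied before the third visit).
#' @param outlier_requires_below_threshold If `TRUE`, a reason-B deferral
#'   additionally requires the measurement to be below the legal threshold.
#'   Default `FALSE`: an outlier defers regardless of the threshold.
#' @param prediction_adjustment If `TRUE`, the outlier cutoff uses the
#'   prediction-interval standard error `sigma * sqrt(1 + 1/n_prior)`, which
#'   accounts for estimation error in the historical mean and makes the
#'   nominal false-positive rate `1 - alpha_outlier` exact at finite history
#'   length. Default `FALSE` (cutoff at `hist_mean - z * sigma`).
#' @param history_scope Which visits contribute measurements to the
#'   historical mean: `"all_visits"` (default; deferral visits' measurements
#'   are still informative) or `"donations_only"` (only visits where the
#'   donor donated under the current policy, i.e. Hb at or above threshold).
#' @param same_day_rule How repeated measurements on the same donor-date are
#'   collapsed at read time: `"max"` (default, mirroring establishments that
#'   record the highest of repeated measurements), `"min"` or `"mean"`.
#' @param units Unit of the `hb` column in input files: `"g_dL"` (default) or
#'   `"g_L"` (values are divided by 10 on read). Units are never
#'   auto-detected; silent rescaling is a data-integrity hazard.
#' @param max_history_length Maximum number of most recent historical
#'   measurements used for the mean (`Inf`, the default, uses the full
#'   career).
#' @param preset Optional name of a shipped country preset (see
#'   [country_presets()]); sets the two thresholds unless they are also given
#'   explicitly.
#'
#' @return An object of class `hb_policy` (a validated named list).
#' @seealso [load_policy()], [country_presets()], [assess_visits()]
#' @examples
#' policy_config()
#' policy_config(preset = "Netherlands", alpha_mean = -0.9)
#' @export
policy_config <- function(threshold_male = 13.5,
                          threshold_female = 12.5,
                          alpha_mean = 0,
                          alpha_outlier = 0.999,
                          min_prior_measurements = 2L,
                          outlier_requires_below_threshold = FALSE,
                          prediction_adjustment = FALSE,
                          history_scope = c("all_visits", "donations_only"),
                          same_day_rule = c("max", "min", "mean"),
                          units = c("g_dL", "g_L"),
                          max_history_length = Inf,
                          preset = NULL) {
  if (!is.null(preset)) {
    pre <- country_presets()
    row <- pre[tolower(pre$country) == tolower(preset), ]
    if (nrow(row) != 1L) {
      stop("Unknown preset '", preset, "'. Available: ",
           paste(pre$country, collapse = ", "), call. = FALSE)
    }
    if (missing(threshold_male)) threshold_male <- row$threshold_male
    if (missing(threshold_female)) threshold_female <- row$threshold_female
  }
  history_scope <- match.arg(history_scope)
  same_day_rule <- match.arg(same_day_rule)
  units <- match.arg(units)

  stopifnot(is.numeric(threshold_male), length(threshold_male) == 1L,
            is.numeric(threshold_female), length(threshold_female) == 1L)
  if (threshold_male <= 0 || threshold_female <= 0) {
    stop("Deferral thresholds must be positive (g/dL).", call. = FALSE)
  }
  if (!is.numeric(alpha_mean) || length(alpha_mean) != 1L ||
      !is.finite(alpha_mean) || abs(alpha_mean) >= 1) {
    stop("`alpha_mean` must lie strictly between -1 and 1 (got ",
         format(alpha_mean), ").", call. = FALSE)
  }
  if (!is.numeric(alpha_outlier) || length(alpha_outlier) != 1L ||
      !is.finite(alpha_outlier) ||
      alpha_outlier <= 0.5 || alpha_outlier >= 1) {
    stop("`alpha_outlier` must lie strictly between 0.5 and 1 (got ",
         format(alpha_outlier),
         "); levels at or below 0.5 place the low-outlier cutoff above ",
         "the mean.", call. = FALSE)
  }
  min_prior_measurements <- as.integer(min_prior_measurements)
  if (is.na(min_prior_measurements) || min_prior_measurements < 2L) {
    stop("`min_prior_measurements` must be an integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(max_history_length) || length(max_history_length) != 1L ||
      (is.finite(max_history_length) && max_history_length < min_prior_measurements)) {
    stop("`max_history_length` must be Inf or an integer >= `min_prior_measurements`.",
         call. = FALSE)
  }
  stopifnot(is.logical(outlier_requires_below_threshold),
            is.logical(prediction_adjustment))

  structure(
    list(
      threshold_male = as.numeric(threshold_male),
      threshold_female = as.numeric(threshold_female),
      alpha_mean = as.numeric(alpha_mean),
      alpha_outlier = as.numeric(alpha_outlier),
      min_prior_measurements = min_prior_measurements,
      outlier_requires_below_threshold = isTRUE(outlier_requires_below_threshold),
      prediction_adjustment = isTRUE(prediction_adjustment),
      history_scope = history_scope,
      same_day_rule = same_day_rule,
      units = units,
      max_history_length = max_history_length,
      preset = if (is.null(preset)) NA_character_ else as.character(preset)
    ),
    class = "hb_policy"
  )
}

#' @export
print.hb_policy <- function(x, ...) {
  cat("<hb_policy>\n")
  cat(sprintf("  thresholds (g/dL): male %.2f, female %.2f%s\n",
              x$threshold_male, x$threshold_female,
              if (!is.na(x$preset)) paste0(" [preset: ", x$preset, "]") else ""))
  cat(sprintf("  alpha_mean: %g   alpha_outlier: %g\n",
              x$alpha_mean, x$alpha_outlier))
  cat(sprintf("  min prior measurements: %d   history: %s%s\n",
              x$min_prior_measurements, x$history_scope,
              if (is.finite(x$max_history_length))
                paste0(" (last ", x$max_history_length, ")") else ""))
  cat(sprintf("  outlier: prediction_adjustment=%s, requires_below_threshold=%s\n",
              x$prediction_adjustment, x$outlier_requires_below_threshold))
  cat(sprintf("  same-day rule: %s   input units: %s\n",
              x$same_day_rule, x$units))
  invisible(x)
}

#' Load a deferral policy from a YAML key-value file
#'
#' Reads a YAML file whose keys are [policy_config()] arguments. Absent keys
#' take their defaults; a `preset` key selects a shipped country preset.
#' Unknown keys produce a warning (not an error) so that configuration files
#' can carry simulator settings alongside policy settings.
#'
#' @param path Path to a YAML file.
#' @return An `hb_policy` object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("preset: Netherlands", "alpha_outlier: 0.999"), f)
#' load_policy(f)
#' @export
load_policy <- function(path) {
  if (!file.exists(path)) stop("Policy file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("Policy file must be a YAML mapping.", call. = FALSE)
  known <- names(formals(policy_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    warning("Ignoring unknown policy key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    cfg <- cfg[intersect(names(cfg), known)]
  }
  do.call(policy_config, cfg)
}

#' Shipped country presets
#'
#' Deferral thresholds and minimum donation intervals for the blood
#' establishments whose policies the package ships as presets, together with
#' published sex-specific mean Hb levels and measurement standard deviations
#' usable as simulator defaults. Thresholds are in g/dL, intervals in days.
#'
#' @return A tibble with one row per country: `country`, `threshold_male`,
#'   `threshold_female`, `min_interval_male`, `min_interval_female`,
#'   `mean_hb_male`, `mean_hb_female`, `sd_hb_male`, `sd_hb_female`.
#' @examples
#' country_presets()
#' @export
country_presets <- function() {
  tibble::tribble(
    ~country,        ~threshold_male, ~threshold_female,
    ~min_interval_male, ~min_interval_female,
    ~mean_hb_male, ~mean_hb_female, ~sd_hb_male, ~sd_hb_female,
    "Australia",     13.0, 12.0,  84,  84, 14.84, 13.37, 0.71, 0.67,
    "Belgium",       13.5, 12.5,  60,  60, 15.19, 13.65, 0.49, 0.52,
    "Finland",       13.0, 12.0,  56,  56, 15.58, 13.89, 0.73, 0.73,
    "France",        13.0, 12.0,  56,  56, 15.13, 13.31, 0.53, 0.62,
    "Netherlands",   13.5, 12.5,  56, 122, 15.06, 13.54, 0.70, 0.67,
    "South Africa",  13.5, 12.5,  56,  56, 15.66, 13.70, 0.84, 0.83,
    "USA",           13.0, 12.5,  56,  56, 15.55, 13.68, 0.85, 0.79
  )
}

# threshold for each row's sex, vectorised
threshold_for <- function(sex, policy) {
  ifelse(sex == "male", policy$threshold_male, policy$threshold_female)
}
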