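#' Consecutive within-donor Hb differences
#'
#' Differences between successive measurements of one donor,
#' `hb[k+1] - hb[k]`, in chronological order. These differences are free of
#' the donor's (stable) level, so their spread reflects measurement
#' variability only -- the basis of [estimate_sigma()].
#'
#' @param hb Numeric vector of one donor's Hb values in chronological order.
#' @return Numeric vector of length `length(hb) - 1` (empty for fewer than
#'   two measurements).
#' @examples
#' consecutive_differences(c(14, 15, 14, 15))
#' @export
consecutive_differences <- function(hb) {
  stopifnot(is.numeric(hb))
  if (length(hb) < 2L) return(numeric(0))
  diff(hb)
}

#' Estimate Hb measurement variability from successive differences
#'
#' For each sex, pools all within-donor consecutive measurement differences
#' and estimates the measurement standard deviation as
#' \deqn{\hat\sigma = SD(differences) / \sqrt{2},}
#' using the sample (n-1) standard deviation. Because the differences are
#' within-donor, between-donor spread does not enter the estimate. The
#' estimate is an upper limit for the pure measurement variability: real
#' within-donor changes (e.g. incomplete post-donation recovery) inflate it.
#'
#' A sex with fewer than `min_pairs` pooled differences is flagged unusable;
#' downstream assessment refuses to run for that sex unless an explicit
#' override is supplied via [sigma_override()].
#'
#' @param visits A visits tibble ([read_visits()] / [simulate_population()]).
#' @param min_pairs Minimum pooled difference count per sex (default 30).
#' @param max_gap_days Optional maximum days between the two visits of a
#'   pair; pairs further apart are excluded (default `Inf`, no limit).
#' @return A tibble of class `hb_sigma` with one row per sex present in the
#'   data: `sex`, `sigma` (g/dL), `n_pairs`, `usable`.
#' @examples
#' pop <- simulate_population(sim_config(n_donors = 200, seed = 3))
#' estimate_sigma(pop)
#' @export
estimate_sigma <- function(visits, min_pairs = 30L, max_gap_days = Inf) {
  stopifnot(is.data.frame(visits), min_pairs >= 2L, max_gap_days > 0)
  diffs <- visits |>
    dplyr::arrange(.data$donor_id, .data$visit_date) |>
    dplyr::group_by(.data$donor_id, .data$sex) |>
    dplyr::summarise(
      d = list(if (dplyr::n() < 2L) numeric(0) else {
        dd <- diff(.data$hb)
        gap <- as.numeric(diff(.data$visit_date))
        dd[gap <= max_gap_days]
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest(dplyr::all_of("d"))

  out <- diffs |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      sigma = if (dplyr::n() >= 2L) stats::sd(.data$d) / sqrt(2) else NA_real_,
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(usable = !is.na(.data$sigma) & .data$n_pairs >= min_pairs)
  class(out) <- c("hb_sigma", class(out))
  out
}

#' Explicit measurement-variability override
#'
#' Builds an `hb_sigma` table from externally known measurement SDs, for use
#' when the dataset has too few visit pairs to estimate them, or when a
#' validated device SD should be imposed.
#'
#' @param male,female Measurement SD in g/dL for each sex (either may be
#'   omitted if that sex is absent from the data).
#' @return An `hb_sigma` tibble with `usable = TRUE` and `n_pairs = NA`.
#' @examples
#' sigma_override(male = 0.70, female = 0.67)
#' @export
sigma_override <- function(male = NULL, female = NULL) {
  rows <- list()
  if (!is.null(male)) rows <- c(rows, list(tibble::tibble(
    sex = "male", sigma = as.numeric(male), n_pairs = NA_integer_, usable = TRUE)))
  if (!is.null(female)) rows <- c(rows, list(tibble::tibble(
    sex = "female", sigma = as.numeric(female), n_pairs = NA_integer_, usable = TRUE)))
  if (length(rows) == 0) stop("Supply at least one of `male`, `female`.",
                              call. = FALSE)
  out <- dplyr::bind_rows(rows)
  if (any(out$sigma < 0)) stop("Measurement SDs must be >= 0.", call. = FALSE)
  class(out) <- c("hb_sigma", class(out))
  out
}

# resolve a per-row sigma vector for the sexes in `sex`;
# `sigma` is an hb_sigma tibble or a named numeric c(male=, female=)
sigma_lookup <- function(sigma, sex) {
  if (is.numeric(sigma) && !is.null(names(sigma))) {
    sigma <- do.call(sigma_override, as.list(sigma))
  }
  if (!is.data.frame(sigma) || !all(c("sex", "sigma") %in% names(sigma))) {
    stop("`sigma` must be an estimate_sigma()/sigma_override() table or a ",
         "named numeric like c(male = 0.7, female = 0.67).", call. = FALSE)
  }
  needed <- unique(sex)
  usable <- if ("usable" %in% names(sigma)) sigma$usable else TRUE
  available <- sigma$sex[usable & !is.na(sigma$sigma)]
  missing <- setdiff(needed, available)
  if (length(missing) > 0) {
    stop("No usable measurement SD for sex: ", paste(missing, collapse = ", "),
         ". Run estimate_sigma() on enough data or supply sigma_override().",
         call. = FALSE)
  }
  map <- stats::setNames(sigma$sigma, sigma$sex)
  unname(map[sex])
}
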