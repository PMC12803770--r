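#' Simulation configuration for synthetic donor careers
#'
#' Describes the generative model used by [simulate_population()]: each donor
#' carries a stable haematological setpoint \eqn{\mu_i \sim N(\mu_{sex},
#' \tau_{sex}^2)} (between-donor spread \eqn{\tau}); every visit measures
#' \eqn{\mu_i} with i.i.d. Gaussian noise of standard deviation
#' \eqn{\sigma_{sex}} (the measurement variability the deferral rule reasons
#' about); visits are spaced by the sex-specific minimum donation interval
#' plus a uniform jitter. Optionally a post-donation deficit is subtracted
#' that recovers linearly on a log-time scale:
#' \deqn{deficit(t) = dip \cdot \max(0, 1 - \log(1+t)/\log(1+T))}
#' for \eqn{t} days since the previous visit and full recovery at \eqn{T}
#' days.
#'
#' Per-sex parameters accept either a single number (used for both sexes) or
#' a named vector `c(male = ..., female = ...)`.
#'
#' @param n_donors Number of donors (>= 1).
#' @param prop_female Proportion of female donors in [0, 1].
#' @param pop_mean_hb Population mean Hb (g/dL) per sex.
#' @param between_donor_sd Between-donor SD of the setpoint (g/dL) per sex.
#' @param meas_sigma Measurement SD (g/dL) per sex.
#' @param visits_per_donor Either a single count (every donor) or a
#'   length-2 range `c(lo, hi)` sampled uniformly per donor.
#' @param min_interval_days Minimum days between visits, per sex.
#' @param interval_jitter_days Upper bound of the uniform whole-day jitter
#'   added to the minimum interval (>= 0).
#' @param recovery_enabled Subtract the post-donation deficit? Default
#'   `FALSE`, matching a variability estimator that ignores recovery.
#' @param recovery_dip Initial post-donation Hb drop in g/dL (default 1.5).
#' @param recovery_days Days to full recovery on the log-time ramp
#'   (default 168).
#' @param start_date Earliest possible first-visit date.
#' @param seed Integer seed; the population is a pure function of the
#'   configuration, and each donor has an independent stream derived from
#'   `(seed, donor index)`.
#' @return An object of class `hb_sim_config`.
#' @examples
#' sim_config(n_donors = 100, seed = 1)
#' @export
sim_config <- function(n_donors = 1000,
                       prop_female = 0.5,
                       pop_mean_hb = c(male = 15.06, female = 13.54),
                       between_donor_sd = c(male = 0.70, female = 0.60),
                       meas_sigma = c(male = 0.70, female = 0.67),
                       visits_per_donor = c(5, 15),
                       min_interval_days = c(male = 56, female = 122),
                       interval_jitter_days = 30,
                       recovery_enabled = FALSE,
                       recovery_dip = 1.5,
                       recovery_days = 168,
                       start_date = as.Date("2015-01-01"),
                       seed = 1L) {
  per_sex <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- c(male = unname(x), female = unname(x))
    }
    if (!all(c("male", "female") %in% names(x))) {
      stop("`", nm, "` must be a single value or named c(male=, female=).",
           call. = FALSE)
    }
    x[c("male", "female")]
  }
  n_donors <- as.integer(n_donors)
  stopifnot(n_donors >= 1L, prop_female >= 0, prop_female <= 1,
            interval_jitter_days >= 0, recovery_dip >= 0, recovery_days >= 1)
  pop_mean_hb <- per_sex(pop_mean_hb, "pop_mean_hb")
  between_donor_sd <- per_sex(between_donor_sd, "between_donor_sd")
  meas_sigma <- per_sex(meas_sigma, "meas_sigma")
  min_interval_days <- per_sex(min_interval_days, "min_interval_days")
  if (any(between_donor_sd < 0) || any(meas_sigma < 0)) {
    stop("Standard deviations must be non-negative.", call. = FALSE)
  }
  if (length(visits_per_donor) == 1L) {
    visits_per_donor <- rep(visits_per_donor, 2L)
  }
  stopifnot(length(visits_per_donor) == 2L,
            visits_per_donor[1] >= 1, visits_per_donor[2] >= visits_per_donor[1])

  structure(
    list(
      n_donors = n_donors,
      prop_female = prop_female,
      pop_mean_hb = pop_mean_hb,
      between_donor_sd = between_donor_sd,
      meas_sigma = meas_sigma,
      visits_per_donor = as.integer(round(visits_per_donor)),
      min_interval_days = min_interval_days,
      interval_jitter_days = interval_jitter_days,
      recovery_enabled = isTRUE(recovery_enabled),
      recovery_dip = recovery_dip,
      recovery_days = recovery_days,
      start_date = as.Date(start_date),
      seed = as.integer(seed)
    ),
    class = "hb_sim_config"
  )
}

# post-donation deficit, linear recovery on a log(time) scale
recovery_deficit <- function(t_days, dip, recovery_days) {
  dip * pmax(0, 1 - log1p(t_days) / log1p(recovery_days))
}

#' Simulate a population of donor careers
#'
#' Generates longitudinal Hb measurements under the stable-setpoint model
#' described in [sim_config()]. The output has the same shape as
#' [read_visits()] output and feeds directly into [estimate_sigma()] and
#' [evaluate_policy()]. The donors' true setpoints are attached as attribute
#' `"true_means"` (see [sim_true_means()]) for ground-truth checks.
#'
#' @param config An [sim_config()] object.
#' @return A visits tibble (`donor_id`, `sex`, `visit_date`, `hb`) sorted by
#'   donor and date.
#' @examples
#' pop <- simulate_population(sim_config(n_donors = 5, seed = 7))
#' head(pop)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "hb_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  sexes <- sample(c("female", "male"), cfg$n_donors, replace = TRUE,
                  prob = c(cfg$prop_female, 1 - cfg$prop_female))
  donor_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_donors)
  id_width <- max(6L, nchar(as.character(cfg$n_donors)))

  one_donor <- function(i) {
    set.seed(donor_seeds[i])
    sex <- sexes[i]
    mu <- rnorm(1, cfg$pop_mean_hb[[sex]], cfg$between_donor_sd[[sex]])
    m <- if (cfg$visits_per_donor[1] == cfg$visits_per_donor[2]) {
      cfg$visits_per_donor[1]
    } else {
      sample(cfg$visits_per_donor[1]:cfg$visits_per_donor[2], 1L)
    }
    origin <- cfg$start_date + floor(runif(1, 0, 365))
    gaps <- if (m > 1) {
      cfg$min_interval_days[[sex]] +
        floor(runif(m - 1, 0, cfg$interval_jitter_days + 1))
    } else numeric(0)
    dates <- origin + c(0, cumsum(gaps))
    deficit <- if (cfg$recovery_enabled && m > 1) {
      c(0, recovery_deficit(gaps, cfg$recovery_dip, cfg$recovery_days))
    } else rep(0, m)
    hb <- mu - deficit + rnorm(m, 0, cfg$meas_sigma[[sex]])
    tibble::tibble(
      donor_id = sprintf(paste0("D%0", id_width, "d"), i),
      sex = sex,
      visit_date = dates,
      hb = hb,
      .mu = mu
    )
  }

  visits <- purrr::map(seq_len(cfg$n_donors), one_donor) |> dplyr::bind_rows()
  true_means <- visits |>
    dplyr::distinct(.data$donor_id, .data$sex, mu = .data$.mu)
  visits <- visits |>
    dplyr::select(-dplyr::all_of(".mu")) |>
    dplyr::arrange(.data$donor_id, .data$visit_date)
  attr(visits, "true_means") <- true_means
  visits
}

#' True donor setpoints of a simulated population
#'
#' @param population A tibble from [simulate_population()].
#' @return A tibble `donor_id`, `sex`, `mu` (true mean Hb, g/dL).
#' @export
sim_true_means <- function(population) {
  tm <- attr(population, "true_means")
  if (is.null(tm)) stop("No true means attached; was this population ",
                        "produced by simulate_population()?", call. = FALSE)
  tm
}

#' Inject donors with consistently low mean Hb
#'
#' Shifts the true setpoint of a random subset of simulated donors to
#' `threshold(sex) - offset`, preserving each visit's measurement noise and
#' recovery structure. This creates the subpopulation of consistently-low
#' donors that the historical-mean rule is designed to newly defer even
#' though many of their single measurements pass the current policy.
#'
#' @param population A tibble from [simulate_population()].
#' @param fraction Fraction of donors to shift, in [0, 1].
#' @param offset How far below the sex-specific threshold the shifted
#'   setpoints sit, in g/dL (>= 0).
#' @param policy An [policy_config()] supplying the thresholds.
#' @param seed Integer seed for the subset draw.
#' @return The population with shifted measurements; the affected donor IDs
#'   are attached as attribute `"injected_donors"` (see [injected_donors()])
#'   and the `"true_means"` attribute is updated.
#' @examples
#' pop <- simulate_population(sim_config(n_donors = 50, seed = 1))
#' low <- inject_low_mean_donors(pop, fraction = 0.1, offset = 0.5, seed = 2)
#' injected_donors(low)
#' @export
inject_low_mean_donors <- function(population, fraction, offset,
                                   policy = policy_config(), seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, offset >= 0,
            inherits(policy, "hb_policy"))
  tm <- sim_true_means(population)
  set.seed(as.integer(seed))
  n_inject <- round(fraction * nrow(tm))
  ids <- if (n_inject > 0) sample(tm$donor_id, n_inject) else character(0)

  tm_new <- tm |>
    dplyr::mutate(mu_new = ifelse(.data$donor_id %in% ids,
                                  threshold_for(.data$sex, policy) - offset,
                                  .data$mu))
  shift <- stats::setNames(tm_new$mu_new - tm_new$mu, tm_new$donor_id)
  population$hb <- population$hb + unname(shift[population$donor_id])
  attr(population, "true_means") <- tm_new |>
    dplyr::select(dplyr::all_of(c("donor_id", "sex")), mu = dplyr::all_of("mu_new"))
  attr(population, "injected_donors") <- sort(ids)
  population
}

#' Donor IDs shifted by [inject_low_mean_donors()]
#'
#' @param population A tibble returned by [inject_low_mean_donors()].
#' @return Character vector of donor IDs.
#' @export
injected_donors <- function(population) {
  ids <- attr(population, "injected_donors")
  if (is.null(ids)) stop("No injected donors recorded on this population.",
                         call. = FALSE)
  ids
}
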