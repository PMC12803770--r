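# Independent oracles used across the suite. Everything here is deliberately
# naive: bisection instead of closed forms, per-visit recomputation from
# scratch instead of running sums, so the oracles cannot share a bug with the
# implementation.

# normal quantile by bisection of pnorm, to ~1e-10
oracle_quantile <- function(p) {
  lo <- -10
  hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# from-scratch single-visit decision, recomputing mean/bound/cutoff naively
oracle_assess <- function(prior_hbs, hb, sex, sigma, policy) {
  thr <- if (sex == "male") policy$threshold_male else policy$threshold_female
  if (is.finite(policy$max_history_length) &&
      length(prior_hbs) > policy$max_history_length) {
    prior_hbs <- prior_hbs[(length(prior_hbs) - policy$max_history_length + 1):
                             length(prior_hbs)]
  }
  n <- length(prior_hbs)
  current <- if (hb < thr) "defer" else "donate"
  if (n < policy$min_prior_measurements) {
    return(list(current = current, alt = "not_assessed",
                hist_mean = NA_real_, bound = NA_real_, cutoff = NA_real_))
  }
  hm <- sum(prior_hbs) / n
  bound <- if (policy$alpha_mean == 0) hm else {
    z <- oracle_quantile((1 + abs(policy$alpha_mean)) / 2)
    hm + sign(policy$alpha_mean) * z * sigma / sqrt(n)
  }
  a <- if (policy$prediction_adjustment) sqrt(1 + 1 / n) else 1
  cutoff <- hm - oracle_quantile(policy$alpha_outlier) * sigma * a
  alt <- if (bound < thr) "defer_A"
  else if (hb < cutoff &&
           (!policy$outlier_requires_below_threshold || hb < thr)) "defer_B"
  else "eligible"
  list(current = current, alt = alt, hist_mean = hm, bound = bound,
       cutoff = cutoff)
}

# visit-by-visit re-assessment of one donor's chronology, from scratch
oracle_assess_donor <- function(hbs, sex, sigma, policy) {
  thr <- if (sex == "male") policy$threshold_male else policy$threshold_female
  out <- vector("list", length(hbs))
  prior <- numeric(0)
  for (k in seq_along(hbs)) {
    out[[k]] <- oracle_assess(prior, hbs[k], sex, sigma, policy)
    keep <- if (policy$history_scope == "donations_only") hbs[k] >= thr else TRUE
    if (keep) prior <- c(prior, hbs[k])
  }
  out
}

# compact builder for a single-donor visits tibble
donor_visits <- function(hbs, sex = "male", id = "D1",
                         start = as.Date("2020-01-01"), by = 60) {
  tibble::tibble(
    donor_id = id,
    sex = sex,
    visit_date = start + by * (seq_along(hbs) - 1),
    hb = as.numeric(hbs)
  )
}

write_visits_file <- function(lines, sep = ",") {
  f <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  writeLines(gsub(",", sep, lines, fixed = TRUE), f)
  f
}
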