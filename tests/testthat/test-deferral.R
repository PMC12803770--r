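test_that("normal_quantile matches bisection inversion of the normal CDF", {
  for (p in c(0.5, 0.975, 0.99, 0.999, 0.9999, 0.025)) {
    expect_equal(normal_quantile(p), oracle_quantile(p), tolerance = 1e-8)
  }
  expect_equal(normal_quantile(0.5), 0)
  expect_equal(normal_quantile(0.999), 3.0902, tolerance = 1e-4)
  expect_equal(normal_quantile(0.975), 1.9600, tolerance = 1e-4)
  expect_error(normal_quantile(0), "between 0 and 1")
  expect_error(normal_quantile(1), "between 0 and 1")
})

test_that("mean_bound reproduces the hand-worked confidence bounds", {
  expect_equal(mean_bound(13.40, 5, 0.7, 0), 13.40) # alpha_mean 0: the mean
  expect_equal(mean_bound(13.6, 4, 0.7, -0.95), 12.914, tolerance = 1e-4)
  expect_equal(mean_bound(13.6, 4, 0.7, +0.95), 14.286, tolerance = 1e-4)
  # sign symmetry about the mean
  lo <- mean_bound(13.6, 4, 0.7, -0.6)
  hi <- mean_bound(13.6, 4, 0.7, 0.6)
  expect_equal((lo + hi) / 2, 13.6, tolerance = 1e-12)
  expect_error(mean_bound(13.6, 4, 0.7, 1), "between -1 and 1")
})

test_that("outlier_cutoff reproduces the hand-worked cutoffs", {
  expect_equal(outlier_cutoff(15, 0.7, 0.999), 12.837, tolerance = 1e-4)
  expect_equal(outlier_cutoff(15, 0.7, 0.999, n_prior = 4,
                              prediction_adjustment = TRUE),
               12.582, tolerance = 1e-4)
  expect_equal(outlier_cutoff(15, 0, 0.999), 15) # sigma 0: cutoff at mean
  # against the naive oracle at arbitrary settings
  expect_equal(outlier_cutoff(14.1, 0.53, 0.99, 7, TRUE),
               14.1 - oracle_quantile(0.99) * 0.53 * sqrt(1 + 1 / 7),
               tolerance = 1e-8)
  expect_error(outlier_cutoff(15, 0.7, 0.4), "between 0.5 and 1")
  expect_error(outlier_cutoff(15, 0.7, 0.999, prediction_adjustment = TRUE),
               "n_prior")
})

test_that("single-visit decisions follow the two-reason rule", {
  pol <- policy_config() # thresholds 13.5/12.5, alpha_mean 0, outlier 0.999
  # reason A: historical mean below threshold
  a <- assess_visit(c(13.0, 13.0), hb = 14.0, sex = "male", sigma = 0.7, pol)
  expect_equal(a$alt_decision, "defer_A")
  expect_equal(a$reason, "A")
  expect_equal(a$current_decision, "donate")
  # unnecessary current deferral: low-but-not-outlying measurement
  b <- assess_visit(rep(15, 10), hb = 13.0, sex = "male", sigma = 0.7, pol)
  expect_equal(b$current_decision, "defer")
  expect_equal(b$alt_decision, "eligible")
  # reason B: genuine low outlier
  c_ <- assess_visit(rep(15, 10), hb = 12.5, sex = "male", sigma = 0.7, pol)
  expect_equal(c_$alt_decision, "defer_B")
  expect_equal(c_$reason, "B")
  # equality at threshold is eligible under the current policy
  d <- assess_visit(rep(15, 10), hb = 13.5, sex = "male", sigma = 0.7, pol)
  expect_equal(d$current_decision, "donate")
  # too little history
  e <- assess_visit(c(15), hb = 15, sex = "male", sigma = 0.7, pol)
  expect_equal(e$alt_decision, "not_assessed")
  expect_equal(e$reason, "NA")
})

test_that("strict mode additionally requires the measurement below threshold", {
  pol <- policy_config(outlier_requires_below_threshold = TRUE)
  # an outlier that is still above the legal threshold
  a <- assess_visit(rep(17.5, 10), hb = 14.0, sex = "male", sigma = 0.7, pol)
  expect_equal(a$alt_decision, "eligible")
  a2 <- assess_visit(rep(17.5, 10), hb = 13.0, sex = "male", sigma = 0.7, pol)
  expect_equal(a2$alt_decision, "defer_B")
  # default mode flags both
  a3 <- assess_visit(rep(17.5, 10), hb = 14.0, sex = "male", sigma = 0.7,
                     policy_config())
  expect_equal(a3$alt_decision, "defer_B")
})

test_that("the first visits are never assessed and counts start at three", {
  a <- assess_visits(donor_visits(c(15, 15)), sigma_override(male = 0.7))
  expect_equal(a$alt_decision, c("not_assessed", "not_assessed"))
  b <- assess_visits(donor_visits(rep(14.5, 5)), sigma_override(male = 0.7))
  expect_equal(b$alt_decision,
               c("not_assessed", "not_assessed", "eligible", "eligible",
                 "eligible"))
  pol4 <- policy_config(min_prior_measurements = 4)
  c_ <- assess_visits(donor_visits(rep(14.5, 6)), sigma_override(male = 0.7),
                      pol4)
  expect_equal(sum(c_$alt_decision == "not_assessed"), 4L)
})

test_that("vectorised assessment matches the from-scratch oracle", {
  set.seed(99)
  policies <- list(
    policy_config(),
    policy_config(alpha_mean = -0.9, alpha_outlier = 0.99,
                  prediction_adjustment = TRUE),
    policy_config(alpha_mean = 0.8, outlier_requires_below_threshold = TRUE),
    policy_config(history_scope = "donations_only"),
    policy_config(max_history_length = 4)
  )
  for (pol in policies) {
    for (rep_i in 1:6) {
      sex <- sample(c("male", "female"), 1)
      thr <- if (sex == "male") pol$threshold_male else pol$threshold_female
      hbs <- round(rnorm(sample(3:12, 1), thr + rnorm(1, 0.8, 0.5), 0.8), 2)
      sigma <- runif(1, 0.4, 0.9)
      got <- assess_visits(donor_visits(hbs, sex = sex),
                           c(male = sigma, female = sigma), pol)
      want <- oracle_assess_donor(hbs, sex, sigma, pol)
      expect_equal(got$alt_decision, vapply(want, `[[`, "", "alt"))
      expect_equal(got$current_decision, vapply(want, `[[`, "", "current"))
      expect_equal(got$hist_mean, vapply(want, `[[`, 0, "hist_mean"),
                   tolerance = 1e-9)
      expect_equal(got$ci_bound, vapply(want, `[[`, 0, "bound"),
                   tolerance = 1e-9)
      expect_equal(got$outlier_cutoff, vapply(want, `[[`, 0, "cutoff"),
                   tolerance = 1e-9)
    }
  }
})

test_that("running-mean histories match naive recomputation to 1e-9", {
  set.seed(7)
  hbs <- rnorm(200, 15, 1)
  got <- assess_visits(donor_visits(hbs), sigma_override(male = 0.7))
  naive <- vapply(seq_along(hbs), function(k) {
    if (k <= 2) NA_real_ else mean(hbs[1:(k - 1)])
  }, 0)
  expect_equal(got$hist_mean, naive, tolerance = 1e-9)
})

test_that("raising alpha_outlier never creates new reason-B deferrals", {
  set.seed(11)
  pop <- simulate_population(sim_config(n_donors = 120, seed = 11))
  sg <- sigma_override(male = 0.7, female = 0.67)
  levels <- c(0.99, 0.999, 0.9999)
  flags <- lapply(levels, function(ao) {
    a <- assess_visits(pop, sg, policy_config(alpha_outlier = ao))
    a$alt_decision == "defer_B"
  })
  expect_true(all(flags[[2]] <= flags[[1]]))
  expect_true(all(flags[[3]] <= flags[[2]]))
})

test_that("raising alpha_mean never creates new reason-A deferrals", {
  set.seed(13)
  pop <- simulate_population(sim_config(n_donors = 120, seed = 13))
  sg <- sigma_override(male = 0.7, female = 0.67)
  grid <- c(-0.99, -0.5, 0, 0.5, 0.99)
  flags <- lapply(grid, function(am) {
    a <- assess_visits(pop, sg, policy_config(alpha_mean = am))
    a$alt_decision == "defer_A"
  })
  for (i in 2:length(grid)) {
    expect_true(all(flags[[i]] <= flags[[i - 1]]))
  }
})

test_that("with sigma zero the rule reduces to mean-below-threshold", {
  set.seed(17)
  hbs <- rnorm(30, 13.6, 0.5)
  a <- assess_visits(donor_visits(hbs), sigma_override(male = 0),
                     policy_config(alpha_mean = -0.9))
  assessed <- a$alt_decision != "not_assessed"
  expect_equal(a$alt_decision[assessed] == "defer_A",
               a$hist_mean[assessed] < 13.5)
  expect_false(any(a$alt_decision == "defer_B" & a$hb >= a$hist_mean))
})

test_that("donations_only history excludes current-policy deferral visits", {
  # visit 3 (12.0) is a current deferral; under donations_only it must not
  # enter later means
  hbs <- c(15, 15, 12, 15, 15)
  a <- assess_visits(donor_visits(hbs), sigma_override(male = 0.7),
                     policy_config(history_scope = "donations_only"))
  expect_equal(a$n_prior, c(0L, 1L, 2L, 2L, 3L))
  expect_equal(a$hist_mean[4], 15)
  b <- assess_visits(donor_visits(hbs), sigma_override(male = 0.7))
  expect_equal(b$hist_mean[4], mean(c(15, 15, 12)))
})

test_that("max_history_length keeps only the most recent measurements", {
  hbs <- c(12, 12, 12, 15, 15, 15, 15)
  a <- assess_visits(donor_visits(hbs), sigma_override(male = 0.7),
                     policy_config(max_history_length = 3))
  expect_equal(a$n_prior, c(0L, 1L, 2L, 3L, 3L, 3L, 3L))
  expect_equal(a$hist_mean[7], 15) # the three low visits have scrolled out
})

test_that("assess_donor insists on a single donor", {
  pop <- simulate_population(sim_config(n_donors = 2, seed = 1))
  expect_error(assess_donor(pop, sigma_override(male = 0.7, female = 0.67)),
               "one donor")
})
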