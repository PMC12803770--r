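---
title: "Methods: historical-mean haemoglobin deferral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: historical-mean haemoglobin deferral}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdefer)
```

## The decision model

A donor's screening measurements are modelled as
$$x_{ik} = \mu_i + \varepsilon_{ik}, \qquad \varepsilon_{ik} \sim N(0, \sigma^2_{sex}),$$
an individual haematological *setpoint* $\mu_i$ that is stable over the
donor's career, observed through i.i.d. Gaussian measurement noise whose
standard deviation $\sigma$ is a property of the establishment's measurement
method (device, sample origin, pre-analytics) plus short-term biological
fluctuation. Under this model a single measurement is a poor basis for an
eligibility decision whenever the threshold margin $|\mu_i - T|$ is
comparable to $\sigma$ — which for capillary devices
($\sigma \approx 0.7$ g/dL) it often is.

The alternative rule treats the donor like a control chart whose centre line
is the historical mean $\bar x_i$ of the $n$ *prior* measurements:

* **Reason A (mean below threshold).** Compare a confidence bound on
  $\mu_i$ to the threshold $T_{sex}$:
  $$\bar x_i + \operatorname{sign}(\alpha_{mean})\,
    z_{(1+|\alpha_{mean}|)/2}\; \sigma/\sqrt{n} \;<\; T.$$
  $\alpha_{mean} < 0$ compares the lower bound (defer when the mean *might*
  be below threshold), $\alpha_{mean} = 0$ the mean itself, and
  $\alpha_{mean} > 0$ the upper bound (defer only when the mean is
  *demonstrably* below threshold).
* **Reason B (low outlier).** If the mean passes, flag the day's measurement
  $y$ when
  $$y < \bar x_i - z_{\alpha_{outlier}}\, \sigma \, a, \qquad
    a = \begin{cases}\sqrt{1 + 1/n} & \text{prediction adjustment on}\\
    1 & \text{otherwise.}\end{cases}$$

Reason A is checked first; a visit can carry only one deferral reason. The
rule needs `min_prior_measurements` (default 2) prior values, so a donor's
first two visits are `not_assessed` and excluded from all evaluation counts
and denominators.

The *current* policy is reconstructed as: defer iff the measurement is
strictly below $T_{sex}$; equality donates. Deferral periods and minimum
donation intervals are deliberately ignored in the retrospective
re-labelling — the evaluation is static, asking how each recorded visit
*would* have been decided, without propagating decisions into counterfactual
careers.

## Estimating the measurement variability

$\sigma$ is estimated per sex by pooling all within-donor consecutive
measurement differences $d = x_{k+1} - x_k$ and taking
$$\hat\sigma = \mathrm{SD}(d) / \sqrt 2,$$
since the difference of two independent equally-noisy measurements has
variance $2\sigma^2$. Differences are pooled across donors into a single SD
(the standard successive-difference estimator) rather than averaging
per-donor SDs; the sample ($n-1$) SD is used, a vanishing distinction at
registry scale. Because differencing removes $\mu_i$, between-donor spread
does not leak into $\hat\sigma$ (tested as a shift-invariance property).

$\hat\sigma$ is an *upper limit*: any real within-donor change — incomplete
post-donation recovery above all — inflates the differences. No recovery
correction is applied; the simulator's recovery switch exists precisely to
quantify that upward bias (it is small at realistic settings). Pairs
spanning a deferral visit are included, since all measurements are
informative about the method's variability; `max_gap_days` can exclude
long-separated pairs as a sensitivity option. A sex with fewer than
`min_pairs` (default 30) differences is flagged unusable and downstream
assessment refuses to run without an explicit `sigma_override()` — silently
proceeding with a two-point SD would be worse than stopping.

## Policy parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold_male`, `threshold_female` | 13.5, 12.5 | g/dL | legal deferral thresholds (EU values; presets ship others) |
| `alpha_mean` | 0 | — | confidence level and side of the mean test, in (−1, 1) |
| `alpha_outlier` | 0.999 | — | outlier probability level, in (0.5, 1); 0.999 ⇒ 1 per 1000 false flags |
| `min_prior_measurements` | 2 | count | history needed before the rule applies |
| `prediction_adjustment` | FALSE | — | widen the outlier cutoff by √(1+1/n) |
| `outlier_requires_below_threshold` | FALSE | — | strict mode for reason B |
| `history_scope` | all_visits | — | which measurements enter the mean |
| `max_history_length` | Inf | count | rolling window over the most recent measurements |

`alpha_outlier` values at or below 0.5 would place the low cutoff at or
above the mean and are rejected as nonsensical, which is why the accepted
interval is (0.5, 1) rather than (0, 1).

## Design choices that the problem leaves open

Several conventions are not forced by the decision rule itself; the package
fixes each one explicitly and offers the alternative as an option where it
is scientifically meaningful:

* **Two-sided interval, one bound compared.** The mean test uses the
  two-sided $|\alpha_{mean}|\cdot100\%$ interval, with the sign of
  $\alpha_{mean}$ selecting the bound. This makes the parameter continuous
  through 0 and symmetric: the lower bound at $\alpha$ and the upper bound
  at $-\alpha$ mirror each other around $\bar x$.
* **The current measurement never enters its own reference mean.** The
  outlier test judges the new observation against the prior mean; letting
  $y$ into $\bar x$ would shrink its own deviation. No option is offered —
  one auditable convention.
* **Reason B does not require $y < T$ by default.** The outlier test guards
  the donor against an anomalous drop regardless of where the threshold
  sits; a strict mode adds the threshold requirement for establishments that
  only ever defer below the legal limit.
* **Deferral visits' measurements stay in the history**
  (`history_scope = "all_visits"`): a measurement is informative about
  $\mu_i$ whether or not the visit yielded a donation. `donations_only` is
  provided for sensitivity.
* **Equality at the threshold donates**, under both policies.
* **Same-day repeats collapse to the maximum** by default (several
  establishments record the highest of repeated measurements); `min` and
  `mean` are options. Date ties break by input row order.
* **Units are never auto-detected** (`units = "g_L"` must be set
  explicitly); a plausibility range of 5–25 g/dL rejects mis-scaled rows.
* **Evaluation denominators.** Deferral rates and the newly-deferred share
  are percentages of all assessed visits; the change in donations is a
  percentage of *current donations* (assessed visits minus current
  deferrals). With `d_alt − d_cur = newly_deferred − newly_eligible`
  enforced as an exact integer identity, the donation change equals
  $(rate_{cur} − rate_{alt})/(1 − rate_{cur}/100)$, which is how the two
  reported percentages relate despite their different denominators.
* **Missing-Hb rows** (e.g. non-Hb deferrals) are rejected at read time and
  counted in the validation report; the model has no use for a visit
  without a measurement.

## The synthetic donor generator

`simulate_population()` generates exactly the structure the rule's
probability statements assume — stable setpoint plus i.i.d. Gaussian noise —
which makes it the correct test bed for the rule's calibration, and an
honest statement of what the tests do and do not show.

Defaults (per-sex where applicable), chosen once as a realistic capillary
setting: population mean Hb 15.06 / 13.54 g/dL (male/female), measurement
SD 0.70 / 0.67 g/dL, between-donor setpoint SD 0.70 / 0.60 g/dL, minimum
intervals 56 / 122 days with up to 30 days of uniform jitter, 5–15 visits
per donor. The male between-donor SD gives a total measurement SD of
≈ 0.99 g/dL — about the population reference spread — and an implied
current-policy male deferral rate near 5%, in line with published registry
rates at the 13.5 g/dL threshold.

The optional post-donation deficit follows
$deficit(t) = dip \cdot \max(0,\, 1 - \log(1+t)/\log(1+T_{rec}))$ — a linear
recovery on the log-time scale — with defaults $dip = 1.5$ g/dL and
$T_{rec} = 168$ days (donor-study literature places full Hb recovery at up
to ~24 weeks for a substantial minority of donors). It is off by default,
matching the variability estimator's assumption; switching it on provides
the upper-limit check on $\hat\sigma$.

Each donor draws from an independent RNG stream derived from
`(seed, donor index)`, so a population is a pure, reproducible function of
its configuration even if generation were parallelised.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real registries:

* **Survivorship and deferral dynamics.** Real donor panels are depleted of
  low-Hb donors (they are deferred for months, or quit); a static Gaussian
  cross-section is not. The effect is strongest for women, whose threshold
  margin is smaller: the generator's female stratum implies a current
  deferral rate around 12%, higher than the ~4–8% registries report.
  Population-level checks in the test suite therefore run on the male
  stratum.
* Setpoint drift (age, menopause, season), iron-store depletion over rapid
  donation sequences, device changes mid-career, and donor return behaviour.

## Numerical and degenerate-input conventions

Normal quantiles come from `qnorm` (validated wrapper `normal_quantile()`);
the test suite checks them against an independent bisection inversion of the
normal CDF. Historical means are computed by grouped cumulative sums; a
property test requires equality with naive per-visit recomputation to
1e−9 g/dL. `sigma = 0` collapses the rule to "defer iff historical mean
below threshold" with the outlier cutoff at the mean itself. A dataset where
no visit has enough history is an error, not an empty report;
`pct_change_deferrals` is `NA` (an explicit undefined marker, never a
number) when there are no current deferrals to change. Presentation rounding
(2 decimals for rates, 1 for the deferral change) happens only at print
time; all stored values are exact.

## Problem sizes used by the test suite

The statistical checks run at sizes chosen so that Monte-Carlo error is
comfortably inside the asserted tolerances: outlier-rate calibration on
2,000 donors × 100 visits (196,000 assessed visits; 3 binomial SEs ≈ 2.1e−4
around the nominal 0.001); variability recovery on 10,000 donors × 10
visits (≈ 90,000 pairs; SE of $\hat\sigma$ ≈ 0.0017 g/dL); the
consistently-low-donor scenario on 3,000 male donors × 25 visits with 1% of
setpoints placed 0.5 g/dL below threshold. The structural identity and
monotonicity properties run over 100 small random populations, since they
must hold exactly at any size.

## Limitations

The evaluation is a static re-labelling: it cannot say how deferral-rate
reductions would propagate through donor return behaviour, iron stores, or
collection planning, and it gives no guidance for a donor's first two
visits. $\hat\sigma$ is population-level per sex; donors with atypical
personal variability are judged against the population's. These are
boundaries of the method, not of the implementation.
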