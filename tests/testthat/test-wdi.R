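test_that("half-life multiplier converts ten half-lives to whole days", {
  est <- wdi_hlm(228.1)
  expect_equal(est$raw_wdi, 2281 / 24, tolerance = 1e-12)
  expect_equal(est$rounded_wdi, 96L)
  expect_equal(wdi_hlm(24)$raw_wdi, 10)
  expect_equal(wdi_hlm(24)$rounded_wdi, 10L)
  expect_equal(wdi_hlm(2.4)$rounded_wdi, 1L)
  # exact inverse identity before rounding
  for (t in c(1, 7.3, 100, 228.1))
    expect_equal(wdi_hlm(t)$raw_wdi * 24 / 10, t)
  expect_error(wdi_hlm(-1), "positive")
})

test_that("withdrawal intervals round up to the next whole day", {
  expect_equal(round_up_wdi(80.6), 81L)
  expect_equal(round_up_wdi(101.7), 102L)
  expect_equal(round_up_wdi(57.0), 57L)
  expect_error(round_up_wdi(-0.1), "negative")
})

test_that("the PAR calculator reproduces the ADI-based worked example", {
  expect_equal(compute_par(5, 60, 0.20, 0.1), 600)
  # identity scaling: full partition, consumption numerically equal to bodyweight
  expect_equal(compute_par(5, 60, 1.0, 60), 5)
  expect_equal(compute_par(10, 60, 0.20, 0.1), 2 * compute_par(5, 60, 0.20, 0.1))
  expect_error(compute_par(5, 60, 1.5, 0.1), "partition")
})

test_that("residue limits encode the MRL substitution rules", {
  expect_equal(residue_limit("two_times_lloq", limits = yolk_limits)$value, 0.15)
  expect_equal(residue_limit("lod", limits = yolk_limits)$value, 0.03)
  expect_equal(residue_limit("explicit_mrl", value = 600)$value, 600)
  expect_error(residue_limit("explicit_mrl"), "value")
})

test_that("zero-variance fits cross the limit at the analytic time", {
  fit <- depletion_fit(exact_line_data(c(5, 20, 35, 50), log(100), -0.1))
  est <- wdi_from_tolerance(fit, 1)
  expect_equal(est$raw_wdi, log(100) / 0.1, tolerance = 0.01)
  expect_equal(est$rounded_wdi, 47L)
  # already compliant at t = 0
  expect_equal(wdi_from_tolerance(fit, 100)$raw_wdi, 0)
  expect_equal(wdi_from_tolerance(fit, 100)$rounded_wdi, 0L)
  expect_error(wdi_from_tolerance(fit, 1e-12, window = 100), "never reaches")
  up <- depletion_fit(data.frame(time = 1:6, value = exp(0.1 * (1:6))))
  expect_error(wdi_from_tolerance(up, 1), "not evident")
})

test_that("a lower residue limit never shortens the interval", {
  for (seed in 1:8) {
    set.seed(400 + seed)
    times <- rep(seq(10, 60, by = 10), each = 4)
    d <- data.frame(time = times,
                    value = exp(runif(1, 1, 3) - runif(1, 0.05, 0.2) * times +
                                  rnorm(length(times), 0, runif(1, 0.05, 0.5))))
    fit <- depletion_fit(d)
    w_low <- wdi_from_tolerance(fit, 0.03, window = 1000)$raw_wdi
    w_high <- wdi_from_tolerance(fit, 0.15, window = 1000)$raw_wdi
    expect_gte(w_low, w_high)
  }
})

test_that("the 99th-percentile interval is at least the 95th on the same window", {
  set.seed(77)
  times <- rep(seq(10, 40, by = 5), each = 10) # exactly 7 timepoints
  d <- data.frame(time = times,
                  value = exp(3 - 0.12 * times + rnorm(length(times), 0, 0.3)))
  fda <- wdi_fda(d, residue_limit("lod", limits = yolk_limits))
  ema <- wdi_ema(d, residue_limit("lod", limits = yolk_limits))
  # the 7-timepoint restriction is the identity here: same fitted line
  expect_equal(coef(ema$diagnostics$fit), coef(fda$diagnostics$fit))
  expect_gte(fda$raw_wdi, ema$raw_wdi)
})

test_that("EMA data checks flag lack of fit and pass perfect log-linear data", {
  clean <- exact_line_data(seq(10, 40, by = 5), 2, -0.08, reps = 5)
  est <- wdi_ema(clean, residue_limit("lod", limits = yolk_limits))
  expect_equal(est$diagnostics$lack_of_fit$F, 0)
  expect_equal(est$diagnostics$lack_of_fit$p, 1)
  expect_length(est$diagnostics$warnings, 0)
  # strongly curved data with replicate scatter must warn
  set.seed(12)
  times <- rep(seq(10, 40, by = 5), each = 8)
  curved <- data.frame(time = times,
                       value = exp(5 - 0.3 * times + 0.004 * times^2 +
                                     rnorm(length(times), 0, 0.05)))
  expect_warning(wdi_ema(curved, residue_limit("lod", limits = yolk_limits),
                         window = 2000),
                 "lack of fit")
})

test_that("only the final seven timepoints enter the EMA fit", {
  times <- seq(5, 60, by = 5) # 12 timepoints
  d <- exact_line_data(times, 2, -0.06, reps = 3)
  est <- wdi_ema(d, residue_limit("lod", limits = yolk_limits))
  expect_equal(est$diagnostics$timepoints_used, utils::tail(times, 7))
  expect_equal(est$diagnostics$fit$n, 21L)
})

test_that("seed-42 synthetic flock yields stable, limit-ordered interval estimates", {
  flock <- suppressMessages(apply_blq_policy(simulate_flock()))
  tps <- summarize_timepoints(flock, min_n = 5L, from_time = 7)
  aug <- augment_timepoints(tps, target_n = 10L, lod = 0.03, seed = 42L)
  w_lod <- wdi_fda(aug, residue_limit("lod", limits = yolk_limits))
  w_2lloq <- wdi_fda(aug, residue_limit("two_times_lloq", limits = yolk_limits))
  expect_gt(w_lod$raw_wdi, w_2lloq$raw_wdi)
  # frozen regression constants from the first verified run
  expect_equal(w_lod$raw_wdi, FROZEN_FDA_LOD, tolerance = 1e-6)
  expect_equal(w_2lloq$raw_wdi, FROZEN_FDA_2LLOQ, tolerance = 1e-6)
})

test_that("a shallow terminal window inverts the EMA/FDA ordering", {
  # steep early depletion, then the last seven timepoints hover just above
  # the limit with a shallow slope
  early <- exact_line_data(seq(8, 28, by = 4), log(30), -0.18, reps = 10)
  late_times <- seq(34, 70, by = 6)
  late <- exact_line_data(late_times, log(0.35) + 0.015 * 34, -0.015, reps = 10)
  set.seed(5)
  jitter <- function(d) { d$value <- d$value * exp(rnorm(nrow(d), 0, 0.15)); d }
  aug <- rbind(jitter(early), jitter(late))
  limit <- residue_limit("lod", limits = yolk_limits)
  fda <- wdi_fda(aug, limit, window = 2000)
  ema <- suppressWarnings(wdi_ema(aug, limit, window = 2000))
  expect_gt(ema$raw_wdi, fda$raw_wdi)
})
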