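test_that("observed peak reads Cmax/Tmax from the data with earliest-tie rule", {
  s <- make_series(c(0, 1, 2), c(0.5, 2.0, 1.0))
  expect_equal(observed_peak(s), c(cmax = 2.0, tmax = 1))
  tie <- make_series(c(1, 2), c(3.0, 3.0))
  expect_equal(observed_peak(tie), c(cmax = 3.0, tmax = 1))
  expect_error(observed_peak(make_series(numeric(), numeric())), "empty")
})

test_that("observed peak of a noise-free hen matches the latent-curve argmax", {
  cfg <- noise_free_config()
  flock <- simulate_flock(cfg)
  peak <- observed_peak(residue_series(flock, "hen1"))
  tt <- seq(0, 90, by = 0.001)
  C <- yolk_concentration(attr(flock, "truth")$hens[1, ], cfg$regimen, tt)
  # within half the (daily) lay interval of the dense grid argmax
  expect_lt(abs((peak[["tmax"]] + 7) - tt[which.max(C)]), 0.5)
})

test_that("terminal best-fit reproduces an exact exponential and the half-life identity", {
  # C(t) = 10 exp(-0.1 t), t in hours 0..10
  t_h <- 0:10
  s <- make_series(t_h / 24, 10 * exp(-0.1 * t_h))
  fit <- fit_terminal(s)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$n_points, 10L) # Tmax point excluded, ties -> larger k
  expect_equal(fit$t_half * fit$lambda_z, log(2))
  expect_equal(log(2) / 0.00304, 228.0, tolerance = 0.05)
  expect_error(fit_terminal(make_series(c(0, 1, 2) / 24, c(3, 2, 1))),
               "insufficient data")
  # early peak followed by rising values: candidates exist but none decline
  expect_error(fit_terminal(make_series((0:4) / 24, c(5, 1, 2, 3, 4))),
               "no terminal phase")
  # monotone rise leaves no post-peak points at all
  expect_error(fit_terminal(make_series((0:5) / 24, c(1, 2, 3, 4, 5, 6))),
               "insufficient data")
})

test_that("manual point selection fits the requested points", {
  t_h <- 0:10
  s <- make_series(t_h / 24, 10 * exp(-0.05 * t_h))
  fit <- fit_terminal(s, selection = 6:11)
  expect_equal(fit$lambda_z, 0.05, tolerance = 1e-10)
  expect_equal(fit$n_points, 6L)
})

test_that("trapezoidal AUC matches closed forms and the extrapolation identity", {
  fit01 <- list(lambda_z = 0.01)
  # rectangle: 1 ng/g held over 1 day = 24 h*ng/g
  rect <- auc_linear(make_series(c(0, 1), c(1, 1)), fit01)
  expect_equal(rect[["auc_last"]], 24)
  # triangle: 0 -> 2 ng/g over 2 days = 48 h*ng/g
  tri <- auc_linear(make_series(c(0, 2), c(0, 2)), fit01)
  expect_equal(tri[["auc_last"]], 48)
  # tail C_last/lambda_z = 0.1/0.01 = 10
  tail_case <- auc_linear(make_series(c(0, 1), c(1, 0.1)), fit01)
  expect_equal(tail_case[["auc_inf"]] - tail_case[["auc_last"]], 10)
  expect_equal(tail_case[["pct_extrapolated"]],
               100 * 10 / tail_case[["auc_inf"]])
})

test_that("noise-free mono-exponential extrapolation equals the analytic tail fraction", {
  lam <- 0.02 # 1/h
  t_h <- seq(0, 240, by = 24)
  s <- make_series(t_h / 24, 5 * exp(-lam * t_h))
  fit <- fit_terminal(s)
  a <- auc_linear(s, fit)
  # analytic: tail = C_last/lam; trapezoid slightly overestimates auc_last
  tail_true <- 5 * exp(-lam * 240) / lam
  expect_equal(a[["auc_inf"]] - a[["auc_last"]], tail_true, tolerance = 1e-6)
  expect_lt(a[["pct_extrapolated"]], 100)
  # row order does not matter once the series is rebuilt sorted
  shuffle <- sample(length(t_h))
  s2 <- make_series(t_h[shuffle] / 24, (5 * exp(-lam * t_h))[shuffle])
  s2 <- s2[order(s2$time), ]
  expect_equal(auc_linear(s2, fit)[["auc_inf"]], a[["auc_inf"]])
})

test_that("flock summary uses geometric means with ranges", {
  ph <- data.frame(hen_id = c("a", "b"),
                   cmax = c(1, 100), tmax_h = c(10, 20),
                   lambda_z = c(0.01, 0.01), t_half_h = c(142.2, 297.3),
                   auc_last = c(1, 1), auc_inf = c(2, 2),
                   pct_extrapolated = c(1, 1),
                   n_terminal = c(3L, 3L), adj_r2 = c(1, 1))
  s <- summary(structure(list(per_hen = ph, fits = list(), matrix = "yolk"),
                         class = "nca"))
  expect_equal(s$geo_mean[s$parameter == "cmax"], 10)
  expect_equal(s$geo_mean[s$parameter == "t_half_h"], 205.6, tolerance = 0.05)
  # geometric mean lies inside the range (up to floating-point rounding)
  expect_true(all(s$geo_mean >= s$min * (1 - 1e-12) &
                    s$geo_mean <= s$max * (1 + 1e-12)))
  # single-hen degenerate summary
  s1 <- summary(structure(list(per_hen = ph[1, ], fits = list(),
                               matrix = "yolk"), class = "nca"))
  expect_equal(s1$geo_mean[s1$parameter == "cmax"], 1)
  expect_equal(s1$min[s1$parameter == "cmax"], s1$max[s1$parameter == "cmax"])
})

test_that("geometric mean never exceeds the arithmetic mean", {
  set.seed(21)
  for (i in 1:25) {
    x <- rlnorm(sample(2:30, 1), meanlog = rnorm(1), sdlog = runif(1, 0, 1))
    expect_lte(geometric_mean(x), mean(x))
  }
})

test_that("lambda_z is recovered from noisy profiles at the study's sampling density", {
  cfg <- flock_sim_config(n_hens = 1L, gsd_ka = 1, gsd_ke = 1, gsd_A = 1,
                          n_cease = 0L, calibrate_observed_cmax = FALSE)
  ke_hours <- cfg$kinetics$ke / 24
  est <- vapply(seq_len(200), function(i) {
    cfg$seed <- 5000L + i
    flock <- simulate_flock(cfg)
    series <- residue_series(flock, "hen1")
    tryCatch(fit_terminal(series)$lambda_z, error = function(e) NA_real_)
  }, 0)
  est <- est[!is.na(est)]
  expect_gt(length(est), 190)
  # individual recoveries are overwhelmingly within 20%, with no gross bias
  expect_gt(mean(abs(est / ke_hours - 1) <= 0.20), 0.80)
  expect_lt(abs(geometric_mean(est) / ke_hours - 1), 0.10)
})
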