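#' Log-linear depletion regression
#'
#' The statistical core of the regulatory withdrawal-interval methods:
#' ordinary least squares of ln(concentration) on time. The fitted object
#' stores the sufficient statistics (residual SD, mean time, centred sum of
#' squares) needed for one-sided regression tolerance limits — an upper
#' bound that, with confidence `confidence`, exceeds the `percentile`
#' quantile of the residue distribution at a given time.
#'
#' @param data data frame with columns `time` (days) and `value`
#'   (concentration ng/g, all positive), e.g. an
#'   [augment_timepoints()] result.
#' @param percentile population percentile the tolerance limit bounds
#'   (FDA methodology uses 0.99, EMA 0.95).
#' @param confidence one-sided confidence level (both agencies use 0.95).
#' @return an object of class `depletion_fit` with components `coefficients`
#'   (`intercept` ln ng/g, `slope` 1/day), `n`, `s` (residual SD on the ln
#'   scale), `xbar`, `Sxx`, `df`, `percentile`, `confidence`, `data` and
#'   `lm` (the underlying [stats::lm()] fit).
#' @seealso [upper_tolerance_limit()], [wdi_from_tolerance()]
#' @examples
#' d <- data.frame(time = rep(10 * 1:5, each = 3),
#'                 value = exp(4 - 0.1 * rep(10 * 1:5, each = 3)))
#' fit <- depletion_fit(d)
#' coef(fit)
#' @export
depletion_fit <- function(data, percentile = 0.95, confidence = 0.95) {
  if (!all(c("time", "value") %in% names(data)))
    stop("'data' needs columns 'time' and 'value'")
  if (any(data$value <= 0)) stop("concentrations must be positive")
  if (length(unique(data$time)) < 2L)
    stop("singular design: need at least 2 distinct times")
  if (nrow(data) < 3L) stop("need at least 3 observations")
  if (percentile <= 0 || percentile >= 1 || confidence <= 0 || confidence >= 1)
    stop("percentile and confidence must lie in (0, 1)")
  fit <- stats::lm(log(value) ~ time, data = data)
  slope <- unname(stats::coef(fit)[2L])
  diagnostics <- character()
  if (slope >= 0)
    diagnostics <- "depletion not evident: non-negative slope"
  # residual SD; zero-residual data (exact lines) are a designed use case,
  # so summary.lm's perfect-fit warning is noise here
  s <- withCallingHandlers(summary(fit)$sigma,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(coefficients = c(intercept = unname(stats::coef(fit)[1L]),
                                  slope = slope),
                 n = nrow(data),
                 s = s,
                 xbar = mean(data$time),
                 Sxx = sum((data$time - mean(data$time))^2),
                 df = fit$df.residual,
                 percentile = percentile, confidence = confidence,
                 data = data[, c("time", "value")], lm = fit,
                 diagnostics = diagnostics),
            class = "depletion_fit")
}

#' One-sided upper tolerance limit of a depletion fit
#'
#' Computes `UTL(t) = yhat(t) + K(t) * s` on the ln-concentration scale,
#' where `yhat(t)` is the fitted regression line and the tolerance factor
#' uses the noncentral-t formulation with the pointwise effective sample
#' size `n*(t) = 1 / (1/n + (t - xbar)^2 / Sxx)`:
#' `K(t) = qt(confidence, df = n - 2, ncp = z_P * sqrt(n*(t))) / sqrt(n*(t))`
#' with `z_P` the standard-normal `percentile` quantile. With probability
#' `confidence`, `UTL(t)` exceeds the true `percentile` quantile of the
#' ln-residue distribution at time `t` (exactly, under the normal-errors
#' model, for each fixed `t`).
#'
#' @param fit a [depletion_fit()].
#' @param t time(s), days (vectorised).
#' @param percentile,confidence override the levels stored in the fit.
#' @return upper tolerance limit(s) on the ln(ng/g) scale.
#' @export
upper_tolerance_limit <- function(fit, t, percentile = fit$percentile,
                                  confidence = fit$confidence) {
  if (fit$df < 1L) stop("insufficient data: no residual degrees of freedom")
  nstar <- 1 / (1 / fit$n + (t - fit$xbar)^2 / fit$Sxx)
  # qt() warns that the noncentral quantile is only accurate to ~1e-8,
  # far below anything a withdrawal time resolved to 0.01 day can see
  K <- withCallingHandlers(
    stats::qt(confidence, df = fit$df,
              ncp = stats::qnorm(percentile) * sqrt(nstar)) / sqrt(nstar),
    warning = function(w) {
      if (grepl("full precision may not have been achieved",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  yhat <- fit$coefficients[["intercept"]] + fit$coefficients[["slope"]] * t
  unname(yhat + K * fit$s)
}

#' @export
coef.depletion_fit <- function(object, ...) object$coefficients

#' @export
residuals.depletion_fit <- function(object, ...) stats::residuals(object$lm)

#' Predictions from a depletion fit
#'
#' @param object a [depletion_fit()].
#' @param t times, days; defaults to the observed times.
#' @param interval `"none"` for the fitted ln-concentration, `"tolerance"`
#'   to add the upper tolerance limit.
#' @param ... unused.
#' @return with `interval = "none"`, the fitted values (ln ng/g); otherwise
#'   a data frame with columns `time`, `fit` and `upper` (ln ng/g).
#' @export
predict.depletion_fit <- function(object, t = object$data$time,
                                  interval = c("none", "tolerance"), ...) {
  interval <- match.arg(interval)
  yhat <- object$coefficients[["intercept"]] + object$coefficients[["slope"]] * t
  if (interval == "none") return(unname(yhat))
  data.frame(time = t, fit = unname(yhat),
             upper = upper_tolerance_limit(object, t))
}

#' Simulate responses from a fitted depletion model
#'
#' Draws new ln-normal responses at the observed design times from the
#' fitted line and residual SD; useful for parametric-bootstrap checks.
#'
#' @param object a [depletion_fit()].
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `time` and `value`.
#' @export
simulate.depletion_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    mu <- predict(object)
    lapply(seq_len(nsim), function(i)
      data.frame(time = object$data$time,
                 value = exp(stats::rnorm(object$n, mu, object$s))))
  })
}

#' @export
print.depletion_fit <- function(x, digits = 4, ...) {
  cat("Log-linear residue depletion fit\n")
  cat(sprintf("  ln C(t) = %.*g %+.*g * t   (t in days, C in ng/g)\n",
              digits, x$coefficients[["intercept"]],
              digits, x$coefficients[["slope"]]))
  cat(sprintf("  n = %d, residual SD = %.*g, tolerance limit: %g%% percentile / %g%% confidence\n",
              x$n, digits, x$s, 100 * x$percentile, 100 * x$confidence))
  if (length(x$diagnostics)) cat("  warning:", x$diagnostics, "\n")
  invisible(x)
}

#' @export
summary.depletion_fit <- function(object, ...) {
  out <- summary(object$lm)
  cat(sprintf("Depletion half-life along the fitted line: %.2f days\n",
              -log(2) / object$coefficients[["slope"]]))
  out
}

#' Plot a depletion fit with its tolerance limit
#'
#' Observed values, fitted line, and the upper tolerance limit on the
#' concentration (log) scale, with an optional residue-limit reference.
#'
#' @param x a [depletion_fit()].
#' @param limit optional [residue_limit()] (or ng/g value) drawn as a
#'   horizontal reference.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the grid of plotted tolerance-limit values.
#' @export
plot.depletion_fit <- function(x, limit = NULL, ...) {
  tt <- seq(min(x$data$time), max(x$data$time) * 1.3, length.out = 200)
  p <- predict(x, tt, interval = "tolerance")
  graphics::plot(x$data$time, x$data$value, log = "y", pch = 1,
                 xlab = "Time after final dose (days)",
                 ylab = "Residue (ng/g)",
                 xlim = range(tt),
                 ylim = range(c(x$data$value, exp(p$upper),
                                if (!is.null(limit)) limit_value(limit))), ...)
  graphics::lines(tt, exp(p$fit))
  graphics::lines(tt, exp(p$upper), lty = 2)
  if (!is.null(limit)) graphics::abline(h = limit_value(limit), lty = 3)
  graphics::legend("topright", bty = "n", lty = c(1, 2),
                   legend = c("fitted line",
                              sprintf("%g/%g tolerance limit",
                                      100 * x$percentile, 100 * x$confidence)))
  invisible(p)
}
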