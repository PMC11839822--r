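#' Residue limit applied in a withdrawal calculation
#'
#' When no tolerance/MRL exists for a drug-matrix combination, regulatory
#' practice substitutes an assay-derived limit: the LOD (US practice) or
#' twice the LLOQ (EU practice).
#'
#' @param basis `"explicit_mrl"`, `"lod"` or `"two_times_lloq"`.
#' @param value the limit in ng/g when `basis = "explicit_mrl"`.
#' @param limits an [assay_limits()] object, required for the assay-derived
#'   bases.
#' @return an object of class `residue_limit` with fields `value` (ng/g)
#'   and `basis`.
#' @examples
#' residue_limit("two_times_lloq",
#'               limits = assay_limits("yolk", 0.03, 0.075)) # 0.15 ng/g
#' @export
residue_limit <- function(basis = c("explicit_mrl", "lod", "two_times_lloq"),
                          value = NULL, limits = NULL) {
  basis <- match.arg(basis)
  value <- switch(basis,
    explicit_mrl = {
      if (is.null(value)) stop("an explicit MRL needs 'value'")
      value
    },
    lod = {
      if (is.null(limits)) stop("basis 'lod' needs 'limits'")
      limits$lod
    },
    two_times_lloq = {
      if (is.null(limits)) stop("basis 'two_times_lloq' needs 'limits'")
      2 * limits$lloq
    })
  stopifnot_scalar_positive(value, "value")
  structure(list(value = value, basis = basis), class = "residue_limit")
}

limit_value <- function(limit) {
  if (inherits(limit, "residue_limit")) limit$value else limit
}

#' @export
print.residue_limit <- function(x, ...) {
  cat(sprintf("Residue limit: %g ng/g (basis: %s)\n", x$value, x$basis))
  invisible(x)
}

#' Round a withdrawal interval up to whole days
#'
#' Withdrawal intervals are issued in whole 24-h increments, always rounded
#' up; whole-day values map to themselves.
#'
#' @param raw raw WDI, days (>= 0).
#' @return integer days.
#' @examples
#' round_up_wdi(80.6)  # 81
#' round_up_wdi(101.7) # 102
#' round_up_wdi(57)    # 57
#' @export
round_up_wdi <- function(raw) {
  if (any(raw < 0)) stop("a withdrawal interval cannot be negative")
  as.integer(ceiling(raw))
}

new_wdi_estimate <- function(method, limit, raw_wdi, diagnostics = list()) {
  structure(list(method = method, limit = limit, raw_wdi = raw_wdi,
                 rounded_wdi = round_up_wdi(raw_wdi),
                 diagnostics = diagnostics),
            class = "wdi_estimate")
}

#' @export
print.wdi_estimate <- function(x, ...) {
  lab <- c(hlm = "terminal half-life multiplier (10 x t1/2)",
           fda_tolerance = "FDA tolerance limit (99th percentile / 95% confidence)",
           ema_mrl = "EMA MRL method (95th percentile / 95% confidence)")[x$method]
  cat("Withdrawal interval estimate\n")
  cat("  method:", lab, "\n")
  if (!is.null(x$limit))
    cat(sprintf("  residue limit: %g ng/g (%s)\n",
                x$limit$value, x$limit$basis))
  cat(sprintf("  raw WDI: %.1f days; recommended (rounded up): %d days\n",
              x$raw_wdi, x$rounded_wdi))
  for (w in x$diagnostics$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Half-life multiplier withdrawal interval
#'
#' WDI as 10 terminal half-lives — the time for >99% of the residue to
#' deplete — converted to days and rounded up to a whole day.
#'
#' @param t_half terminal half-life, hours.
#' @return a `wdi_estimate` (no residue limit applies).
#' @examples
#' wdi_hlm(228.1) # raw 95.0 days, recommended 96
#' @export
wdi_hlm <- function(t_half) {
  stopifnot_scalar_positive(t_half, "t_half")
  new_wdi_estimate("hlm", NULL, raw_wdi = 10 * hours_to_days(t_half))
}

#' Withdrawal interval from a tolerance limit
#'
#' The WDI is the earliest time at which the upper tolerance limit of the
#' depletion fit falls to (or below) the residue limit. The crossing is
#' located on a 0.01-day grid and refined by root bisection between the
#' bracketing grid points.
#'
#' @param fit a [depletion_fit()] with negative slope.
#' @param limit a [residue_limit()] (or a ng/g value).
#' @param window search window end, days (default 365).
#' @param method label recorded on the estimate.
#' @param diagnostics extra diagnostics to carry on the estimate.
#' @return a `wdi_estimate`; its diagnostics include `utl_curve`, the
#'   tolerance-limit curve sampled at whole days.
#' @export
wdi_from_tolerance <- function(fit, limit, window = 365,
                               method = "fda_tolerance",
                               diagnostics = list()) {
  if (fit$coefficients[["slope"]] >= 0)
    stop("depletion not evident: slope is non-negative")
  lim <- limit_value(limit)
  threshold <- log(lim)
  f <- function(t) upper_tolerance_limit(fit, t) - threshold
  grid <- seq(0, window, by = 0.01)
  below <- f(grid) <= 0
  if (!any(below))
    stop(sprintf("tolerance limit never reaches %g ng/g within %g days",
                 lim, window))
  i <- which(below)[1L]
  raw <- if (i == 1L) 0 else
    stats::uniroot(f, lower = grid[i - 1L], upper = grid[i],
                   tol = 1e-6)$root
  if (!inherits(limit, "residue_limit"))
    limit <- residue_limit("explicit_mrl", value = lim)
  days <- 0:ceiling(min(window, raw + 10))
  diagnostics$utl_curve <- data.frame(time = days,
                                      utl = exp(upper_tolerance_limit(fit, days)))
  diagnostics$fit <- fit
  new_wdi_estimate(method, limit, raw, diagnostics)
}

#' FDA-style tolerance-limit withdrawal interval
#'
#' US methodology: fit the log-linear depletion regression to *all*
#' elimination-phase timepoints (each with at least 10 values after
#' augmentation) and find when the 99th-percentile / 95%-confidence upper
#' tolerance limit drops to the operational tolerance.
#'
#' @param augmented an [augment_timepoints()] result (or any data frame
#'   with `time`/`value` columns; un-augmented data are accepted for
#'   general use).
#' @param limit a [residue_limit()]; typically the assay LOD when no
#'   tolerance exists.
#' @param percentile,confidence tolerance-limit levels (0.99 / 0.95).
#' @param window search window, days.
#' @return a `wdi_estimate` with method `"fda_tolerance"`.
#' @export
wdi_fda <- function(augmented, limit, percentile = 0.99, confidence = 0.95,
                    window = 365) {
  fit <- depletion_fit(augmented, percentile = percentile,
                       confidence = confidence)
  wdi_from_tolerance(fit, limit, window = window, method = "fda_tolerance")
}

#' EMA-style MRL withdrawal interval
#'
#' EU methodology: restrict to the final `max_timepoints` (default 7)
#' timepoints — the most the agency's worksheet accepts — fit the
#' log-linear regression, and find when the 95th-percentile /
#' 95%-confidence upper tolerance limit drops to the MRL (twice the LLOQ
#' when no MRL exists). Two data checks are run on the restricted window
#' and reported as warnings rather than hard failures: a lack-of-fit F test
#' of the straight line against the per-timepoint-means model, and
#' Bartlett's test of variance homogeneity across timepoints (both at
#' alpha = 0.05).
#'
#' @param augmented an [augment_timepoints()] result (long `time`/`value`
#'   data frame).
#' @param limit a [residue_limit()].
#' @param max_timepoints number of final timepoints used (default 7).
#' @param percentile,confidence tolerance-limit levels (0.95 / 0.95).
#' @param window search window, days.
#' @param strict if `TRUE`, failed data checks abort instead of warning.
#' @return a `wdi_estimate` with method `"ema_mrl"`; diagnostics carry the
#'   check results (`lack_of_fit`, `bartlett`) and any warnings.
#' @export
wdi_ema <- function(augmented, limit, max_timepoints = 7L,
                    percentile = 0.95, confidence = 0.95, window = 365,
                    strict = FALSE) {
  times <- sort(unique(augmented$time))
  if (length(times) < 3L)
    stop("insufficient data: need at least 3 timepoints")
  used <- utils::tail(times, max_timepoints)
  data <- augmented[augmented$time %in% used, , drop = FALSE]
  fit <- depletion_fit(data, percentile = percentile,
                       confidence = confidence)
  checks <- ema_data_checks(data)
  warnings <- character()
  if (!is.na(checks$lack_of_fit$p) && checks$lack_of_fit$p < 0.05)
    warnings <- c(warnings,
                  sprintf("lack of fit of the log-linear model (F = %.2f, p = %.3g)",
                          checks$lack_of_fit$F, checks$lack_of_fit$p))
  if (!is.na(checks$bartlett$p) && checks$bartlett$p < 0.05)
    warnings <- c(warnings,
                  sprintf("heterogeneous variances across timepoints (Bartlett p = %.3g)",
                          checks$bartlett$p))
  if (strict && length(warnings)) stop(paste(warnings, collapse = "; "))
  for (w in warnings) warning(w, call. = FALSE)
  est <- wdi_from_tolerance(fit, limit, window = window, method = "ema_mrl",
                            diagnostics = c(checks,
                                            list(warnings = warnings,
                                                 timepoints_used = used)))
  est
}

# lack-of-fit F test (pure-error decomposition) and Bartlett homogeneity
# test on ln(value) grouped by timepoint
ema_data_checks <- function(data) {
  g <- factor(data$time)
  y <- log(data$value)
  x <- data$time
  fit_line <- stats::lm(y ~ x)
  n <- length(y); k <- nlevels(g)
  sse <- sum(stats::residuals(fit_line)^2)
  sspe <- sum(stats::resid(stats::lm(y ~ g))^2)
  tol <- 1e-10 * max(1, sum(y^2)) # numerically-zero sums of squares
  sslf <- max(sse - sspe, 0)
  lof <- list(F = NA_real_, p = NA_real_)
  if (k > 2L && n > k && sspe > tol) {
    Fstat <- (sslf / (k - 2)) / (sspe / (n - k))
    lof <- list(F = Fstat, p = stats::pf(Fstat, k - 2, n - k,
                                         lower.tail = FALSE))
  } else if (k > 2L && n > k) {
    lof <- list(F = if (sslf > tol) Inf else 0,
                p = if (sslf > tol) 0 else 1)
  }
  bart <- tryCatch({
    b <- stats::bartlett.test(y, g)
    list(stat = unname(b$statistic), p = b$p.value)
  }, error = function(e) list(stat = NA_real_, p = NA_real_))
  list(lack_of_fit = lof, bartlett = bart)
}

#' Provisionally acceptable residue limit
#'
#' A non-regulatory residue limit derived from the acceptable daily intake:
#' `PAR = ADI x bodyweight x partition_fraction / consumption`, in ug/kg
#' (ppb). With the US inputs for eggs (ADI 5 ug/kg/day, 60 kg person, 20%
#' of the ADI apportioned to eggs, 0.1 kg eggs/day) this gives 600 ppb.
#'
#' @param adi acceptable daily intake, ug/kg bodyweight/day.
#' @param bodyweight consumer bodyweight, kg.
#' @param partition_fraction fraction of the ADI apportioned to this food,
#'   in (0, 1].
#' @param consumption daily consumption of the food, kg/day.
#' @return the PAR in ug/kg (equivalently ppb or ng/g).
#' @examples
#' compute_par(5, 60, 0.20, 0.1) # 600
#' @export
compute_par <- function(adi = 5, bodyweight = 60, partition_fraction = 0.20,
                        consumption = 0.1) {
  stopifnot_scalar_positive(adi, "adi")
  stopifnot_scalar_positive(bodyweight, "bodyweight")
  stopifnot_scalar_positive(consumption, "consumption")
  if (partition_fraction <= 0 || partition_fraction > 1)
    stop("'partition_fraction' must lie in (0, 1]")
  adi * bodyweight * partition_fraction / consumption
}
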