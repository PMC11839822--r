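#' Observed peak of a residue series
#'
#' Cmax and Tmax read directly from the data: the maximum measured
#' concentration and its collection time, ties resolved to the earliest
#' time.
#'
#' @param series a [residue_series()] (columns `time`, `concentration`).
#' @return named numeric: `cmax` (ng/g) and `tmax` (same time unit as the
#'   series, days since final dose).
#' @export
observed_peak <- function(series) {
  if (!nrow(series)) stop("empty residue series: no data to summarise")
  i <- which(series$concentration == max(series$concentration))[1L]
  c(cmax = series$concentration[i], tmax = series$time[i])
}

# adjusted R^2 ties are resolved toward more points only when numerically
# indistinguishable; a looser tolerance would let near-peak curvature creep
# into the terminal set on clean data
TERMINAL_TIE_TOL <- 1e-9

# adjusted R^2, slope and intercept of ln(y) ~ x for every suffix of length
# k = 3..m, vectorised via reverse cumulative sums
terminal_candidates <- function(x, y) {
  m <- length(x)
  ly <- log(y)
  rx <- rev(x); rly <- rev(ly)
  k <- seq_len(m)
  sx <- cumsum(rx); sy <- cumsum(rly)
  sxx <- cumsum(rx^2); syy <- cumsum(rly^2); sxy <- cumsum(rx * rly)
  Sxx <- sxx - sx^2 / k
  Syy <- syy - sy^2 / k
  Sxy <- sxy - sx * sy / k
  slope <- Sxy / Sxx
  intercept <- sy / k - slope * sx / k
  r2 <- ifelse(Syy > 0, Sxy^2 / (Sxx * Syy), 1)
  adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
  ok <- k >= 3
  data.frame(k = k[ok], slope = slope[ok], intercept = intercept[ok],
             adj_r2 = adj[ok])
}

#' Terminal log-linear fit
#'
#' Estimates the terminal elimination rate constant (lambda_z) by linear
#' regression of ln(concentration) on time over the terminal portion of a
#' residue series. With the default `"best_fit_adjusted_r2"` rule the
#' candidate point sets are the last k post-peak points (k = 3 up to all
#' points strictly after Tmax; the Tmax point itself is excluded), and the
#' set maximising the adjusted R-squared is chosen; numerical ties are
#' resolved in favour of more points. Candidates with a non-negative slope
#' are discarded.
#'
#' Internally times are converted to hours, the conventional reporting unit
#' for egg pharmacokinetic parameters.
#'
#' @param series a [residue_series()] with times in days.
#' @param selection `"best_fit_adjusted_r2"` (default) or a manually chosen
#'   integer vector of row indices into `series`.
#' @return an object of class `terminal_fit`: `lambda_z` (1/h), `intercept`
#'   (ln ng/g at t = 0 h), `t_half` (h), `n_points`, `adj_r2`, `span_h`
#'   (range of times used, h), `times_used` (days).
#' @export
fit_terminal <- function(series, selection = "best_fit_adjusted_r2") {
  peak <- observed_peak(series)
  if (is.numeric(selection)) {
    idx <- sort(unique(as.integer(selection)))
    if (length(idx) < 3L) stop("manual selection needs at least 3 points")
    x <- days_to_hours(series$time[idx]); y <- series$concentration[idx]
    fit <- stats::lm(log(y) ~ x)
    slope <- unname(stats::coef(fit)[2L])
    if (slope >= 0) stop("no terminal phase: selected points do not decline")
    adj_r2 <- withCallingHandlers(summary(fit)$adj.r.squared,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    out <- list(lambda_z = -slope,
                intercept = unname(stats::coef(fit)[1L]),
                n_points = length(idx),
                adj_r2 = adj_r2,
                span_h = range(x), times_used = series$time[idx])
  } else {
    post <- series[series$time > peak["tmax"], , drop = FALSE]
    if (nrow(post) < 3L)
      stop("insufficient data: need at least 3 post-peak points")
    cand <- terminal_candidates(days_to_hours(post$time), post$concentration)
    cand <- cand[cand$slope < 0, , drop = FALSE]
    if (!nrow(cand))
      stop("no terminal phase: no declining post-peak candidate set")
    best <- max(cand$adj_r2)
    pick <- cand[cand$adj_r2 >= best - TERMINAL_TIE_TOL, , drop = FALSE]
    pick <- pick[which.max(pick$k), ]
    used <- post$time[(nrow(post) - pick$k + 1L):nrow(post)]
    out <- list(lambda_z = -pick$slope, intercept = pick$intercept,
                n_points = pick$k, adj_r2 = pick$adj_r2,
                span_h = days_to_hours(range(used)), times_used = used)
  }
  out$t_half <- log(2) / out$lambda_z
  structure(out, class = "terminal_fit")
}

#' Trapezoidal AUC with extrapolation
#'
#' Area under the concentration-time curve by the linear trapezoidal rule
#' over the observed points, extrapolated to infinity with the terminal fit:
#' `auc_inf = auc_last + C_last / lambda_z`.
#'
#' @param series a [residue_series()] (times in days).
#' @param fit a [fit_terminal()] result.
#' @return named numeric: `auc_last`, `auc_inf` (h*ng/g) and
#'   `pct_extrapolated` (%).
#' @export
auc_linear <- function(series, fit) {
  if (nrow(series) < 2L) stop("AUC needs at least 2 points")
  x <- days_to_hours(series$time); y <- series$concentration
  auc_last <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  tail_area <- y[length(y)] / fit$lambda_z
  auc_inf <- auc_last + tail_area
  c(auc_last = auc_last, auc_inf = auc_inf,
    pct_extrapolated = 100 * tail_area / auc_inf)
}

#' Non-compartmental analysis of a flock
#'
#' Runs per-hen NCA on the post-final-dose residue profiles of one matrix:
#' observed Cmax/Tmax, best-fit terminal log-linear regression, and linear
#' trapezoidal AUC extrapolated to infinity. Hens whose profile does not
#' support a terminal fit (fewer than 3 quantifiable post-peak points, or no
#' declining phase) are reported with `NA` fit parameters and a warning.
#'
#' @param flock a `flock_data` object. Records below the LOD are ignored.
#' @param matrix egg matrix, default `"yolk"`.
#' @return an object of class `nca`: a list with `per_hen` (data frame with
#'   columns `hen_id`, `cmax` ng/g, `tmax_h`, `lambda_z` 1/h, `t_half_h`,
#'   `auc_last`, `auc_inf` h*ng/g, `pct_extrapolated`, `n_terminal`,
#'   `adj_r2`), `fits` (per-hen `terminal_fit`s) and `matrix`.
#' @seealso [summary.nca()] for the geometric-mean flock summary.
#' @export
nca <- function(flock, matrix = "yolk") {
  hens <- unique(flock$observations$hen_id)
  fits <- list()
  rows <- lapply(hens, function(h) {
    series <- residue_series(flock, h, matrix)
    row <- data.frame(hen_id = h, cmax = NA_real_, tmax_h = NA_real_,
                      lambda_z = NA_real_, t_half_h = NA_real_,
                      auc_last = NA_real_, auc_inf = NA_real_,
                      pct_extrapolated = NA_real_,
                      n_terminal = NA_integer_, adj_r2 = NA_real_,
                      stringsAsFactors = FALSE)
    if (!nrow(series)) {
      warning("hen ", h, ": no quantifiable data, skipped")
      return(row)
    }
    peak <- observed_peak(series)
    row$cmax <- peak[["cmax"]]
    row$tmax_h <- days_to_hours(peak[["tmax"]])
    fit <- tryCatch(fit_terminal(series), error = function(e) {
      warning("hen ", h, ": ", conditionMessage(e)); NULL
    })
    if (!is.null(fit)) {
      fits[[h]] <<- fit
      a <- auc_linear(series, fit)
      row$lambda_z <- fit$lambda_z
      row$t_half_h <- fit$t_half
      row$auc_last <- a[["auc_last"]]
      row$auc_inf <- a[["auc_inf"]]
      row$pct_extrapolated <- a[["pct_extrapolated"]]
      row$n_terminal <- fit$n_points
      row$adj_r2 <- fit$adj_r2
    }
    row
  })
  structure(list(per_hen = do.call(rbind, rows), fits = fits,
                 matrix = matrix),
            class = "nca")
}

#' @export
print.nca <- function(x, digits = 4, ...) {
  cat(sprintf("Non-compartmental analysis, egg %s (%d hens)\n",
              x$matrix, nrow(x$per_hen)))
  print(format(x$per_hen, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Flock-level NCA summary
#'
#' Geometric mean and (min, max) range of each NCA parameter over the hens
#' with a valid terminal fit, the conventional presentation for
#' lognormally distributed PK parameters.
#'
#' @param object an [nca()] result.
#' @param ... unused.
#' @return an object of class `nca_summary`: data frame with columns
#'   `parameter`, `unit`, `geo_mean`, `min`, `max`, `n`.
#' @export
summary.nca <- function(object, ...) {
  ph <- object$per_hen
  params <- c(cmax = "ng/g", tmax_h = "h", lambda_z = "1/h",
              t_half_h = "h", auc_last = "h*ng/g", auc_inf = "h*ng/g",
              pct_extrapolated = "%")
  rows <- lapply(names(params), function(p) {
    v <- ph[[p]]
    v <- v[!is.na(v) & v > 0]
    data.frame(parameter = p, unit = params[[p]],
               geo_mean = if (length(v)) geometric_mean(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("nca_summary", "data.frame"))
}

#' @export
print.nca_summary <- function(x, digits = 4, ...) {
  cat("Flock NCA summary: geometric mean (range)\n")
  df <- as.data.frame(x)
  df$`geometric mean (range)` <- sprintf("%.4g (%.4g-%.4g)",
                                         df$geo_mean, df$min, df$max)
  print(df[, c("parameter", "unit", "geometric mean (range)", "n")],
        row.names = FALSE)
  invisible(x)
}

#' Geometric-mean summary of per-hen NCA results
#'
#' Convenience wrapper equivalent to `summary(nca_result)`; provided as a
#' standalone verb for scripted pipelines.
#'
#' @param nca_result an [nca()] result.
#' @return see [summary.nca()].
#' @export
summarize_flock_nca <- function(nca_result) summary(nca_result)
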