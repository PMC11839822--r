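#' Per-timepoint summaries of yolk residues
#'
#' Bins quantifiable observations (below-LOD records must already have been
#' excluded via [apply_blq_policy()]) to integer days since the final dose
#' — collection was every 24 h, so the nearest-day bin is the natural
#' sampling grid — and keeps bins with at least `min_n` observations. The
#' mean and SD are the sample statistics of the observed values; the raw
#' values themselves are carried along so that downstream augmentation can
#' pass them through unchanged.
#'
#' @param flock a `flock_data` object.
#' @param matrix egg matrix, default `"yolk"`.
#' @param min_n minimum observations for a bin to be retained (default 5).
#' @param from_time drop bins before this day (e.g. the flock peak time, to
#'   restrict to the elimination phase); default 0.
#' @return a data frame of class `timepoint_summary` with columns `time`
#'   (days since final dose), `n_observed`, `mean`, `sd` (ng/g), and the
#'   per-bin observed values in `attr(x, "values")`.
#' @export
summarize_timepoints <- function(flock, matrix = "yolk", min_n = 5L,
                                 from_time = 0) {
  obs <- flock$observations
  keep <- obs$matrix == matrix & !is.na(obs$concentration) &
    obs$censor != "below_lod"
  obs <- obs[keep, , drop = FALSE]
  day <- round(obs$time)
  obs <- obs[day >= from_time, , drop = FALSE]
  day <- day[day >= from_time]
  if (!nrow(obs)) stop("insufficient data: no quantifiable observations")
  values <- split(obs$concentration, day)
  n <- lengths(values)
  values <- values[n >= min_n]
  if (!length(values))
    stop("insufficient data: no timepoint has >= ", min_n, " observations")
  out <- data.frame(time = as.numeric(names(values)),
                    n_observed = lengths(values),
                    mean = vapply(values, mean, 0),
                    sd = vapply(values, stats::sd, 0))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("timepoint_summary", "data.frame"),
            values = values[order(as.numeric(names(values)))],
            matrix = matrix)
}

# draw n values from Normal(mean, sd) truncated below at `lower`, by
# rejection; sd = 0 degenerates to the mean
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric())
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(max(n - length(out), 16L) * 2L, mean, sd)
    out <- c(out, draw[draw >= lower])
  }
  out[seq_len(n)]
}

#' Monte Carlo "virtual animal" augmentation
#'
#' Tops each timepoint up to `target_n` values by drawing the shortfall
#' from a normal distribution with that timepoint's observed mean and SD,
#' truncated below at the LOD (sub-LOD data are excluded from withdrawal
#' calculations, so sub-LOD draws are rejected at source). Observed values
#' pass through unchanged; given the same seed, output is identical across
#' runs.
#'
#' @param summary a [summarize_timepoints()] result.
#' @param target_n required values per timepoint (default 10, the sample
#'   size regulatory tolerance-limit methods expect).
#' @param lod truncation bound, ng/g.
#' @param seed RNG seed.
#' @return a data frame of class `augmented_timepoints`, long format:
#'   `time` (days since final dose), `value` (ng/g), `source`
#'   (`"observed"` or `"simulated"`). The LOD is kept in `attr(x, "lod")`.
#' @export
augment_timepoints <- function(summary, target_n = 10L, lod, seed = 1L) {
  stopifnot_scalar_positive(lod, "lod")
  values <- attr(summary, "values")
  if (is.null(values)) stop("'summary' must come from summarize_timepoints()")
  if (target_n < max(summary$n_observed))
    stop("target_n must be at least the largest observed count")
  if (any(summary$mean < lod))
    stop("degenerate truncation: a timepoint mean is below the LOD")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(summary)), function(i) {
      obs <- values[[i]]
      need <- target_n - length(obs)
      sim <- rtruncnorm_lower(need, summary$mean[i], summary$sd[i], lod)
      data.frame(time = summary$time[i],
                 value = c(obs, sim),
                 source = rep(c("observed", "simulated"),
                              c(length(obs), need)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("augmented_timepoints", "data.frame"),
              lod = lod, target_n = as.integer(target_n))
  })
}
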