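#' Assay limits for one egg matrix
#'
#' Detection and quantification limits of the analytical assay, per egg
#' matrix. The limit of detection (LOD) and lower limit of quantification
#' (LLOQ) drive the censoring status attached to every residue record.
#'
#' @param matrix `"yolk"` or `"white"`.
#' @param lod limit of detection, ng/g.
#' @param lloq lower limit of quantification, ng/g; must exceed `lod`.
#' @return an object of class `assay_limits`.
#' @examples
#' assay_limits("yolk", lod = 0.03, lloq = 0.075)
#' @export
assay_limits <- function(matrix = c("yolk", "white"), lod, lloq) {
  matrix <- match.arg(matrix)
  stopifnot_scalar_positive(lod, "lod")
  stopifnot_scalar_positive(lloq, "lloq")
  if (!(lod < lloq)) stop("assay limits require 0 < lod < lloq")
  structure(list(matrix = matrix, lod = lod, lloq = lloq),
            class = "assay_limits")
}

#' Default ivermectin egg assay limits
#'
#' LOD/LLOQ of the fluorescence UPLC assay for ivermectin in eggs:
#' 0.03/0.075 ng/g in yolk and 0.01/0.025 ng/g in white.
#'
#' @return named list with `yolk` and `white` [assay_limits()] objects.
#' @export
default_assay_limits <- function() {
  list(yolk = assay_limits("yolk", lod = 0.03, lloq = 0.075),
       white = assay_limits("white", lod = 0.01, lloq = 0.025))
}

#' Dosing regimen
#'
#' @param dose_per_weight dose, mg/kg bodyweight.
#' @param interval_days days between repeated doses (ignored for a single
#'   dose).
#' @param n_doses number of administrations.
#' @param route free-text route description.
#' @return an object of class `dose_regimen`.
#' @examples
#' dose_regimen() # 0.4 mg/kg topically, twice, 7 days apart
#' @export
dose_regimen <- function(dose_per_weight = 0.4, interval_days = 7,
                         n_doses = 2L, route = "topical") {
  stopifnot_scalar_positive(dose_per_weight, "dose_per_weight")
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) stop("'n_doses' must be >= 1")
  if (n_doses > 1L) stopifnot_scalar_positive(interval_days, "interval_days")
  structure(list(dose_per_weight = dose_per_weight,
                 interval_days = interval_days,
                 n_doses = n_doses, route = route),
            class = "dose_regimen")
}

# days between the first and the last administered dose
regimen_span <- function(regimen) (regimen$n_doses - 1L) * regimen$interval_days

#' Censoring status of a measured concentration
#'
#' Total classification of a value against the assay limits: below the LOD,
#' detectable but below the LLOQ, or quantified. `NA` values (e.g. from a
#' below-detection token in a data file) map to `"below_lod"`.
#'
#' @param value concentration, ng/g (may be `NA`).
#' @param limits an [assay_limits()] object.
#' @return character vector over
#'   `c("quantified", "below_lloq_above_lod", "below_lod")`.
#' @export
censor_status <- function(value, limits) {
  out <- ifelse(is.na(value) | value < limits$lod, "below_lod",
         ifelse(value < limits$lloq, "below_lloq_above_lod", "quantified"))
  as.character(out)
}

new_flock_data <- function(observations, limits, regimen, body_weights = NULL) {
  rownames(observations) <- NULL
  structure(list(observations = observations, limits = limits,
                 regimen = regimen, body_weights = body_weights),
            class = "flock_data")
}

#' Read an egg-residue dataset
#'
#' Reads a comma-delimited file with header columns `hen_id`, `time_days`,
#' `matrix` and `concentration` into a `flock_data` object. `time_days` is
#' the study day (days since the *first* dose); internally all times are
#' shifted to days since the *final* dose, the origin used by every
#' depletion analysis. The `concentration` column holds a number in ng/g or
#' one of the literal tokens `BLOD` (below the limit of detection) / `BLOQ`
#' (detected but below the limit of quantification); numeric values are
#' censored against the matrix-specific LOD/LLOQ.
#'
#' Token `BLOQ` rows carry no reportable number, so their concentration is
#' recorded as missing and such rows are excluded from numeric analyses.
#'
#' @param path file path.
#' @param limits named list of [assay_limits()] (one per matrix), as from
#'   [default_assay_limits()].
#' @param regimen a [dose_regimen()].
#' @param body_weights optional named numeric vector of hen body weights, kg.
#' @return a `flock_data` object. Its `observations` data frame has columns
#'   `hen_id`, `time` (days since final dose), `matrix`, `concentration`
#'   (ng/g, `NA` when below LOD or token-censored) and `censor`.
#' @seealso [write_flock()], [apply_blq_policy()], [simulate_flock()]
#' @export
read_flock <- function(path, limits = default_assay_limits(),
                       regimen = dose_regimen(), body_weights = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  needed <- c("hen_id", "time_days", "matrix", "concentration")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("input file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  bad <- character()
  n <- nrow(raw)
  time <- suppressWarnings(as.numeric(raw$time_days))
  bad_time <- which(is.na(time))
  if (length(bad_time))
    bad <- c(bad, sprintf("line %d: unparseable time '%s'",
                          bad_time + 1L, raw$time_days[bad_time]))

  matrix <- tolower(raw$matrix)
  bad_matrix <- which(!matrix %in% names(limits))
  if (length(bad_matrix))
    stop("unknown matrix label(s): ",
         paste(sprintf("line %d: '%s'", bad_matrix + 1L, raw$matrix[bad_matrix]),
               collapse = "; "))

  tok <- toupper(raw$concentration)
  conc <- suppressWarnings(as.numeric(raw$concentration))
  is_blod <- tok == "BLOD"
  is_bloq <- tok == "BLOQ"
  bad_conc <- which(is.na(conc) & !is_blod & !is_bloq)
  if (length(bad_conc))
    bad <- c(bad, sprintf("line %d: unparseable concentration '%s'",
                          bad_conc + 1L, raw$concentration[bad_conc]))
  if (length(bad))
    stop("malformed rows:\n  ", paste(bad, collapse = "\n  "))
  if (any(conc < 0, na.rm = TRUE)) {
    i <- which(conc < 0)[1L]
    stop(sprintf("negative concentration on line %d", i + 1L))
  }

  censor <- character(n)
  for (m in unique(matrix)) {
    idx <- matrix == m
    censor[idx] <- censor_status(conc[idx], limits[[m]])
  }
  censor[is_blod] <- "below_lod"
  censor[is_bloq] <- "below_lloq_above_lod"
  conc[is_blod | censor == "below_lod"] <- NA_real_

  obs <- data.frame(hen_id = raw$hen_id,
                    time = time - regimen_span(regimen),
                    matrix = matrix,
                    concentration = conc,
                    censor = censor,
                    stringsAsFactors = FALSE)
  flock <- new_flock_data(obs, limits, regimen, body_weights)
  validate_flock(flock)
  flock
}

validate_flock <- function(flock) {
  obs <- flock$observations
  if (!nrow(obs)) stop("flock dataset has no observations")
  if (!is.null(flock$body_weights) && any(flock$body_weights <= 0))
    stop("body weights must be positive")
  span <- regimen_span(flock$regimen)
  if (any(obs$time < -span - 1e-9))
    stop("observation times precede the first dose")
  invisible(flock)
}

#' Write an egg-residue dataset
#'
#' Inverse of [read_flock()]: emits the study-day CSV representation.
#' Concentrations are written at full double precision and censored records
#' as `BLOD`/`BLOQ` tokens, so a write/read round trip preserves every
#' record and censor label exactly.
#'
#' @param flock a `flock_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flock <- function(flock, path) {
  obs <- flock$observations
  conc <- sprintf("%.17g", obs$concentration)
  conc[obs$censor == "below_lod"] <- "BLOD"
  conc[obs$censor == "below_lloq_above_lod" & is.na(obs$concentration)] <- "BLOQ"
  out <- data.frame(hen_id = obs$hen_id,
                    time_days = sprintf("%.17g", obs$time + regimen_span(flock$regimen)),
                    matrix = obs$matrix,
                    concentration = conc,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude censored records
#'
#' Filters a flock dataset by censoring status prior to depletion analysis.
#' The default policy removes only records below the LOD; values in
#' \[LOD, LLOQ) are retained as reported. The stricter policy additionally
#' removes everything below the LLOQ.
#'
#' @param flock a `flock_data` object.
#' @param policy `"exclude_below_lod"` (default) or `"exclude_below_lloq"`.
#' @return the filtered `flock_data`; the number of records removed is
#'   reported via `message()`.
#' @export
apply_blq_policy <- function(flock,
                             policy = c("exclude_below_lod",
                                        "exclude_below_lloq")) {
  policy <- match.arg(policy)
  obs <- flock$observations
  drop <- switch(policy,
    exclude_below_lod = obs$censor == "below_lod",
    exclude_below_lloq = obs$censor != "quantified")
  if (any(drop))
    message(sprintf("%s: removed %d of %d records", policy,
                    sum(drop), nrow(obs)))
  flock$observations <- obs[!drop, , drop = FALSE]
  rownames(flock$observations) <- NULL
  flock
}

#' Per-hen residue-time series
#'
#' Extracts one hen's concentration-time profile for one matrix: records
#' with a reportable concentration (below-LOD and token-censored rows are
#' dropped), sorted by time. This is the input unit for non-compartmental
#' analysis.
#'
#' @param flock a `flock_data` object.
#' @param hen_id hen identifier.
#' @param matrix egg matrix, default `"yolk"`.
#' @param from_time drop records before this time (days since final dose);
#'   default 0 restricts to the post-final-dose profile. Use `-Inf` for the
#'   full record.
#' @return a data frame of class `residue_series` with columns `time` (days
#'   since final dose) and `concentration` (ng/g).
#' @export
residue_series <- function(flock, hen_id, matrix = "yolk", from_time = 0) {
  obs <- flock$observations
  keep <- obs$hen_id == hen_id & obs$matrix == matrix &
    !is.na(obs$concentration) & obs$censor != "below_lod" &
    obs$time >= from_time
  out <- obs[keep, c("time", "concentration")]
  out <- out[order(out$time), , drop = FALSE]
  if (any(duplicated(out$time)))
    stop("duplicate collection times for hen ", hen_id)
  rownames(out) <- NULL
  structure(out, class = c("residue_series", "data.frame"),
            hen_id = hen_id, matrix = matrix)
}

#' Laying-pattern summary
#'
#' Summarises egg production: each hen's mean interval between consecutive
#' eggs, the flock mean of those per-hen means, the longest single gap, and
#' which hens ceased laying (last egg more than `cease_gap_days` before the
#' end of collection). Lay events are the distinct collection times per hen,
#' regardless of matrix or censoring.
#'
#' @param flock a `flock_data` object.
#' @param cease_gap_days a hen whose last egg precedes the study end by more
#'   than this many days is flagged as having ceased laying (default 14).
#' @return a list of class `laying_summary` with elements `per_hen` (data
#'   frame: `hen_id`, `n_eggs`, `mean_interval`, `longest_gap`, `last_egg`,
#'   `ceased`), `flock_mean_interval`, `interval_range`, `longest_gap` and
#'   `hens_ceased`.
#' @export
summarize_laying <- function(flock, cease_gap_days = 14) {
  obs <- flock$observations
  study_end <- max(obs$time)
  hens <- unique(obs$hen_id)
  rows <- lapply(hens, function(h) {
    times <- sort(unique(obs$time[obs$hen_id == h]))
    gaps <- diff(times)
    data.frame(hen_id = h, n_eggs = length(times),
               mean_interval = if (length(gaps)) mean(gaps) else NA_real_,
               longest_gap = if (length(gaps)) max(gaps) else NA_real_,
               last_egg = times[length(times)],
               ceased = (study_end - times[length(times)]) > cease_gap_days,
               stringsAsFactors = FALSE)
  })
  per_hen <- do.call(rbind, rows)
  few <- per_hen$hen_id[per_hen$n_eggs < 2L]
  if (length(few))
    warning("hen(s) with fewer than 2 eggs excluded from interval statistics: ",
            paste(few, collapse = ", "))
  mi <- per_hen$mean_interval[!is.na(per_hen$mean_interval)]
  structure(list(per_hen = per_hen,
                 flock_mean_interval = mean(mi),
                 interval_range = range(mi),
                 longest_gap = max(per_hen$longest_gap, na.rm = TRUE),
                 hens_ceased = per_hen$hen_id[per_hen$ceased]),
            class = "laying_summary")
}

#' @export
print.laying_summary <- function(x, ...) {
  cat("Laying pattern summary\n")
  cat(sprintf("  flock mean inter-egg interval: %.2f days (per-hen range %.2f-%.2f)\n",
              x$flock_mean_interval, x$interval_range[1], x$interval_range[2]))
  cat(sprintf("  longest gap between consecutive eggs: %.1f days\n", x$longest_gap))
  if (length(x$hens_ceased))
    cat("  hens ceased laying:", paste(x$hens_ceased, collapse = ", "), "\n")
  else cat("  no hen ceased laying\n")
  invisible(x)
}

#' @export
print.flock_data <- function(x, ...) {
  obs <- x$observations
  cat(sprintf("Egg residue dataset: %d records, %d hens, matrices: %s\n",
              nrow(obs), length(unique(obs$hen_id)),
              paste(sort(unique(obs$matrix)), collapse = ", ")))
  cat(sprintf("  time (days since final dose): %.1f to %.1f\n",
              min(obs$time), max(obs$time)))
  tab <- table(obs$censor)
  cat("  censoring:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Mean residue-time profile plot
#'
#' Plots mean +/- SD measured concentration against days since the final
#' dose for one matrix, with the LOD as a reference line. Records below the
#' LOD are excluded (they carry no number).
#'
#' @param x a `flock_data` object.
#' @param matrix egg matrix to plot.
#' @param log use a log concentration axis (`"y"`, default) or `""`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the per-day summary data frame.
#' @export
plot.flock_data <- function(x, matrix = "yolk", log = "y", ...) {
  obs <- x$observations
  obs <- obs[obs$matrix == matrix & !is.na(obs$concentration), ]
  if (!nrow(obs)) stop("no quantifiable records for matrix ", matrix)
  day <- round(obs$time)
  m <- tapply(obs$concentration, day, mean)
  s <- tapply(obs$concentration, day, stats::sd)
  d <- as.numeric(names(m))
  lod <- x$limits[[matrix]]$lod
  ylim <- range(c(lod, m, m + ifelse(is.na(s), 0, s)), na.rm = TRUE)
  graphics::plot(d, m, type = "b", pch = 16, log = log,
                 xlab = "Time after final dose (days)",
                 ylab = sprintf("Ivermectin in egg %s (ng/g)", matrix),
                 ylim = ylim, ...)
  up <- m + s
  ok <- !is.na(s) & s > 0
  graphics::arrows(d[ok], m[ok], d[ok], up[ok], angle = 90, length = 0.03)
  graphics::abline(h = lod, lty = 3)
  graphics::mtext(sprintf("LOD = %g ng/g", lod), side = 4, cex = 0.7)
  invisible(data.frame(day = d, mean = as.numeric(m), sd = as.numeric(s)))
}
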