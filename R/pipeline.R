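#' Pipeline configuration
#'
#' Assembles the options for [run_pipeline()]. Either `input` (a CSV as
#' read by [read_flock()]) or `sim_config` (a [flock_sim_config()]) supplies
#' the data.
#'
#' @param input optional path to an egg-residue CSV.
#' @param sim_config a [flock_sim_config()], used when `input` is `NULL`.
#' @param matrix egg matrix analysed.
#' @param blq_policy censored-record policy, see [apply_blq_policy()].
#' @param min_n,target_n timepoint selection / augmentation sample sizes.
#' @param methods WDI methods to run, subset of `c("hlm", "fda", "ema")`.
#' @param ema_limits limit bases for the EMA method (the FDA method always
#'   uses the LOD-as-tolerance rule).
#' @param window WDI search window, days.
#' @param seed master seed; each stochastic stage derives its own child
#'   seed as `seed + stage index`, so a stage re-run in isolation
#'   reproduces its in-pipeline output.
#' @param out_dir output directory (created if missing).
#' @param figures write PNG residue-time figures.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            sim_config = flock_sim_config(),
                            matrix = "yolk",
                            blq_policy = "exclude_below_lod",
                            min_n = 5L, target_n = 10L,
                            methods = c("hlm", "fda", "ema"),
                            ema_limits = c("lod", "two_times_lloq"),
                            window = 365,
                            seed = 42L,
                            out_dir = tempfile("eggwdi-run-"),
                            figures = FALSE) {
  methods <- match.arg(methods, c("hlm", "fda", "ema"), several.ok = TRUE)
  if (!length(methods)) stop("at least one WDI method must be requested")
  structure(list(input = input, sim_config = sim_config, matrix = matrix,
                 blq_policy = blq_policy, min_n = as.integer(min_n),
                 target_n = as.integer(target_n), methods = methods,
                 ema_limits = ema_limits, window = window,
                 seed = as.integer(seed), out_dir = out_dir,
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; nested `sim_config`
#' keys mirror [flock_sim_config()] (scalar fields only).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim_config
  y$sim_config <- NULL
  sim <- if (is.null(sim_args)) flock_sim_config()
         else do.call(flock_sim_config, sim_args)
  do.call(pipeline_config, c(y, list(sim_config = sim)))
}

#' Run the full withdrawal-interval pipeline
#'
#' Orchestrates the stages end to end: obtain the flock dataset (simulate
#' or read), apply the censoring policy, per-hen NCA with flock
#' geometric-mean summary, per-timepoint summarisation restricted to the
#' elimination phase (from the timepoint of peak mean concentration
#' onward), Monte Carlo augmentation to `target_n` values per timepoint,
#' and the requested WDI methods. All artifacts are written to
#' `config$out_dir`: `flock.csv`, `nca.csv`, `augmented.csv`, `wdi.json`
#' and `report.md` (plus figures when requested). Re-running with an
#' identical configuration reproduces every number exactly.
#'
#' @param config a [pipeline_config()] or a path to a YAML file for
#'   [read_pipeline_config()].
#' @return a list of class `wdi_report`: `flock`, `laying`, `nca`,
#'   `nca_summary`, `timepoints`, `augmented`, `estimates` (named list of
#'   `wdi_estimate`s), `table` (Table-style summary data frame), `seed`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: data
  flock <- if (!is.null(config$input)) {
    read_flock(config$input)
  } else {
    sim <- config$sim_config
    sim$seed <- config$seed + 1L
    simulate_flock(sim)
  }
  write_flock(flock, file.path(config$out_dir, "flock.csv"))
  laying <- summarize_laying(flock)

  # stage 2: censoring policy
  flock_q <- apply_blq_policy(flock, config$blq_policy)

  # stage 3: NCA
  nca_res <- suppressWarnings(nca(flock_q, config$matrix))
  nca_sum <- summary(nca_res)
  utils::write.csv(nca_res$per_hen, file.path(config$out_dir, "nca.csv"),
                   row.names = FALSE)

  # stage 4: elimination-phase timepoints + augmentation
  tps_all <- summarize_timepoints(flock_q, config$matrix, min_n = config$min_n)
  peak_time <- tps_all$time[which.max(tps_all$mean)]
  tps <- summarize_timepoints(flock_q, config$matrix, min_n = config$min_n,
                              from_time = peak_time)
  lod <- flock$limits[[config$matrix]]$lod
  augmented <- augment_timepoints(tps, target_n = config$target_n, lod = lod,
                                  seed = config$seed + 4L)
  utils::write.csv(as.data.frame(augmented),
                   file.path(config$out_dir, "augmented.csv"),
                   row.names = FALSE)

  # stage 5: WDI estimates
  limits <- flock$limits[[config$matrix]]
  gm_thalf <- nca_sum$geo_mean[nca_sum$parameter == "t_half_h"]
  estimates <- list()
  if ("hlm" %in% config$methods)
    estimates$hlm <- wdi_hlm(gm_thalf)
  if ("fda" %in% config$methods)
    estimates$fda_lod <- wdi_fda(augmented,
                                 residue_limit("lod", limits = limits),
                                 window = config$window)
  if ("ema" %in% config$methods)
    for (basis in config$ema_limits) {
      nm <- paste0("ema_", basis)
      estimates[[nm] ] <- suppressWarnings(
        wdi_ema(augmented, residue_limit(basis, limits = limits),
                window = config$window))
    }

  tab <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(method = nm,
               limit_ppb = if (is.null(e$limit)) NA_real_ else e$limit$value,
               raw_wdi_days = round(e$raw_wdi, 1),
               recommended_wdi_days = e$rounded_wdi,
               stringsAsFactors = FALSE)
  }))

  jsonlite::write_json(
    list(seed = config$seed, matrix = config$matrix,
         wdi = lapply(estimates, function(e)
           list(method = e$method,
                limit_ng_g = if (is.null(e$limit)) NULL else e$limit$value,
                limit_basis = if (is.null(e$limit)) NULL else e$limit$basis,
                raw_wdi_days = e$raw_wdi,
                recommended_wdi_days = e$rounded_wdi))),
    file.path(config$out_dir, "wdi.json"),
    auto_unbox = TRUE, digits = NA)

  report <- c(
    "# Egg residue withdrawal-interval report",
    "",
    sprintf("Seed: %d. Matrix: egg %s. Concentrations in ng/g, times in days since the final dose.",
            config$seed, config$matrix),
    "",
    sprintf("Laying: flock mean inter-egg interval %.2f days (per-hen range %.2f-%.2f); hens ceased laying: %s.",
            laying$flock_mean_interval, laying$interval_range[1],
            laying$interval_range[2],
            if (length(laying$hens_ceased))
              paste(laying$hens_ceased, collapse = ", ") else "none"),
    "",
    "## NCA (geometric mean, range)",
    "",
    sprintf("- %s (%s): %.4g (%.4g-%.4g), n = %d",
            nca_sum$parameter, nca_sum$unit, nca_sum$geo_mean,
            nca_sum$min, nca_sum$max, nca_sum$n),
    "",
    "## Withdrawal intervals",
    "",
    "| Method | Limit (ppb) | Raw WDI (days) | Recommended (days) |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.1f | %d |", tab$method,
            ifelse(is.na(tab$limit_ppb), "-", format(tab$limit_ppb)),
            tab$raw_wdi_days, tab$recommended_wdi_days))
  writeLines(report, file.path(config$out_dir, "report.md"))

  if (config$figures) {
    grDevices::png(file.path(config$out_dir, "profile_%d.png"),
                   width = 900, height = 600, res = 120)
    for (m in names(flock$limits))
      try(plot(flock, matrix = m), silent = TRUE)
    grDevices::dev.off()
  }

  structure(list(flock = flock, laying = laying, nca = nca_res,
                 nca_summary = nca_sum, timepoints = tps,
                 augmented = augmented, estimates = estimates, table = tab,
                 seed = config$seed, out_dir = config$out_dir),
            class = "wdi_report")
}

#' @export
print.wdi_report <- function(x, ...) {
  cat("Egg withdrawal-interval report (seed", x$seed, ")\n\n")
  print(x$nca_summary)
  cat("\n")
  print(x$table, row.names = FALSE)
  cat("\nArtifacts in:", x$out_dir, "\n")
  invisible(x)
}
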