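# shared fixtures: all built in code at test time

yolk_limits <- assay_limits("yolk", lod = 0.03, lloq = 0.075)

# deterministic single- or multi-hen configuration: no noise, no
# between-hen spread, daily laying, nobody ceases
noise_free_config <- function(n_hens = 1L, seed = 1L, ...) {
  flock_sim_config(n_hens = n_hens,
                   gsd_ka = 1, gsd_ke = 1, gsd_A = 1,
                   lay_gap_mean = 0, n_cease = 0L,
                   cv_assay = 0, cv_bio = 0,
                   calibrate_observed_cmax = FALSE,
                   seed = seed, ...)
}

# write a small flock CSV and read it back
write_flock_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("hen_id,time_days,matrix,concentration", rows), path)
  path
}

# build a residue_series directly from vectors (bypassing a flock object)
make_series <- function(time, concentration, hen_id = "h1", matrix = "yolk") {
  structure(data.frame(time = time, concentration = concentration),
            class = c("residue_series", "data.frame"),
            hen_id = hen_id, matrix = matrix)
}

# exact log-linear "augmented" dataset: value = exp(intercept + slope*time),
# r replicates per timepoint
exact_line_data <- function(times, intercept, slope, reps = 3L) {
  data.frame(time = rep(times, each = reps),
             value = exp(intercept + slope * rep(times, each = reps)))
}

# regression constants for the seed-42 synthetic augmented fixture,
# frozen from the first verified run of the FDA tolerance-limit method
FROZEN_FDA_LOD <- 91.6145930340
FROZEN_FDA_2LLOQ <- 67.9145596289
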