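#' Experiment configuration
#'
#' Bundles everything needed for a reproducible growth-curve run: plate
#' geometry, seeding density, cycle configuration, survival-model
#' parameters, delayed-death dynamics and the treatment schedule.
#'
#' @param plate `"24-well"`, `"6-well"`, or a number giving a grid diameter
#'   in voxels directly (scaled test grids).
#' @param n0 initial number of seeded cells.
#' @param schedule a [treatment_schedule()] (default: untreated).
#' @param config a [cycle_config()].
#' @param rt_params [alphar_params()] for radiation, or `NULL`.
#' @param ht_params [alphar_params()] for heat (CEM43 units), or `NULL`.
#' @param slope_a thermo-radiosensitization slope for combined fractions.
#' @param dynamics a [death_dynamics()].
#' @param sensitivity a `phase_sensitivity` or `NULL` (solve per fraction).
#' @param t_end end of simulation, hours.
#' @param record_every curve sampling interval, hours (default 1).
#' @param mode `"delayed"` or `"instantaneous"` radiation kill.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(plate = "24-well", n0,
                              schedule = treatment_schedule(numeric(0)),
                              config = cycle_config(),
                              rt_params = NULL, ht_params = NULL,
                              slope_a = 0,
                              dynamics = death_dynamics(),
                              sensitivity = NULL,
                              t_end = 200, record_every = 1,
                              mode = c("delayed", "instantaneous")) {
  mode <- match.arg(mode)
  stopifnot(n0 >= 0, t_end > 0)
  structure(list(plate = plate, n0 = as.integer(n0), schedule = schedule,
                 config = config, rt_params = rt_params,
                 ht_params = ht_params, slope_a = slope_a,
                 dynamics = dynamics, sensitivity = sensitivity,
                 t_end = t_end, record_every = record_every, mode = mode),
            class = "experiment_config")
}

config_grid <- function(cfg) {
  if (is.numeric(cfg$plate)) return(ca_grid(diameter_voxels = cfg$plate))
  p <- plate_preset(cfg$plate)
  ca_grid(p$well_diameter_mm, p$voxel_edge_um)
}

#' Run a single replicate experiment
#'
#' Seeds the population, runs the treatment schedule and records the growth
#' curve. Fully deterministic given the seed.
#'
#' @param cfg an [experiment_config()].
#' @param seed integer RNG seed for this replicate.
#' @param ... overrides forwarded to [apply_fraction()] (e.g. `s_rt` for
#'   envelope runs).
#' @return A `growth_curve` data frame (time and compartment counts, plus a
#'   `viable` column = total - doomed - giant) with the final `ca_state` in
#'   attribute `"state"`.
#' @export
run_experiment <- function(cfg, seed = 1, ...) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(seed)
  grid <- config_grid(cfg)
  if (cfg$n0 > grid$capacity)
    stop("n0 exceeds the grid capacity (", grid$capacity, ")")
  state <- seed_population(cfg$n0, grid, cfg$config)
  state <- run_schedule(state, cfg$schedule, cfg$t_end, cfg$record_every,
                        dynamics = cfg$dynamics,
                        rt_params = cfg$rt_params, ht_params = cfg$ht_params,
                        slope_a = cfg$slope_a, sensitivity = cfg$sensitivity,
                        mode = cfg$mode, ...)
  curve <- state$curve
  curve$viable <- curve$total - curve$doomed - curve$giant
  class(curve) <- c("growth_curve", "data.frame")
  attr(curve, "state") <- state
  attr(curve, "seed") <- seed
  curve
}

#' Run a seeded replicate ensemble
#'
#' Runs `n_replicates` independent replicates (each with its own seed
#' derived from the master seed) and aggregates per-time-point means and
#' standard deviations for every compartment.
#'
#' @param cfg an [experiment_config()].
#' @param n_replicates number of replicates (>= 1).
#' @param seed master seed; replicate seeds are drawn from it.
#' @param ... forwarded to [run_experiment()].
#' @return An `ensemble_curve` data frame: `time`, then `<col>_mean` and
#'   `<col>_sd` for each compartment column; individual replicate curves in
#'   attribute `"replicates"`.
#' @export
run_ensemble <- function(cfg, n_replicates, seed = 1, ...) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  reps <- lapply(seeds, function(s) run_experiment(cfg, seed = s, ...))
  times <- reps[[1]]$time
  cols <- setdiff(names(reps[[1]]), "time")
  out <- data.frame(time = times)
  for (cn in cols) {
    mat <- vapply(reps, function(r) r[[cn]], numeric(length(times)))
    mat <- matrix(mat, nrow = length(times))
    out[[paste0(cn, "_mean")]] <- rowMeans(mat)
    out[[paste0(cn, "_sd")]] <- apply(mat, 1, stats::sd)
  }
  if (n_replicates == 1) out[grep("_sd$", names(out))] <- 0
  class(out) <- c("ensemble_curve", "data.frame")
  attr(out, "replicates") <- reps
  attr(out, "seeds") <- seeds
  out
}

#' Confidence-bound envelope runs
#'
#' Re-runs a single-fraction radiation experiment with the surviving
#' fraction pinned to the lower and upper bounds of its confidence interval
#' (clonogenic assays carry large uncertainties; the envelope shows how far
#' the predicted growth curve moves within them), alongside the central
#' run.
#'
#' @param cfg an [experiment_config()] whose schedule delivers radiation.
#' @param survival_ci numeric `c(low, high)` confidence bounds on the
#'   surviving fraction.
#' @param s_central optional central surviving fraction override (default:
#'   computed from `cfg$rt_params`).
#' @param n_replicates replicates per curve.
#' @param seed master seed (same for all three ensembles, isolating the
#'   survival effect).
#' @return A list of three `ensemble_curve`s: `central`, `lower`, `upper`.
#' @export
envelope_runs <- function(cfg, survival_ci, s_central = NULL,
                          n_replicates = 5, seed = 1) {
  stopifnot(length(survival_ci) == 2, survival_ci[1] <= survival_ci[2])
  if (!is.null(s_central))
    stopifnot(survival_ci[1] <= s_central, s_central <= survival_ci[2])
  central <- if (is.null(s_central))
    run_ensemble(cfg, n_replicates, seed) else
    run_ensemble(cfg, n_replicates, seed, s_rt = s_central)
  list(central = central,
       lower = run_ensemble(cfg, n_replicates, seed, s_rt = survival_ci[1]),
       upper = run_ensemble(cfg, n_replicates, seed, s_rt = survival_ci[2]))
}

#' Time of regrowth onset
#'
#' First recorded time after the last treatment fraction at which the mean
#' viable count exceeds its value at treatment end; `NA` if the population
#' never regrows within the record.
#'
#' @param ens an `ensemble_curve`.
#' @param treatment_end time of the last fraction, hours.
#' @return Time in hours, or `NA`.
#' @export
regrowth_onset <- function(ens, treatment_end) {
  v <- ens$viable_mean
  t <- ens$time
  i0 <- max(which(t <= treatment_end + 1e-9))
  after <- which(t > treatment_end & v > v[i0])
  if (!length(after)) return(NA_real_)
  t[min(after)]
}

#' Heat-timing fractionation sweep
#'
#' For a fixed fractionated radiation course, adds a single heat fraction
#' (given simultaneously with the radiation fraction of a chosen day) at
#' each candidate day in turn and compares the resulting ensemble growth
#' curves and regrowth-onset times.
#'
#' @param cfg an [experiment_config()] whose schedule is the radiation-only
#'   course; `ht_params` must be set.
#' @param heat_t43 thermal dose of the single heat fraction, CEM43.
#' @param candidate_days day indices (1-based fraction numbers) at which to
#'   try the heat fraction.
#' @param n_replicates replicates per candidate.
#' @param seed master seed, shared across candidates.
#' @return A list with `curves` (one `ensemble_curve` per candidate day) and
#'   `summary` (data frame: day, fraction time, regrowth onset).
#' @export
heat_timing_sweep <- function(cfg, heat_t43, candidate_days,
                              n_replicates = 5, seed = 1) {
  stopifnot(inherits(cfg, "experiment_config"),
            all(candidate_days >= 1),
            all(candidate_days <= nrow(cfg$schedule)))
  t_last <- max(cfg$schedule$time)
  curves <- list()
  onset <- numeric(length(candidate_days))
  for (i in seq_along(candidate_days)) {
    d <- candidate_days[i]
    cfg_i <- cfg
    cfg_i$schedule$t43[d] <- heat_t43
    ens <- run_ensemble(cfg_i, n_replicates, seed)
    curves[[i]] <- ens
    onset[i] <- regrowth_onset(ens, t_last)
  }
  names(curves) <- paste0("day", candidate_days)
  list(curves = curves,
       summary = data.frame(day = candidate_days,
                            fraction_time = cfg$schedule$time[candidate_days],
                            regrowth_onset = onset))
}

# ---- I/O --------------------------------------------------------------------

#' Write a growth curve as tidy long-format CSV
#'
#' One row per (time, compartment) pair; numeric values are written with
#' full precision so a round-trip through [read_growth_curve()] is exact.
#'
#' @param curve a `growth_curve` or `ensemble_curve` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_curve <- function(curve, path) {
  cols <- setdiff(names(curve), "time")
  long <- data.frame(
    time = rep(curve$time, times = length(cols)),
    compartment = rep(cols, each = nrow(curve)),
    count = unlist(lapply(cols, function(cn) curve[[cn]]), use.names = FALSE))
  long$count <- sprintf("%.17g", long$count)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a growth curve written by [write_growth_curve()]
#'
#' @param path CSV path.
#' @return A `growth_curve` data frame (wide format).
#' @export
read_growth_curve <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "compartment", "count") %in% names(long)))
  times <- unique(long$time)
  out <- data.frame(time = times)
  for (cn in unique(long$compartment))
    out[[cn]] <- long$count[long$compartment == cn]
  class(out) <- c("growth_curve", "data.frame")
  out
}

# small stable polynomial hash of a serialized object, for run manifests
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the configuration hash, seed and package version of a run as
#' JSON, for provenance alongside the curve CSV.
#'
#' @param cfg an [experiment_config()].
#' @param seed the master seed used.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, seed, path) {
  man <- list(
    config_hash = config_hash(cfg),
    seed = seed,
    n0 = cfg$n0,
    plate = cfg$plate,
    t_end = cfg$t_end,
    mode = cfg$mode,
    n_fractions = nrow(cfg$schedule),
    package = "thermorad",
    version = as.character(utils::packageVersion("thermorad")))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
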