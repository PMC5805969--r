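#' Reference growth curve
#'
#' Experiment-style reference data: mean cell counts (with SDs from
#' replicate wells) at a handful of observation times, plus the design
#' metadata needed to reproduce the matching simulation.
#'
#' @param times observation times, hours, strictly increasing.
#' @param mean_counts mean total cell counts (> 0 allowed to be 0 only for
#'   fully killed wells).
#' @param sd_counts per-time SDs (default 0).
#' @param metadata list of design metadata (treatment, plate, n0, ...).
#' @return A `reference_curve` object.
#' @export
reference_curve <- function(times, mean_counts, sd_counts = 0,
                            metadata = list()) {
  stopifnot(length(times) == length(mean_counts))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (any(mean_counts < 0)) stop("counts must be non-negative")
  structure(list(times = times, mean_counts = mean_counts,
                 sd_counts = rep_len(sd_counts, length(times)),
                 metadata = metadata),
            class = "reference_curve")
}

#' Coefficient of determination between simulation and reference
#'
#' Interpolates the simulated total-count curve linearly at the reference
#' times and returns `R^2 = 1 - SS_res / SS_tot` against the reference
#' means. Can be negative when the simulation fits worse than the reference
#' mean; 1 for a perfect fit.
#'
#' @param sim a `growth_curve`/`ensemble_curve` data frame (uses `total`, or
#'   `total_mean` for ensembles), or a list with `times` and `counts`.
#' @param ref a [reference_curve()].
#' @return The coefficient of determination (<= 1).
#' @export
r_squared <- function(sim, ref) {
  stopifnot(inherits(ref, "reference_curve"))
  if (length(ref$times) < 3) stop("need at least 3 reference points")
  if (is.data.frame(sim)) {
    st <- sim$time
    sc <- if ("total_mean" %in% names(sim)) sim$total_mean else sim$total
  } else {
    st <- sim$times; sc <- sim$counts
  }
  pred <- stats::approx(st, sc, xout = ref$times, rule = 2)$y
  obs <- ref$mean_counts
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Generate a synthetic reference growth curve
#'
#' Runs a replicate ensemble under the given configuration, samples its
#' mean total count at experiment-like observation times and perturbs the
#' means with multiplicative Gaussian noise, emitting triplicate-style SDs.
#' A synthetic stand-in for haemocytometer-counted growth curves, used for
#' parameter-recovery testing of the calibration.
#'
#' @param cfg an [experiment_config()].
#' @param noise_sd_fraction multiplicative noise SD as a fraction of the
#'   mean (default 0.05).
#' @param sample_times observation times, hours (default every 24 h from 24
#'   to `cfg$t_end`).
#' @param n_replicates ensemble size behind the means.
#' @param seed RNG seed.
#' @return A [reference_curve()] with the generating configuration in its
#'   metadata.
#' @export
make_reference_fixture <- function(cfg, noise_sd_fraction = 0.05,
                                   sample_times = NULL,
                                   n_replicates = 3, seed = 1) {
  stopifnot(noise_sd_fraction >= 0)
  if (is.null(sample_times))
    sample_times <- seq(24, cfg$t_end, by = 24)
  ens <- run_ensemble(cfg, n_replicates, seed = seed)
  mu <- stats::approx(ens$time, ens$total_mean, xout = sample_times,
                      rule = 2)$y
  set.seed(seed + 1L)
  noisy <- mu * (1 + stats::rnorm(length(mu), 0, noise_sd_fraction))
  noisy <- pmax(noisy, 0)
  sds <- stats::approx(ens$time, ens$total_sd, xout = sample_times,
                       rule = 2)$y
  reference_curve(sample_times, noisy,
                  sd_counts = pmax(sds, noise_sd_fraction * mu),
                  metadata = list(config = cfg, seed = seed,
                                  noise_sd_fraction = noise_sd_fraction,
                                  synthetic = TRUE))
}

#' Fit the delayed-death parameters by grid search
#'
#' Exhaustive seeded grid search over `(k_delay, p_mitoticCat)`:
#' for every grid point the treatment experiment is re-simulated as a small
#' ensemble and scored by [r_squared()] against the reference curve; the
#' argmax is returned together with the full R^2 surface. `p_senescence`
#' is held fixed. A grid search (rather than a gradient method) is used
#' because the objective is a noisy stochastic-simulation output; with
#' fixed seeds the whole fit is deterministic and the surface inspectable.
#'
#' @param ref a [reference_curve()].
#' @param cfg an [experiment_config()] describing the treatment experiment
#'   (its `dynamics` supplies the fixed `p_senescence`).
#' @param k_delay_grid candidate death-delay rates, h^-1.
#' @param p_mcat_grid candidate mitotic-catastrophe probabilities.
#' @param n_replicates ensemble size per grid point.
#' @param seed master seed (same for every grid point, so the surface is
#'   smooth in the parameters).
#' @return A list: `k_delay`, `p_mitoticCat` (argmax), `r2` (its score),
#'   `surface` (data frame k_delay x p_mitoticCat x r2), `flat` (TRUE when
#'   the surface is numerically constant, i.e. the parameters are
#'   unidentifiable from this reference).
#' @export
fit_death_dynamics <- function(ref, cfg,
                               k_delay_grid = seq(0.003, 0.027, by = 0.003),
                               p_mcat_grid = seq(0.05, 0.5, by = 0.05),
                               n_replicates = 3, seed = 1) {
  stopifnot(inherits(ref, "reference_curve"),
            inherits(cfg, "experiment_config"))
  if (!length(k_delay_grid) || !length(p_mcat_grid))
    stop("empty parameter grid")
  grid <- expand.grid(k_delay = k_delay_grid, p_mitoticCat = p_mcat_grid)
  grid$r2 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg_i <- cfg
    cfg_i$dynamics <- death_dynamics(
      k_delay = grid$k_delay[i], p_mitoticCat = grid$p_mitoticCat[i],
      p_senescence = cfg$dynamics$p_senescence)
    ens <- run_ensemble(cfg_i, n_replicates, seed = seed)
    grid$r2[i] <- r_squared(ens, ref)
  }
  best <- which.max(grid$r2)
  list(k_delay = grid$k_delay[best],
       p_mitoticCat = grid$p_mitoticCat[best],
       r2 = grid$r2[best],
       surface = grid,
       flat = diff(range(grid$r2)) < 1e-9)
}
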