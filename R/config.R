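#' Read cell-line parameters from YAML
#'
#' Reads a cell-line description with the doubling time, phase fractions,
#' per-modality AlphaR parameters, combination slope, delayed-death
#' parameters and optional explicit gamma overrides. Any block may be
#' omitted; defaults come from the corresponding constructors.
#'
#' Expected layout (all keys optional except `doubling_time_h` and the
#' modality blocks actually used):
#' ```yaml
#' name: HCT116
#' doubling_time_h: 19.5
#' rate_sd_fraction: 0.05
#' lag_hours: 2
#' phase_fractions: {G1: 0.40, S: 0.35, G2: 0.20, M: 0.05}
#' rt: {alpha: 0.5, beta: 0.042}
#' ht: {alpha0: 0.1, alphaR: 0.1, beta: 0.005}
#' combination: {slope_a: 0.01}
#' dynamics: {k_delay: 0.009, p_mitoticCat: 0.2, p_senescence: 0.05}
#' gamma: {G1: 1.0, S: 0.9, G2: 1.1, M: 1.2}
#' ```
#'
#' @param path YAML file path.
#' @return A list with `name`, `config` ([cycle_config()]), `rt_params`,
#'   `ht_params`, `slope_a`, `dynamics` and `sensitivity` (`NULL` unless a
#'   `gamma` block is present).
#' @export
read_cell_line <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$doubling_time_h)) stop("cell-line file lacks doubling_time_h")
  pf <- if (!is.null(y$phase_fractions)) unlist(y$phase_fractions) else
    c(G1 = 0.40, S = 0.35, G2 = 0.20, M = 0.05)
  cfg <- cycle_config(
    mean_doubling_time = y$doubling_time_h,
    rate_sd_fraction = if (is.null(y$rate_sd_fraction)) 0.05 else
      y$rate_sd_fraction,
    phase_fractions = pf,
    lag_hours = if (is.null(y$lag_hours)) 2 else y$lag_hours)
  rt <- if (!is.null(y$rt))
    do.call(alphar_params, y$rt) else NULL
  ht <- if (!is.null(y$ht))
    do.call(alphar_params, y$ht) else NULL
  dyn <- if (!is.null(y$dynamics))
    do.call(death_dynamics, y$dynamics) else death_dynamics()
  sens <- if (!is.null(y$gamma))
    phase_sensitivity_manual(unlist(y$gamma)) else NULL
  list(name = y$name, config = cfg, rt_params = rt, ht_params = ht,
       slope_a = if (is.null(y$combination$slope_a)) 0 else
         y$combination$slope_a,
       dynamics = dyn, sensitivity = sens)
}

#' Read a treatment schedule from CSV
#'
#' One row per fraction with columns `time` (h), `dose_Gy` and `t43`
#' (CEM43); missing dose columns default to 0.
#'
#' @param path CSV file path.
#' @return A [treatment_schedule()].
#' @export
read_schedule <- function(path) {
  d <- utils::read.csv(path)
  if (!"time" %in% names(d)) stop("schedule CSV needs a `time` column")
  treatment_schedule(d$time,
                     dose_Gy = if ("dose_Gy" %in% names(d)) d$dose_Gy else 0,
                     t43 = if ("t43" %in% names(d)) d$t43 else 0)
}
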