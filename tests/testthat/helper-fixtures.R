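# shared fixtures: scaled-down grids and the HCT116 parameter set

hct116_rt <- function() alphar_params(alpha = 0.5, beta = 0.042)

# heat parameters in CEM43 units with a visible shoulder; alpha0 = alphaR
# as fitted for hyperthermia survival curves
demo_ht <- function() alphar_params(alpha0 = 0.1, alphaR = 0.1, beta = 0.005)

# a small circular grid for desk-scale runs
small_grid <- function(d = 41) ca_grid(diameter_voxels = d)

# config for a scaled treated experiment on a small grid
small_cfg <- function(n0 = 500, d = 101, t_end = 120,
                      schedule = treatment_schedule(numeric(0)), ...) {
  experiment_config(plate = d, n0 = n0, schedule = schedule,
                    t_end = t_end, ...)
}

# log-linear estimate of the population doubling time over [t1, t2]
fit_doubling_time <- function(curve, t1 = 24, t2 = 96) {
  sel <- curve$time >= t1 & curve$time <= t2 & curve$total > 0
  stats::coef(stats::lm(log2(curve$total[sel]) ~ curve$time[sel]))[[2]]^-1
}
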