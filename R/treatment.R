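#' Delayed-death dynamics parameters
#'
#' Radiation-induced cell death is not instantaneous: a cell that fails the
#' survival draw is "doomed" and assigned a delay to death sampled from an
#' exponential distribution with rate `k_delay`. Until then it keeps
#' proliferating (daughters inherit the death time) and at each M exit may
#' enter mitotic catastrophe with probability `p_mitoticCat`, becoming
#' senescent with probability `p_senescence` or a giant cell otherwise.
#' Defaults are the calibrated HCT116 values.
#'
#' @param k_delay exponential rate of the death-delay distribution, h^-1
#'   (default 0.009; mean delay ~111 h).
#' @param p_mitoticCat probability of mitotic catastrophe at M exit of a
#'   doomed cell (default 0.2).
#' @param p_senescence probability that a catastrophe yields a senescent
#'   rather than a giant cell (default 0.05).
#' @return A `death_dynamics` object.
#' @export
death_dynamics <- function(k_delay = 0.009, p_mitoticCat = 0.2,
                           p_senescence = 0.05) {
  stopifnot(k_delay > 0,
            p_mitoticCat >= 0, p_mitoticCat <= 1,
            p_senescence >= 0, p_senescence <= 1)
  structure(list(k_delay = k_delay, p_mitoticCat = p_mitoticCat,
                 p_senescence = p_senescence),
            class = "death_dynamics")
}

#' Sample delays to radiation-induced death
#'
#' @param n number of draws.
#' @param dynamics a [death_dynamics()].
#' @return Exponential variates (hours) with rate `k_delay`, mean
#'   `1/k_delay`.
#' @export
sample_death_delay <- function(n, dynamics = death_dynamics()) {
  stopifnot(inherits(dynamics, "death_dynamics"))
  stats::rexp(n, rate = dynamics$k_delay)
}

#' Mitotic fate of a doomed cell at M exit
#'
#' Decision applied by the engine whenever a doomed cell completes its
#' cycle: with probability `1 - p_mitoticCat` it divides normally (the
#' daughter inherits the parent's death time); otherwise it undergoes
#' mitotic catastrophe and becomes senescent (probability `p_senescence`;
#' permanently viable, never divides) or giant (no daughters, size counter
#' increments at each further attempted division, dies at its scheduled
#' death time). Exposed for direct testing of the branch probabilities.
#'
#' @param n number of independent draws (doomed M exits).
#' @param dynamics a [death_dynamics()].
#' @return Character vector over `"divide"`, `"giant"`, `"senescent"`.
#' @export
mitotic_fate <- function(n, dynamics = death_dynamics()) {
  stopifnot(inherits(dynamics, "death_dynamics"))
  cat_draw <- stats::runif(n) < dynamics$p_mitoticCat
  sen_draw <- stats::runif(n) < dynamics$p_senescence
  ifelse(!cat_draw, "divide", ifelse(sen_draw, "senescent", "giant"))
}

#' Treatment schedule
#'
#' A sequence of treatment fractions, each delivering a radiation dose
#' and/or a thermal dose at an absolute simulation time.
#'
#' @param time fraction times, hours, non-decreasing.
#' @param dose_Gy radiation dose per fraction, Gy (recycled).
#' @param t43 thermal dose per fraction, CEM43 (recycled); pass a
#'   [thermal_profile()] through [cem43()] to obtain it.
#' @return A `treatment_schedule` data frame with columns
#'   `time`, `dose_Gy`, `t43`.
#' @export
treatment_schedule <- function(time, dose_Gy = 0, t43 = 0) {
  stopifnot(is.numeric(time))
  if (is.unsorted(time)) stop("fraction times must be non-decreasing")
  if (any(dose_Gy < 0) || any(t43 < 0)) stop("doses must be >= 0")
  out <- data.frame(time = time,
                    dose_Gy = rep_len(dose_Gy, length(time)),
                    t43 = rep_len(t43, length(time)))
  class(out) <- c("treatment_schedule", "data.frame")
  out
}

#' Evenly spaced fractions
#'
#' Expands "n fractions of d Gy every 24 h" into a schedule.
#'
#' @param n_fractions number of fractions.
#' @param dose_Gy dose per fraction, Gy.
#' @param interval_h spacing in hours (default 24).
#' @param start_h time of the first fraction (default 0).
#' @param t43 thermal dose accompanying each fraction (default 0).
#' @return A [treatment_schedule()].
#' @export
schedule_every <- function(n_fractions, dose_Gy, interval_h = 24,
                           start_h = 0, t43 = 0) {
  stopifnot(n_fractions >= 0)
  treatment_schedule(start_h + interval_h * (seq_len(n_fractions) - 1),
                     dose_Gy = dose_Gy, t43 = t43)
}

#' Weekday (Mon-Fri) fractionation
#'
#' Expands a clinical-style schedule of one fraction per day, five days a
#' week, skipping weekends, e.g. 30 fractions delivered over six weeks.
#'
#' @param n_fractions number of fractions.
#' @param dose_Gy dose per fraction, Gy.
#' @param start_h time of the first fraction (a Monday), hours.
#' @return A [treatment_schedule()].
#' @export
schedule_weekdays <- function(n_fractions, dose_Gy, start_h = 0) {
  stopifnot(n_fractions >= 0)
  day <- integer(0); d <- 0
  while (length(day) < n_fractions) {
    if (d %% 7 < 5) day <- c(day, d)    # days 0-4 of each week treat
    d <- d + 1
  }
  treatment_schedule(start_h + 24 * day, dose_Gy = dose_Gy)
}

# drop cells `idx` from the state, keeping occupancy and counters consistent
remove_cells <- function(state, idx) {
  if (!length(idx)) return(state)
  cl <- state$cells
  lin <- (cl$pos_y[idx] - 1L) * state$grid$n + cl$pos_x[idx]
  state$grid$occ[lin] <- 0L
  keep <- setdiff(seq_along(cl$pos_x), idx)
  state$cells <- lapply(cl, `[`, keep)
  # renumber surviving cells in the occupancy grid
  lin_keep <- (state$cells$pos_y - 1L) * state$grid$n + state$cells$pos_x
  state$grid$occ[lin_keep] <- seq_along(lin_keep)
  state$removed <- state$removed + length(idx)
  state
}

#' Apply one treatment fraction
#'
#' Implements the per-cell treatment decision tree. Every cell draws
#' `N ~ Uniform(0, 1)` and is compared against the surviving fractions of
#' the delivered modality:
#'
#' * heat only: cells with `N > S_HT` are removed immediately (heat kill is
#'   instantaneous);
#' * radiation only: cells with `N > S_RT` (phase-weighted) are doomed, with
#'   death time `now + Exp(k_delay)`;
#' * combined: cells with `N > S_HT` are removed immediately; cells with
#'   `S_HT >= N > S_RTHT` follow radiation-style delayed death.
#'
#' Radiation survival is weighted by each cell's current cycle phase
#' (`S^gamma_phase`); the weighting applies to the radiation factor of
#' combined treatments too, while heat kill is phase-independent. Senescent
#' cells are inert to treatment. Already-doomed cells hit by a later
#' fraction keep their schedule unless the new draw implies an earlier
#' death (`refraction = "earliest"`, the default) or are skipped entirely
#' (`"ignore"`).
#'
#' @param state a `ca_state`.
#' @param dose_Gy radiation dose of this fraction, Gy.
#' @param t43 thermal dose of this fraction, CEM43 (or a
#'   [thermal_profile()], which is converted).
#' @param rt_params [alphar_params()] for radiation (Gy units). Required
#'   when `dose_Gy > 0` unless `s_rt` is given.
#' @param ht_params [alphar_params()] for heat (CEM43 units). Required when
#'   `t43 > 0` unless `s_ht` is given.
#' @param slope_a thermo-radiosensitization slope (Gy^-1 per CEM43) for
#'   combined fractions.
#' @param sensitivity a `phase_sensitivity`, or `NULL` to solve the
#'   ratio-1.5 map at this fraction's radiation survival (uniform weighting
#'   when no radiation is delivered).
#' @param dynamics a [death_dynamics()].
#' @param mode `"delayed"` (default) or `"instantaneous"`: in instantaneous
#'   mode cells failing the radiation draw are removed at the moment of
#'   treatment instead of being doomed (comparison experiments).
#' @param refraction policy for doomed cells hit again: `"earliest"` or
#'   `"ignore"`.
#' @param s_rt,s_ht,s_rtht optional explicit surviving fractions overriding
#'   the model-computed values (used for confidence-bound envelope runs).
#' @return The updated `ca_state`.
#' @export
apply_fraction <- function(state, dose_Gy = 0, t43 = 0,
                           rt_params = NULL, ht_params = NULL, slope_a = 0,
                           sensitivity = NULL,
                           dynamics = death_dynamics(),
                           mode = c("delayed", "instantaneous"),
                           refraction = c("earliest", "ignore"),
                           s_rt = NULL, s_ht = NULL, s_rtht = NULL) {
  stopifnot(inherits(state, "ca_state"))
  mode <- match.arg(mode)
  refraction <- match.arg(refraction)
  if (inherits(t43, "thermal_profile")) t43 <- cem43(t43)
  stopifnot(dose_Gy >= 0, t43 >= 0)
  now <- state$time

  has_rt <- dose_Gy > 0 || !is.null(s_rt) || !is.null(s_rtht)
  has_ht <- t43 > 0 || !is.null(s_ht)
  if (!has_rt && !has_ht) return(state)

  # population-level surviving fractions of this fraction
  if (has_ht) {
    if (is.null(s_ht)) {
      if (is.null(ht_params)) stop("heat delivered but no ht_params / s_ht")
      s_ht <- ht_survival(t43, ht_params)
    }
  } else s_ht <- 1
  if (has_rt) {
    if (has_ht) {
      if (is.null(s_rtht)) {
        if (is.null(rt_params))
          stop("combined fraction but no rt_params / s_rtht")
        cp <- combination_params(rt_params$alpha0 - rt_params$alphaR,
                                 rt_params$beta, slope_a, ht_params)
        s_rtht <- rtht_survival(dose_Gy, t43, cp)
      }
      s_rt_factor <- s_rtht / s_ht   # radiation factor of the combination
    } else {
      if (is.null(s_rt)) {
        if (is.null(rt_params)) stop("radiation delivered but no rt_params / s_rt")
        s_rt <- alphar_survival(dose_Gy, rt_params)
      }
      s_rt_factor <- s_rt
    }
  } else s_rt_factor <- 1

  # a fraction that cannot affect any cell consumes no randomness
  if (s_ht >= 1 && s_rt_factor >= 1) return(state)

  if (is.null(sensitivity)) {
    sensitivity <- if (s_rt_factor > 0 && s_rt_factor < 1)
      phase_sensitivity(s_rt_factor,
                        state$config$phase_fractions) else
      phase_sensitivity_uniform()
  }

  cl <- state$cells
  m <- length(cl$pos_x)
  if (m == 0) return(state)

  # current phase of every cell (doomed cells cycle too; giants treated as
  # cycling for weighting purposes; senescent handled below)
  phase <- rep("G0", m)
  cyc <- !cl$quiescent & cl$fate != 2L
  phase[cyc] <- assign_phase(pmin(cl$clock[cyc], cl$duration[cyc]),
                             cl$duration[cyc], state$config)

  s_rt_cell <- phase_weighted_survival(s_rt_factor, phase, sensitivity)
  s_kill <- s_ht * s_rt_cell            # overall per-cell surviving fraction

  N <- stats::runif(m)
  senescent <- cl$fate == 2L

  # instantaneous heat kill (phase-independent)
  ht_kill <- has_ht & N > s_ht & !senescent
  # radiation-induced delayed death
  rt_doom <- has_rt & !ht_kill & N > s_kill & !senescent
  if (refraction == "ignore") rt_doom <- rt_doom & cl$fate == 0L

  if (mode == "instantaneous") {
    kill_now <- which(ht_kill | rt_doom)
    return(remove_cells(state, kill_now))
  }

  doom_idx <- which(rt_doom)
  if (length(doom_idx)) {
    delay <- sample_death_delay(length(doom_idx), dynamics)
    new_dt <- now + delay
    old_dt <- cl$death_time[doom_idx]
    upd <- cl$fate[doom_idx] == 0L | new_dt < old_dt   # earliest-death wins
    tgt <- doom_idx[upd]
    state$cells$death_time[tgt] <- new_dt[upd]
    newly <- tgt[state$cells$fate[tgt] == 0L]
    state$cells$fate[newly] <- 1L
  }
  remove_cells(state, which(ht_kill))
}

#' Run a full treatment schedule against a state
#'
#' Alternates [advance()] and [apply_fraction()] over the fractions of a
#' schedule, then advances to `t_end`.
#'
#' @param state a `ca_state`.
#' @param schedule a [treatment_schedule()].
#' @param t_end final simulation time, hours.
#' @param record_every growth-curve sampling interval, hours.
#' @param ... passed to [apply_fraction()] (parameters, sensitivity,
#'   dynamics, mode, overrides).
#' @param dynamics a [death_dynamics()]; used both by the engine (mitotic
#'   catastrophe) and the fraction draws.
#' @return The final `ca_state` with the full recorded curve.
#' @export
run_schedule <- function(state, schedule, t_end, record_every = 1,
                         dynamics = death_dynamics(), ...) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  for (i in seq_len(nrow(schedule))) {
    ft <- schedule$time[i]
    if (ft > t_end) break
    if (ft > state$time)
      state <- advance(state, ft, record_every, dynamics)
    state <- apply_fraction(state, dose_Gy = schedule$dose_Gy[i],
                            t43 = schedule$t43[i], dynamics = dynamics, ...)
  }
  if (t_end > state$time)
    state <- advance(state, t_end, record_every, dynamics)
  state
}
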