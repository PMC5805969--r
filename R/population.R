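#' Cell-cycle configuration
#'
#' Timing parameters of the four-stage cycle. Each cell owns an individual
#' cycle duration drawn from a normal distribution around the population
#' doubling time (5% SD by default, truncated at three SDs). The cycle is
#' split into G1, S, G2 and M by fixed fractions; G2 and M default to 20%
#' and 5%. Freshly seeded populations pass through an attachment lag during
#' which the cycle clock is frozen (treatment can still kill during lag).
#'
#' @param mean_doubling_time mean cycle duration in hours (default 19.5, the
#'   calibrated HCT116 value).
#' @param rate_sd_fraction SD of individual cycle durations as a fraction of
#'   the mean (default 0.05).
#' @param phase_fractions named fractions of the cycle spent in
#'   `G1, S, G2, M`; must sum to 1.
#' @param lag_hours attachment lag after seeding, hours (default 2).
#' @param dt_hours simulation time step in hours (default 0.5, resolving the
#'   ~1 h M-phase).
#' @return A `cycle_config` object.
#' @export
cycle_config <- function(mean_doubling_time = 19.5,
                         rate_sd_fraction = 0.05,
                         phase_fractions = c(G1 = 0.40, S = 0.35,
                                             G2 = 0.20, M = 0.05),
                         lag_hours = 2,
                         dt_hours = 0.5) {
  stopifnot(mean_doubling_time > 0, rate_sd_fraction >= 0,
            lag_hours >= 0, dt_hours > 0)
  need <- c("G1", "S", "G2", "M")
  if (!all(need %in% names(phase_fractions)))
    stop("phase_fractions must name G1, S, G2, M")
  pf <- phase_fractions[need]
  if (any(pf < 0) || abs(sum(pf) - 1) > 1e-9)
    stop("phase fractions must be non-negative and sum to 1")
  structure(list(mean_doubling_time = mean_doubling_time,
                 rate_sd_fraction = rate_sd_fraction,
                 phase_fractions = pf, lag_hours = lag_hours,
                 dt_hours = dt_hours),
            class = "cycle_config")
}

.FATE_LEVELS <- c("viable", "doomed", "senescent", "giant")

# truncated-normal cycle durations (+/- 3 sd, positive)
draw_durations <- function(n, config) {
  mu <- config$mean_doubling_time
  sd <- config$rate_sd_fraction * mu
  if (sd == 0 || n == 0) return(rep(mu, n))
  d <- stats::rnorm(n, mu, sd)
  bad <- abs(d - mu) > 3 * sd | d <= 0
  while (any(bad)) {
    d[bad] <- stats::rnorm(sum(bad), mu, sd)
    bad <- abs(d - mu) > 3 * sd | d <= 0
  }
  d
}

#' Cycle phase from the cell clock
#'
#' Phases occupy consecutive half-open intervals `[start, end)` of the
#' individual cycle duration, in the order G1, S, G2, M, with boundaries at
#' the cumulative phase fractions. A clock exactly at the duration maps to M.
#'
#' @param cycle_clock hours into the current cycle (vectorized).
#' @param cycle_duration individual cycle duration(s), hours.
#' @param config a [cycle_config()].
#' @return Character vector of phases.
#' @export
assign_phase <- function(cycle_clock, cycle_duration, config) {
  stopifnot(inherits(config, "cycle_config"))
  if (any(cycle_clock < 0 | cycle_clock > cycle_duration))
    stop("cycle_clock must lie in [0, cycle_duration]")
  frac <- pmin(cycle_clock / cycle_duration, 1 - 1e-12)
  cf <- cumsum(config$phase_fractions)
  c("G1", "S", "G2", "M")[
    findInterval(frac, c(0, cf[1:3]), rightmost.closed = FALSE)]
}

#' Seed a population onto the lattice
#'
#' Places `n` cells at uniformly random distinct in-well voxels. Cycle
#' durations are drawn from the truncated normal of the config; clocks are
#' drawn uniformly over each cell's cycle so that the initial phase
#' occupancies match the configured phase fractions in expectation.
#'
#' @param n number of cells; at most the grid capacity.
#' @param grid a [ca_grid()].
#' @param config a [cycle_config()].
#' @return A `ca_state` simulation state: grid (with occupancy), cell
#'   vectors, simulation time (0 h) and creation/removal counters.
#' @export
seed_population <- function(n, grid, config = cycle_config()) {
  stopifnot(inherits(grid, "ca_grid"), inherits(config, "cycle_config"))
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  if (n > grid$capacity)
    stop("cannot seed ", n, " cells on a grid of capacity ", grid$capacity)
  free <- which(grid$mask & grid$occ == 0L)
  sel <- if (n > 0) sample(free, n) else integer(0)
  occ <- grid$occ
  occ[sel] <- seq_len(n)
  grid$occ <- occ
  dur <- draw_durations(n, config)
  cells <- list(
    pos_x = as.integer((sel - 1L) %% grid$n + 1L),
    pos_y = as.integer((sel - 1L) %/% grid$n + 1L),
    clock = stats::runif(n, 0, dur),
    duration = dur,
    fate = integer(n),
    death_time = rep(Inf, n),
    ntoggle = as.integer(stats::runif(n) < 0.5),
    giant_size = integer(n),
    quiescent = logical(n))
  structure(list(grid = grid, cells = cells, time = 0,
                 created = n, removed = 0, config = config),
            class = "ca_state")
}

#' @export
print.ca_state <- function(x, ...) {
  cc <- count_compartments(x)
  cat(sprintf("CA state at t = %g h: %d cells (%d viable cycling, %d G0, %d doomed, %d senescent, %d giant)\n",
              x$time, cc[["total"]],
              cc[["G1"]] + cc[["S"]] + cc[["G2"]] + cc[["M"]],
              cc[["G0"]], cc[["doomed"]], cc[["senescent"]], cc[["giant"]]))
  invisible(x)
}

#' Compartment counts of a simulation state
#'
#' @param state a `ca_state`.
#' @return Named integer vector: viable cycling cells by phase
#'   (`G1, S, G2, M`), quiescent (`G0`), `doomed`, `senescent`, `giant`, and
#'   `total` (their sum = all cells on the grid).
#' @export
count_compartments <- function(state) {
  stopifnot(inherits(state, "ca_state"))
  cl <- state$cells
  out <- c(G1 = 0L, S = 0L, G2 = 0L, M = 0L, G0 = 0L,
           doomed = 0L, senescent = 0L, giant = 0L)
  cyc <- cl$fate == 0L & !cl$quiescent
  if (any(cyc)) {
    ph <- assign_phase(cl$clock[cyc], cl$duration[cyc], state$config)
    tb <- table(factor(ph, levels = c("G1", "S", "G2", "M")))
    out[c("G1", "S", "G2", "M")] <- as.integer(tb)
  }
  out["G0"] <- sum(cl$fate == 0L & cl$quiescent)
  out["doomed"] <- sum(cl$fate == 1L)
  out["senescent"] <- sum(cl$fate == 2L)
  out["giant"] <- sum(cl$fate == 3L)
  c(out, total = sum(out))
}

#' Advance the cellular automaton
#'
#' Runs the simulation from the state's current time to `t_end`. In each
#' time step, cells (visited in a fresh random permutation to avoid spatial
#' bias) advance their cycle clock; on cycle completion a cell divides into
#' a uniformly chosen free voxel of the nearest non-empty neighbourhood
#' shell (Moore and Von Neumann neighbourhoods alternate per cell between
#' division attempts, giving circular colony growth), or enters reversible
#' quiescence (G0) when no voxel is free up to third-order neighbours.
#' Quiescent cells re-check for space each step. Doomed cells divide
#' normally (daughters inherit the parent's death time) but may enter
#' mitotic catastrophe at M exit, becoming senescent or giant; cells whose
#' death time has passed are removed.
#'
#' @param state a `ca_state` from [seed_population()] or a previous call.
#' @param t_end absolute simulation time to advance to, hours.
#' @param record_every sampling interval for the growth curve, hours
#'   (default 1); `NULL` records only the end point.
#' @param dynamics a [death_dynamics()] providing the mitotic-catastrophe
#'   and senescence probabilities.
#' @return The updated `ca_state`, with the recorded counts appended to
#'   `state$curve` (data frame: time and compartment counts).
#' @export
advance <- function(state, t_end, record_every = 1,
                    dynamics = death_dynamics()) {
  stopifnot(inherits(state, "ca_state"), t_end >= state$time)
  cfg <- state$config
  record_times <- if (is.null(record_every)) t_end else
    unique(c(seq(state$time, t_end, by = record_every), t_end))
  cl <- state$cells
  res <- engine_run(
    occ = as.integer(state$grid$occ), mask = as.integer(state$grid$mask),
    n = state$grid$n,
    pos_x = cl$pos_x, pos_y = cl$pos_y, clock_ = cl$clock,
    dur = cl$duration, fate = cl$fate, death_time = cl$death_time,
    ntoggle = cl$ntoggle, giant_size = cl$giant_size,
    quiescent = cl$quiescent,
    t0 = state$time, t_end = t_end, dt = cfg$dt_hours,
    lag_until = cfg$lag_hours,
    mean_duration = cfg$mean_doubling_time,
    sd_fraction = cfg$rate_sd_fraction,
    p_mcat = dynamics$p_mitoticCat, p_sen = dynamics$p_senescence,
    cum_fractions = cumsum(cfg$phase_fractions)[1:3],
    record_times = record_times,
    created0 = state$created, removed0 = state$removed)
  state$cells <- list(
    pos_x = res$pos_x, pos_y = res$pos_y, clock = res$clock,
    duration = res$duration, fate = res$fate, death_time = res$death_time,
    ntoggle = res$ntoggle, giant_size = res$giant_size,
    quiescent = res$quiescent)
  state$grid$occ <- matrix(res$occ, state$grid$n, state$grid$n)
  state$time <- t_end
  state$created <- res$created
  state$removed <- res$removed
  curve <- as.data.frame(res$curve)
  names(curve) <- c("time", "G1", "S", "G2", "M", "G0",
                    "doomed", "senescent", "giant", "total")
  if (!is.null(state$curve) && nrow(state$curve) > 0) {
    # avoid duplicating the boundary sample between consecutive segments
    curve <- curve[curve$time > max(state$curve$time) + 1e-9, , drop = FALSE]
  }
  state$curve <- rbind(state$curve, curve)
  state
}
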