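#' AlphaR dose-response parameters
#'
#' Container for the parameters of the AlphaR clonogenic-survival model:
#' damage induction `alpha0`, damage repair `alphaR` and loss of repair
#' capacity with dose `beta`. Below a threshold dose `D_T` survival follows a
#' linear-quadratic (LQ) exponential, `exp(-(alpha0 - alphaR) d - beta d^2)`;
#' above `D_T` repair is exhausted and survival decays as a single
#' exponential. With the default (derived) threshold `D_T = alphaR / beta`
#' the post-threshold arm is `exp(-alpha0 d)` and the curve is exactly
#' continuous at `D_T`.
#'
#' For radiation-only fits that never leave the LQ regime pass `alpha`
#' (`= alpha0 - alphaR`) and `beta` only; the threshold is then infinite.
#' For hyperthermia `alpha0 = alphaR`, giving a pure shoulder
#' `exp(-beta t43^2)` below `D_T`. Dose units are Gy for radiation and CEM43
#' (cumulative equivalent minutes at 43 degrees C) for heat.
#'
#' @param alpha0 damage rate per unit dose (Gy^-1 or CEM43^-1).
#' @param alphaR repair rate per unit dose; `0 <= alphaR <= alpha0`.
#' @param beta quadratic coefficient per unit dose squared (>= 0).
#' @param alpha shorthand for the LQ difference `alpha0 - alphaR`; when given
#'   (and `alpha0` is not), the model is the pure LQ arm with no threshold.
#' @param D_T optional explicit threshold dose. Defaults to `alphaR / beta`
#'   when both are positive, else `Inf`. If supplied explicitly the
#'   post-threshold arm is `S(D_T) * exp(-alpha0 (d - D_T))`, which keeps the
#'   curve continuous for any choice of `D_T`.
#' @return An object of class `alphar_params`.
#' @examples
#' rt <- alphar_params(alpha = 0.5, beta = 0.042)   # HCT116 radiation
#' alphar_survival(2, rt)                            # ~0.31
#' ht <- alphar_params(alpha0 = 0.1, alphaR = 0.1, beta = 0.005)
#' alphar_survival(10, ht)                           # exp(-0.5)
#' @export
alphar_params <- function(alpha0 = NULL, alphaR = NULL, beta = 0,
                          alpha = NULL, D_T = NULL) {
  if (is.null(alpha0)) {
    if (is.null(alpha))
      stop("supply either `alpha0` (+ `alphaR`) or `alpha`")
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
    alpha0 <- alpha
    alphaR <- 0
    if (is.null(D_T)) D_T <- Inf
  }
  if (is.null(alphaR)) alphaR <- 0
  stopifnot(is.numeric(alpha0), is.numeric(alphaR), is.numeric(beta),
            length(alpha0) == 1L, length(alphaR) == 1L, length(beta) == 1L)
  if (alphaR < 0 || alpha0 < alphaR)
    stop("need alpha0 >= alphaR >= 0")
  if (beta < 0) stop("beta must be >= 0")
  explicit_DT <- !is.null(D_T)
  if (is.null(D_T))
    D_T <- if (beta > 0 && alphaR > 0) alphaR / beta else Inf
  stopifnot(D_T > 0)
  structure(
    list(alpha0 = alpha0, alphaR = alphaR, beta = beta,
         D_T = D_T, explicit_DT = explicit_DT),
    class = "alphar_params")
}

#' @export
print.alphar_params <- function(x, ...) {
  cat(sprintf(
    "AlphaR parameters: alpha0 = %g, alphaR = %g, beta = %g, D_T = %g\n",
    x$alpha0, x$alphaR, x$beta, x$D_T))
  invisible(x)
}

#' AlphaR surviving fraction
#'
#' Evaluates the AlphaR model at the given dose(s): the LQ arm
#' `exp(-(alpha0 - alphaR) d - beta d^2)` for `d <= D_T`, and a single
#' exponential beyond the threshold. Survival is 1 at zero dose, continuous
#' at `D_T`, and non-increasing in dose.
#'
#' @param dose dose in Gy (radiation) or CEM43 (heat); vectorized, >= 0.
#' @param params an [alphar_params()] object.
#' @return Surviving fraction(s) in `[0, 1]`.
#' @export
alphar_survival <- function(dose, params) {
  stopifnot(inherits(params, "alphar_params"), is.numeric(dose))
  if (any(dose < 0)) stop("dose must be non-negative")
  a0 <- params$alpha0; aR <- params$alphaR; b <- params$beta; dt <- params$D_T
  lq <- exp(-(a0 - aR) * dose - b * dose^2)
  if (!any(dose > dt)) return(lq)
  post <- if (params$explicit_DT) {
    # continuous extension from an externally supplied threshold
    s_dt <- exp(-(a0 - aR) * dt - b * dt^2)
    s_dt * exp(-a0 * (dose - dt))
  } else {
    # with D_T = alphaR/beta the repair term vanishes at the threshold
    exp(-a0 * dose)
  }
  ifelse(dose > dt, post, lq)
}

#' Thermal profile of a heat exposure
#'
#' An ordered sequence of heating steps, each a duration in minutes at a
#' constant temperature in degrees Celsius, e.g. the read-out of a thermal
#' cycler programme.
#'
#' @param minutes step durations in minutes (>= 0).
#' @param temp_C step temperatures in degrees C (0-100).
#' @return An object of class `thermal_profile`.
#' @examples
#' cem43(thermal_profile(5, 46))  # 40 CEM43
#' @export
thermal_profile <- function(minutes, temp_C) {
  stopifnot(is.numeric(minutes), is.numeric(temp_C),
            length(minutes) == length(temp_C))
  if (any(minutes < 0)) stop("durations must be >= 0")
  if (any(temp_C < 0 | temp_C > 100))
    stop("temperatures must lie in [0, 100] degrees C")
  structure(list(minutes = as.numeric(minutes), temp_C = as.numeric(temp_C)),
            class = "thermal_profile")
}

#' @export
print.thermal_profile <- function(x, ...) {
  cat(sprintf("Thermal profile: %d step(s), %g CEM43 total\n",
              length(x$minutes), cem43(x)))
  invisible(x)
}

#' Concatenate thermal profiles
#' @param ... `thermal_profile` objects.
#' @return The concatenated `thermal_profile`; `cem43()` is additive over
#'   concatenation.
#' @export
c.thermal_profile <- function(...) {
  ps <- list(...)
  stopifnot(all(vapply(ps, inherits, logical(1), "thermal_profile")))
  thermal_profile(unlist(lapply(ps, `[[`, "minutes")),
                  unlist(lapply(ps, `[[`, "temp_C")))
}

#' CEM43 thermal dose
#'
#' Converts a time-temperature profile into cumulative equivalent minutes at
#' 43 degrees C using the standard two-case (Sapareto-Dewey) convention:
#' `t43 = sum_i t_i * R^(43 - T_i)` with `R = 0.5` for `T_i >= 43` and
#' `R = 0.25` for `T_i < 43`. Steps at 40 degrees C or below are biologically
#' inert and excluded.
#'
#' @param profile a [thermal_profile()].
#' @return Thermal dose in CEM43 (minutes, >= 0).
#' @export
cem43 <- function(profile) {
  stopifnot(inherits(profile, "thermal_profile"))
  t <- profile$minutes; T <- profile$temp_C
  keep <- T > 40
  if (!any(keep)) return(0)
  t <- t[keep]; T <- T[keep]
  R <- ifelse(T >= 43, 0.5, 0.25)
  sum(t * R^(43 - T))
}

#' Hyperthermia surviving fraction
#'
#' AlphaR survival with the dose argument replaced by thermal dose. For heat
#' the fitted parameters satisfy `alpha0 = alphaR`, so the sub-threshold arm
#' is the pure shoulder `exp(-beta t43^2)` and the post-threshold arm a
#' single exponential.
#'
#' @param t43 thermal dose in CEM43 (vectorized, >= 0), e.g. from [cem43()].
#' @param params [alphar_params()] in CEM43 units.
#' @return Surviving fraction(s).
#' @export
ht_survival <- function(t43, params) alphar_survival(t43, params)

#' Combined radiation + heat parameters
#'
#' Thermo-radiosensitization is modelled as a linear increase of the
#' radiation alpha coefficient with thermal dose,
#' `alpha_RTHT(t43) = alpha_RT + a * t43`, while beta is unchanged. The
#' combined surviving fraction multiplies the heat-only survival by the
#' sensitized LQ radiation term.
#'
#' @param alpha_RT radiation LQ alpha (Gy^-1).
#' @param beta_RT radiation LQ beta (Gy^-2).
#' @param slope_a sensitization slope (Gy^-1 per CEM43, >= 0).
#' @param ht_params [alphar_params()] for the heat-only survival, CEM43 units.
#' @return An object of class `combination_params`.
#' @export
combination_params <- function(alpha_RT, beta_RT, slope_a, ht_params) {
  stopifnot(is.numeric(alpha_RT), is.numeric(beta_RT), is.numeric(slope_a),
            inherits(ht_params, "alphar_params"))
  if (slope_a < 0) stop("slope_a must be >= 0")
  if (alpha_RT < 0 || beta_RT < 0) stop("alpha_RT, beta_RT must be >= 0")
  structure(list(alpha_RT = alpha_RT, beta_RT = beta_RT,
                 slope_a = slope_a, ht_params = ht_params),
            class = "combination_params")
}

#' Combined radiotherapy + hyperthermia surviving fraction
#'
#' `S_RTHT(d, t43) = S_HT(t43) * exp(-(alpha_RT + a t43) d - beta_RT d^2)`.
#' Reduces to radiation-only survival at `t43 = 0` and to heat-only survival
#' at `d = 0`; never exceeds either single-modality survival when the
#' sensitization slope is non-negative.
#'
#' @param dose radiation dose in Gy (>= 0).
#' @param t43 thermal dose in CEM43 (>= 0).
#' @param params a [combination_params()] object.
#' @return Surviving fraction(s).
#' @export
rtht_survival <- function(dose, t43, params) {
  stopifnot(inherits(params, "combination_params"))
  if (any(dose < 0)) stop("dose must be non-negative")
  if (any(t43 < 0)) stop("t43 must be non-negative")
  s_ht <- ht_survival(t43, params$ht_params)
  s_ht * exp(-(params$alpha_RT + params$slope_a * t43) * dose -
               params$beta_RT * dose^2)
}

# ---- cycle-phase sensitivity weighting --------------------------------------

.PHASES <- c("G1", "S", "G2", "M", "G0")

#' Solve the cycle-phase sensitivity map
#'
#' Radiation sensitivity differs between cycle stages; phase-specific
#' survival is modelled as a power of the population survival,
#' `S_phase = S^gamma_phase`. The gamma map is fixed by two conditions at a
#' reference dose:
#'
#' 1. consecutive phase survivals stand in a constant ratio `r` (default
#'    1.5), ordered S (most resistant) > G1 > G2 > M (most sensitive):
#'    `S_S = r S_G1 = r^2 S_G2 = r^3 S_M`;
#' 2. the phase-fraction-weighted mean of the phase survivals equals the
#'    unweighted population survival `S` at that dose.
#'
#' Writing `S_phase = x * r^(k_phase)` with `k = (2, 3, 1, 0)` for
#' (G1, S, G2, M), condition 2 is linear in `x`, so
#' `x = S / sum_p f_p r^(k_p)` in closed form and
#' `gamma_phase = log(S_phase) / log(S)`. Quiescent (G0) cells default to the
#' G1 sensitivity; pass `gamma_G0` to override.
#'
#' @param base_survival population surviving fraction `S` at the reference
#'   dose, in `(0, 1)`.
#' @param phase_fractions named fractions of cycling cells per phase
#'   (`G1`, `S`, `G2`, `M`), summing to 1. A `G0` entry, if present, joins
#'   the normalization with the G1 sensitivity.
#' @param ratio consecutive phase-survival ratio (default 1.5).
#' @param gamma_G0 optional explicit exponent for quiescent cells.
#' @return A named numeric vector of exponents over `G1, S, G2, M, G0`,
#'   class `phase_sensitivity`.
#' @examples
#' g <- phase_sensitivity(0.03, c(G1 = 0.40, S = 0.35, G2 = 0.20, M = 0.05))
#' 0.03^g[["S"]] / 0.03^g[["G1"]]  # 1.5
#' @export
phase_sensitivity <- function(base_survival,
                              phase_fractions = c(G1 = 0.40, S = 0.35,
                                                  G2 = 0.20, M = 0.05),
                              ratio = 1.5, gamma_G0 = NULL) {
  stopifnot(base_survival > 0, base_survival < 1, ratio > 0)
  f <- phase_fractions
  need <- c("G1", "S", "G2", "M")
  if (!all(need %in% names(f))) stop("phase_fractions must name G1, S, G2, M")
  fG0 <- if ("G0" %in% names(f)) f[["G0"]] else 0
  f4 <- f[need]
  if (abs(sum(f4) + fG0 - 1) > 1e-9 && abs(sum(f4) - 1) > 1e-9)
    stop("phase fractions must sum to 1")
  # resistance exponents: S most resistant, then G1, G2, M
  k <- c(G1 = 2, S = 3, G2 = 1, M = 0)
  w <- f4[need] * ratio^k[need]
  if (fG0 > 0) w[["G1"]] <- w[["G1"]] + fG0 * ratio^k[["G1"]]  # G0 ~ G1
  x <- base_survival / sum(w)
  s_phase <- x * ratio^k[need]
  if (any(s_phase > 1))
    stop("phase survivals exceed 1; reference survival too close to 1 for ",
         "the requested ratio")
  g <- log(s_phase) / log(base_survival)
  names(g) <- need
  g <- c(g, G0 = if (is.null(gamma_G0)) g[["G1"]] else gamma_G0)
  structure(g, class = "phase_sensitivity",
            base_survival = base_survival, ratio = ratio)
}

#' As a plain gamma map
#'
#' Builds a `phase_sensitivity` object from explicit exponents (config
#' override) instead of solving the ratio rule.
#'
#' @param gamma named numeric vector with entries for `G1, S, G2, M` and
#'   optionally `G0` (defaults to the G1 value).
#' @return A `phase_sensitivity` object.
#' @export
phase_sensitivity_manual <- function(gamma) {
  need <- c("G1", "S", "G2", "M")
  if (!all(need %in% names(gamma))) stop("gamma must name G1, S, G2, M")
  if (any(gamma <= 0)) stop("gamma exponents must be positive")
  g <- gamma[need]
  g <- c(g, G0 = if ("G0" %in% names(gamma)) gamma[["G0"]] else g[["G1"]])
  structure(g, class = "phase_sensitivity", base_survival = NA_real_,
            ratio = NA_real_)
}

#' Uniform (phase-independent) sensitivity
#' @return A `phase_sensitivity` with all exponents 1.
#' @export
phase_sensitivity_uniform <- function() {
  phase_sensitivity_manual(c(G1 = 1, S = 1, G2 = 1, M = 1, G0 = 1))
}

#' Phase-weighted surviving fraction
#'
#' Applies the cycle-phase sensitivity exponent to a population surviving
#' fraction: `S_phase = S^gamma_phase`. At `S = 0` the weighted survival is 0
#' for any positive exponent.
#'
#' @param base_survival population surviving fraction in `[0, 1]`; vectorized.
#' @param phase character vector of phases (`G1`, `S`, `G2`, `M`, `G0`),
#'   recycled against `base_survival`.
#' @param sensitivity a `phase_sensitivity` object.
#' @return Phase-specific surviving fraction(s).
#' @export
phase_weighted_survival <- function(base_survival, phase, sensitivity) {
  stopifnot(inherits(sensitivity, "phase_sensitivity"))
  if (any(base_survival < 0 | base_survival > 1))
    stop("base_survival must lie in [0, 1]")
  if (!all(phase %in% .PHASES)) stop("unknown phase")
  g <- unclass(sensitivity)[phase]
  ifelse(base_survival == 0, 0, base_survival^g)
}
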