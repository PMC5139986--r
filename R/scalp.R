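#' Pressure-based scalp flow estimate
#'
#' Linear pressure-to-flow relation for the extracerebral compartment,
#' `Fx = lam_Fx + lam_Fx_p * Pa`, used when no direct flow measurement is
#' available.
#'
#' @param Pa Mean arterial pressure (mmHg), scalar or vector.
#' @param params Calibrated scalp parameters (or any list with `lam_Fx`,
#'   `lam_Fx_p`).
#' @return Flow in normalised units. Errors if the computed flow is not
#'   strictly positive.
#' @export
scalp_flow_pressure <- function(Pa, params) {
  stopifnot(all(Pa > 0))
  F <- params$lam_Fx + params$lam_Fx_p * Pa
  if (any(F <= 0)) {
    stop("scalp_flow_pressure: non-positive flow at Pa = ",
         paste(Pa[F <= 0], collapse = ", "),
         "; check lam_Fx/lam_Fx_p parameterisation", call. = FALSE)
  }
  F
}

#' Flux-based scalp flow estimate
#'
#' When laser-Doppler flux has been recorded, flow is the baseline-normalised
#' flux scaled by a 'normal' flow value: `Fy = Flux_y * Fy_n`.
#'
#' @param Flux_y Normalised laser-Doppler flux (dimensionless, baseline 1).
#' @param params Calibrated scalp parameters (uses `Fy_n`).
#' @return Flow in normalised units.
#' @export
scalp_flow_flux <- function(Flux_y, params) {
  stopifnot(all(Flux_y > 0))
  Flux_y * params$Fy_n
}

#' Fit the pressure-to-flow coefficients
#'
#' Ordinary least-squares fit of `flow ~ Pa` giving the default `lam_Fx`
#' and `lam_Fx_p`. The packaged table
#' `inst/extdata/synthetic_pressure_flux.csv` is a synthetic stand-in for
#' experimental pressure--flux recordings (which are not redistributable):
#' 26 pairs drawn from flow = 0.1 + 0.009 Pa plus Gaussian noise (sd 0.02)
#' over the normal pressure range, flux pre-normalised to flow units.
#'
#' @param table Data frame with columns `Pa` and `flow`; default reads the
#'   packaged synthetic table.
#' @return List with `lam_Fx` and `lam_Fx_p`.
#' @export
fit_scalp_flow <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "synthetic_pressure_flux.csv",
                        package = "fnirsim", mustWork = TRUE)
    table <- utils::read.csv(path)
  }
  stopifnot(all(c("Pa", "flow") %in% names(table)))
  fit <- stats::lm(flow ~ Pa, data = table)
  list(lam_Fx = unname(stats::coef(fit)[1]),
       lam_Fx_p = unname(stats::coef(fit)[2]))
}

#' Calibrate the scalp Windkessel compartment
#'
#' Normalises the compartment so that at baseline the total blood volume is
#' 1 with venous:arterial ratio `vratio`, the venous fraction of total
#' vascular resistance is `Rfrac_v` (so the baseline venous pressure is
#' `Rfrac_v * Pa`), and the compliant share of the baseline venous volume
#' is `Volc_frac`. Arterial conductance follows `G = F / Pa` with
#' `G ~ r^4` and `Va ~ r^2` relative to baseline. If the pressure-model
#' coefficients are not supplied they are fitted with [fit_scalp_flow()];
#' the flux-variant normal flow `Fy_n` defaults to the pressure-model
#' baseline flow.
#'
#' @param scalp_cfg Scalp configuration block (see [default_config()]).
#' @param baseline Baseline systemic inputs.
#' @param SvO2_n Baseline cerebral venous saturation (%), shared by the
#'   scalp venous volume.
#' @param hb_scale Haemoglobin scaling (uM per unit normalised volume).
#' @return List of calibrated constants plus `state0`, the baseline
#'   [scalp state][scalp_derivatives].
#' @export
calibrate_scalp <- function(scalp_cfg, baseline = default_config()$baseline,
                            SvO2_n = 70, hb_scale = 100) {
  sc <- scalp_cfg
  if (!(sc$Volc_frac > 0 && sc$Volc_frac < 1)) {
    stop("calibrate_scalp: constraint violated: 0 < Volc_frac < 1", call. = FALSE)
  }
  if (!(sc$Rfrac_v > 0 && sc$Rfrac_v < 1)) {
    stop("calibrate_scalp: constraint violated: 0 < Rfrac_v < 1", call. = FALSE)
  }
  if (!(sc$vratio > 0)) {
    stop("calibrate_scalp: constraint violated: vratio > 0", call. = FALSE)
  }
  if (is.null(sc$lam_Fx) || is.null(sc$lam_Fx_p)) {
    sc[c("lam_Fx", "lam_Fx_p")] <- fit_scalp_flow()
  }
  Pa_n <- baseline$Pa
  F_n <- scalp_flow_pressure(Pa_n, sc)
  if (is.null(sc$Fy_n)) sc$Fy_n <- F_n

  Va_n <- 1 / (1 + sc$vratio)
  Vv_n <- sc$vratio / (1 + sc$vratio)
  G_n <- F_n / Pa_n
  # venous pressure divider: Pv/Pa = G/(G+Gv) = Rfrac_v at baseline
  Gv <- G_n * (1 - sc$Rfrac_v) / sc$Rfrac_v
  Pv_n <- G_n * Pa_n / (G_n + Gv)
  Vv_nc <- Vv_n * (1 - sc$Volc_frac)      # non-compliant venous volume
  Cv_vol <- sc$Volc_frac * Vv_n / Pv_n    # volume stored per mmHg venous pressure

  state0 <- c(Pv = Pv_n, G = G_n, r = 1, Va = Va_n, Vv = Vv_n, F = F_n)
  if (abs(state0[["Va"]] + state0[["Vv"]] - 1) > 1e-12) {
    stop("calibrate_scalp: constraint violated: Va + Vv = 1", call. = FALSE)
  }
  c(sc, list(
    Pa_n = Pa_n, F_n = F_n, G_n = G_n, Gv = Gv, Pv_n = Pv_n,
    Va_n = Va_n, Vv_n = Vv_n, Vv_nc = Vv_nc, Cv_vol = Cv_vol,
    SvO2_n = SvO2_n, hb_scale = hb_scale, state0 = state0
  ))
}

# Algebraic part of the scalp state: conductance from the flow estimate
# (G = F/Pa), radius from G ~ r^4, arterial volume from Va ~ r^2, venous
# volume from the compliant split.
scalp_algebraic <- function(Pv, Pa, flow_est, params) {
  if (Pa <= 0) stop("scalp_algebraic: Pa must be positive", call. = FALSE)
  G <- flow_est / Pa
  r <- (G / params$G_n)^0.25
  c(Pv = Pv, G = G, r = r,
    Va = params$Va_n * r^2,
    Vv = params$Vv_nc + params$Cv_vol * Pv,
    F = flow_est)
}

#' Time derivative of the scalp state
#'
#' Only the venous pressure is dynamic:
#' `dPv/dt = (G (Pa - Pv) - Pv Gv) / Cv`; all other state variables follow
#' algebraically from the instantaneous flow estimate (conductance
#' `G = F/Pa`, radius, volumes).
#'
#' @param state Named scalp state vector (uses `Pv`).
#' @param Pa Arterial pressure (mmHg).
#' @param flow_est Flow estimate from [scalp_flow_pressure()] or
#'   [scalp_flow_flux()].
#' @param params Calibrated scalp parameters.
#' @return List: `deriv` (named vector with `dPv`) and `state` (the full
#'   algebraically-completed state).
#' @export
scalp_derivatives <- function(state, Pa, flow_est, params) {
  Pv <- as.list(state)$Pv
  st <- scalp_algebraic(Pv, Pa, flow_est, params)
  dPv <- (st[["G"]] * (Pa - Pv) - Pv * params$Gv) / params$Cv
  list(deriv = c(Pv = dPv), state = st)
}

#' Steady state of the scalp compartment
#'
#' Analytic: `Pv* = G Pa / (G + Gv)` with `G = F/Pa`.
#'
#' @inheritParams scalp_derivatives
#' @return Full named scalp state vector at the steady state.
#' @export
scalp_steady_state <- function(Pa, flow_est, params) {
  G <- flow_est / Pa
  Pv <- G * Pa / (G + params$Gv)
  scalp_algebraic(Pv, Pa, flow_est, params)
}

#' Scalp compartment oxygen saturations
#'
#' The scalp arterial volume carries the systemic arterial saturation
#' unchanged; the venous volume is pinned at the baseline cerebral venous
#' saturation (no metabolism is modelled in the scalp, oxygen consumption
#' is fixed).
#'
#' @param state Scalp state (unused; saturations do not depend on it).
#' @param SaO2 Systemic arterial saturation (%), scalar or vector.
#' @param params Calibrated scalp parameters.
#' @return List with `arterial` (= SaO2) and `venous` (constant, %).
#' @export
scalp_oxygen <- function(state, SaO2, params) {
  stopifnot(all(SaO2 >= 0 & SaO2 <= 100))
  list(arterial = SaO2, venous = rep(params$SvO2_n, length(SaO2)))
}
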