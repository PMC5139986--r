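#' Electron-transfer rates of the metabolic chain
#'
#' Evaluates the three linearised reaction rates of the terminal
#' mitochondrial electron transport chain: substrate -> CuA (`f1`),
#' CuA -> a3 (`f2`) and a3 -> O2 (`f3`). Each rate is a linear function of
#' the proton motive force and of the natural logarithms of the donor and
#' acceptor pool concentrations:
#'
#' \deqn{f_1 = \lambda_{f1} + \lambda_{f1,p}\Delta p + \lambda_{f1,a}\log[CuA_{ox}]}
#' \deqn{f_2 = \lambda_{f2} + \lambda_{f2,p}\Delta p + \lambda_{f2,a}\log[CuA_{red}] + \lambda_{f2,b}\log[a3_{ox}]}
#' \deqn{f_3 = \lambda_{f3} + \lambda_{f3,p}\Delta p + \lambda_{f3,b}\log[a3_{red}] + \lambda_{f3,O}\log[O_2]}
#'
#' Note on naming: the coefficient on the \eqn{\log[a3_{ox}]} term in `f2`
#' is treated as a coefficient of the second equation and named `lam_f2_b`
#' (per-equation naming), even though it is sometimes written with an
#' f1 subscript.
#'
#' @param state Named list or vector with `CuA_ox`, `CuA_red`, `a3_ox`,
#'   `a3_red`, `O2` (mM) and `dp` (mV).
#' @param params Named list with the eleven `lam_*` coefficients
#'   (`lam_f1`, `lam_f1_p`, `lam_f1_a`, `lam_f2`, `lam_f2_p`, `lam_f2_a`,
#'   `lam_f2_b`, `lam_f3`, `lam_f3_p`, `lam_f3_b`, `lam_f3_O`).
#' @return Named numeric vector `c(f1, f2, f3)` in mM/s.
#' @export
metabolic_rates <- function(state, params) {
  s <- as.list(state)
  for (pool in c("CuA_ox", "CuA_red", "a3_ox", "a3_red", "O2")) {
    v <- s[[pool]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      stop("metabolic_rates: non-positive concentration in pool '", pool,
           "' (value = ", format(v), ")", call. = FALSE)
    }
  }
  p <- params
  f1 <- p$lam_f1 + p$lam_f1_p * s$dp + p$lam_f1_a * log(s$CuA_ox)
  f2 <- p$lam_f2 + p$lam_f2_p * s$dp + p$lam_f2_a * log(s$CuA_red) +
    p$lam_f2_b * log(s$a3_ox)
  f3 <- p$lam_f3 + p$lam_f3_p * s$dp + p$lam_f3_b * log(s$a3_red) +
    p$lam_f3_O * log(s$O2)
  c(f1 = f1, f2 = f2, f3 = f3)
}

# Derive the full cerebral parameter set (rate coefficients, transport
# constants, baseline state) from a configuration block. Purely analytic:
# intercepts are solved so that the baseline is an exact fixed point.
cerebral_params <- function(config = default_config()) {
  cc <- config$cerebral
  bl <- config$baseline
  Sa_n <- bl$SaO2 / 100
  Sv_n <- cc$SvO2_n / 100
  if (Sv_n >= Sa_n) stop("cerebral calibration: SvO2_n must be below baseline SaO2")

  Va_n <- 1 / (1 + cc$vratio)
  Vv_n <- cc$vratio / (1 + cc$vratio)

  # oxygen transport: diffusion constant from the baseline balance,
  # blood-side extraction coefficient from the baseline saturation gap
  E_n  <- Sa_n - Sv_n
  O2cap_n <- cc$phi * (Sa_n + Sv_n) / 2
  if (O2cap_n <= cc$O2_n) {
    stop("cerebral calibration: capillary O2 proxy must exceed tissue O2 at baseline")
  }
  D  <- cc$CMRO2_n / (O2cap_n - cc$O2_n)
  c1 <- cc$CMRO2_n / E_n # extraction flux per unit flow per unit saturation gap

  # metabolic chain: slopes from elasticities, intercepts from the baseline
  CuA_ox_n  <- cc$CuA_ox_frac_n * cc$CuA_tot
  CuA_red_n <- cc$CuA_tot - CuA_ox_n
  a3_ox_n   <- cc$a3_ox_frac_n * cc$a3_tot
  a3_red_n  <- cc$a3_tot - a3_ox_n
  lam <- list(
    lam_f1_p = -cc$e1p * cc$f_n / cc$dp_n,
    lam_f1_a =  cc$e1a * cc$f_n,
    lam_f2_p = -cc$e2p * cc$f_n / cc$dp_n,
    lam_f2_a =  cc$e2a * cc$f_n,
    lam_f2_b =  cc$e2b * cc$f_n,
    lam_f3_p = -cc$e3p * cc$f_n / cc$dp_n,
    lam_f3_b =  cc$e3b * cc$f_n,
    lam_f3_O =  cc$e3O * cc$f_n
  )
  if (lam$lam_f3_O < 0) stop("cerebral calibration: lam_f3_O must be >= 0")
  lam$lam_f1 <- cc$f_n - lam$lam_f1_p * cc$dp_n - lam$lam_f1_a * log(CuA_ox_n)
  lam$lam_f2 <- cc$f_n - lam$lam_f2_p * cc$dp_n - lam$lam_f2_a * log(CuA_red_n) -
    lam$lam_f2_b * log(a3_ox_n)
  lam$lam_f3 <- cc$f_n - lam$lam_f3_p * cc$dp_n - lam$lam_f3_b * log(a3_red_n) -
    lam$lam_f3_O * log(cc$O2_n)

  # proton motive force: consumption coefficient balances pumping at baseline
  kc <- 3 * cc$kp * cc$f_n / cc$dp_n

  p <- c(cc, lam, list(
    kc = kc, D = D, c1 = c1, E_n = E_n,
    Va_n = Va_n, Vv_n = Vv_n,
    Sa_n = Sa_n, Sv_n = Sv_n,
    CuA_ox_n = CuA_ox_n, CuA_red_n = CuA_red_n,
    a3_ox_n = a3_ox_n, a3_red_n = a3_red_n,
    Pa_n = bl$Pa, CO2_n = bl$PaCO2, SaO2_n = bl$SaO2,
    G_cn = 1 / bl$Pa, # normalised conductance: F = r^4 * Pa / Pa_n
    HbO2_abs_n = cc$hb_scale * (Va_n * Sa_n + Vv_n * Sv_n),
    HHb_abs_n  = cc$hb_scale * (Va_n * (1 - Sa_n) + Vv_n * (1 - Sv_n))
  ))
  p
}

# Demanded flow set-point from the systemic inputs and the (slow-sensed)
# tissue O2; the achieved steady flow carries a small residual passive
# pressure slope a_P, representing incomplete autoregulation.
flow_setpoint <- function(Pa, PaCO2, SaO2, u, O2_sensed, p) {
  F_dem <- 1 +
    p$g_CO2f * (PaCO2 - p$CO2_n) / p$CO2_n +
    p$g_uf * (u - 1) -
    p$g_O2f * (O2_sensed - p$O2_n) / p$O2_n -
    p$g_saf * (SaO2 - p$SaO2_n) / p$SaO2_n
  F_sp <- F_dem * (1 + p$a_P * (Pa - p$Pa_n) / p$Pa_n)
  max(F_sp, 0.05)
}

# Instantaneous venous saturation (fraction): blood-side extraction equals
# tissue-side diffusion at each instant, which is linear in Sv.
venous_saturation <- function(F, Sa, O2, p) {
  num <- p$c1 * F * Sa - p$D * p$phi * Sa / 2 + p$D * O2
  den <- p$c1 * F + p$D * p$phi / 2
  min(max(num / den, 1e-3), Sa)
}

#' Baseline cerebral state
#'
#' The calibrated baseline state is an exact fixed point of
#' [cerebral_derivatives()] under baseline inputs.
#'
#' @param params Calibrated cerebral parameters from [calibrate_cerebral()].
#' @return Named state vector `c(r, O2f, O2, CuA_ox, CuA_red, a3_ox, a3_red, dp)`.
#' @export
cerebral_baseline_state <- function(params) {
  c(r = 1, O2f = params$O2_n, O2 = params$O2_n,
    CuA_ox = params$CuA_ox_n, CuA_red = params$CuA_red_n,
    a3_ox = params$a3_ox_n, a3_red = params$a3_red_n,
    dp = params$dp_n)
}

#' Time derivatives of the cerebral compartment
#'
#' The cerebral state comprises the characteristic arterial radius `r`
#' (first-order relaxation towards the regulation set-point), the
#' slow-sensed tissue O2 `O2f` driving the O2 feedback channel, tissue O2
#' `O2` (delivery minus consumption), the four redox pools of the chain
#' (`CuA_ox`/`CuA_red`, `a3_ox`/`a3_red`; oxidised and reduced derivatives
#' are exact negatives, so pool totals are conserved) and the proton motive
#' force `dp` (pumping by f1..f3 minus demand-scaled consumption).
#'
#' @param state Named state vector as from [cerebral_baseline_state()].
#' @param inputs Named list/vector of systemic inputs `Pa`, `PaCO2`, `SaO2`, `u`.
#' @param params Calibrated cerebral parameters.
#' @return List: `deriv` (named vector, same order as `state`) and `aux`
#'   (named vector with flow `F`, venous saturation `SvO2` in %, arterial
#'   volume `Va`, venous volume `Vv`, conductance `G`, `CMRO2` in mM/s and
#'   the three rates).
#' @export
cerebral_derivatives <- function(state, inputs, params) {
  s <- as.list(state)
  inp <- as.list(inputs)
  p <- params
  Sa <- inp$SaO2 / 100

  rates <- metabolic_rates(s, p)
  CMRO2 <- p$CMRO2_n * rates[["f3"]] / p$f_n

  F  <- s$r^4 * inp$Pa / p$Pa_n
  Sv <- venous_saturation(F, Sa, s$O2, p)
  O2cap <- p$phi * (Sa + Sv) / 2

  F_sp <- flow_setpoint(inp$Pa, inp$PaCO2, inp$SaO2, inp$u, s$O2f, p)
  r_target <- (F_sp * p$Pa_n / inp$Pa)^0.25

  d <- c(
    r = (r_target - s$r) / p$tau_r,
    O2f = (s$O2 - s$O2f) / p$tau_fb,
    O2 = p$D * (O2cap - s$O2) - CMRO2,
    CuA_ox = rates[["f2"]] - rates[["f1"]],
    CuA_red = rates[["f1"]] - rates[["f2"]],
    a3_ox = rates[["f3"]] - rates[["f2"]],
    a3_red = rates[["f2"]] - rates[["f3"]],
    dp = (p$kp * sum(rates) - p$kc * inp$u * s$dp) / p$C_dp
  )
  if (any(!is.finite(d))) {
    stop("cerebral_derivatives: non-finite derivative at state ",
         paste(names(state), signif(unlist(state), 6), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  aux <- c(F = F, SvO2 = 100 * Sv, Va = p$Va_n * s$r^2, Vv = p$Vv_n,
           G = p$G_cn * s$r^4, CMRO2 = CMRO2, rates)
  list(deriv = d, aux = aux)
}

# Given dp (and inputs), walk the chain analytically: the common steady rate
# follows from the proton balance, then each rate equation yields one pool,
# ending with the tissue O2 demanded by the metabolic side. Returns NULL if
# a pool falls outside (0, total).
chain_from_dp <- function(dp, u, p) {
  f <- p$f_n * u * dp / p$dp_n
  CuA_ox <- exp((f - p$lam_f1 - p$lam_f1_p * dp) / p$lam_f1_a)
  if (!is.finite(CuA_ox) || CuA_ox <= 0 || CuA_ox >= p$CuA_tot) return(NULL)
  CuA_red <- p$CuA_tot - CuA_ox
  a3_ox <- exp((f - p$lam_f2 - p$lam_f2_p * dp - p$lam_f2_a * log(CuA_red)) /
                 p$lam_f2_b)
  if (!is.finite(a3_ox) || a3_ox <= 0 || a3_ox >= p$a3_tot) return(NULL)
  a3_red <- p$a3_tot - a3_ox
  O2 <- exp((f - p$lam_f3 - p$lam_f3_p * dp - p$lam_f3_b * log(a3_red)) /
              p$lam_f3_O)
  if (!is.finite(O2) || O2 <= 0) return(NULL)
  list(f = f, CuA_ox = CuA_ox, CuA_red = CuA_red,
       a3_ox = a3_ox, a3_red = a3_red, O2 = O2)
}

#' Cerebral steady state for given systemic inputs
#'
#' Solves the joint vascular--metabolic steady state by a one-dimensional
#' root search over the proton motive force: for each candidate `dp` the
#' chain equations yield the common reaction rate, the redox pools and the
#' tissue O2 demanded by the metabolic side; the residual is the mismatch
#' of the tissue O2 mass balance against the flow the regulation delivers.
#' Deterministic; the returned state satisfies
#' `max(abs(derivatives)) < tol` (checked, error on non-convergence).
#'
#' @param inputs Named list/vector with `Pa`, `PaCO2`, `SaO2`, `u` (missing
#'   entries filled from the baseline).
#' @param params Calibrated cerebral parameters from [calibrate_cerebral()].
#' @param tol Residual tolerance on the state derivatives.
#' @return A list of class `cerebral_state`: radius `r_c`, conductance
#'   `G_c`, volumes `Va_c`, `Vv_c`, venous saturation `SvO2_c` (%), flow
#'   `F_c`, `CMRO2`, the metabolic state, the raw ODE `state` vector, and
#'   the steady-state haemoglobin changes from baseline `dHbO2`, `dHHb`
#'   (uM) and `doxCCO` (uM).
#' @export
cerebral_steady_state <- function(inputs, params, tol = 1e-8) {
  p <- params
  inp <- as.list(inputs)
  for (nm in c("Pa", "PaCO2", "SaO2", "u")) {
    if (is.null(inp[[nm]])) {
      inp[[nm]] <- c(Pa = p$Pa_n, PaCO2 = p$CO2_n, SaO2 = p$SaO2_n, u = 1)[[nm]]
    }
  }
  Sa <- inp$SaO2 / 100

  residual <- function(dp) {
    ch <- chain_from_dp(dp, inp$u, p)
    if (is.null(ch)) return(NA_real_)
    CMRO2 <- p$CMRO2_n * ch$f / p$f_n
    F <- flow_setpoint(inp$Pa, inp$PaCO2, inp$SaO2, inp$u, ch$O2, p)
    Sv <- Sa - p$E_n * (CMRO2 / p$CMRO2_n) / F
    Sv <- min(max(Sv, 1e-3), Sa)
    p$D * (p$phi * (Sa + Sv) / 2 - ch$O2) - CMRO2
  }

  grid <- p$dp_n * seq(0.3, 2, by = 0.01)
  vals <- vapply(grid, residual, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2) {
    stop("cerebral_steady_state: no feasible proton motive force bracket for inputs ",
         paste(names(inp), unlist(inp), sep = "=", collapse = ", "), call. = FALSE)
  }
  sgn <- sign(vals[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (length(flip) == 0) {
    stop("cerebral_steady_state: no sign change in steady-state residual ",
         "(min |residual| = ", format(min(abs(vals[ok]))), ")", call. = FALSE)
  }
  i <- ok[flip[1]]; j <- ok[flip[1] + 1]
  dp <- stats::uniroot(residual, lower = grid[i], upper = grid[j],
                       tol = 1e-12)$root

  ch <- chain_from_dp(dp, inp$u, p)
  F <- flow_setpoint(inp$Pa, inp$PaCO2, inp$SaO2, inp$u, ch$O2, p)
  r <- (F * p$Pa_n / inp$Pa)^0.25
  state <- c(r = r, O2f = ch$O2, O2 = ch$O2,
             CuA_ox = ch$CuA_ox, CuA_red = ch$CuA_red,
             a3_ox = ch$a3_ox, a3_red = ch$a3_red, dp = dp)
  der <- cerebral_derivatives(state, inp, p)
  scale <- pmax(abs(state), 1e-6)
  resid <- max(abs(der$deriv) / scale)
  if (resid > tol) {
    stop("cerebral_steady_state: residual ", format(resid),
         " exceeds tolerance ", format(tol), call. = FALSE)
  }

  Va <- p$Va_n * r^2
  Vv <- p$Vv_n
  Sv <- der$aux[["SvO2"]] / 100
  HbO2 <- p$hb_scale * (Va * Sa + Vv * Sv)
  HHb  <- p$hb_scale * (Va * (1 - Sa) + Vv * (1 - Sv))
  structure(list(
    inputs = inp, r_c = r, G_c = p$G_cn * r^4, Va_c = Va, Vv_c = Vv,
    SvO2_c = 100 * Sv, F_c = F, CMRO2 = der$aux[["CMRO2"]],
    metabolic = ch[c("CuA_ox", "CuA_red", "a3_ox", "a3_red", "O2")],
    dp = dp, state = state, residual = resid,
    dHbO2 = HbO2 - p$HbO2_abs_n,
    dHHb = HHb - p$HHb_abs_n,
    doxCCO = p$cco_scale * 1000 * (ch$CuA_ox - p$CuA_ox_n)
  ), class = "cerebral_state")
}

#' @export
print.cerebral_state <- function(x, ...) {
  cat(sprintf(
    "<cerebral_state> r=%.4f F=%.4f CMRO2=%.5f SvO2=%.1f%% dHbO2=%+.3f dHHb=%+.3f uM\n",
    x$r_c, x$F_c, x$CMRO2, x$SvO2_c, x$dHbO2, x$dHHb))
  invisible(x)
}

#' Default directional calibration targets
#'
#' Signs of the steady-state (dHbO2, dHHb) response to an isolated increase
#' of each systemic input, plus monotonicity of CMRO2 in demand. These are
#' the qualitative responses of the underlying physiology: autoregulation
#' makes both haemoglobin species fall with pressure; hypercapnia,
#' hyperoxia and demand raise HbO2 and lower HHb.
#'
#' @param flat If `TRUE`, degenerate zero-gain targets (flat responses).
#' @return A list understood by [calibrate_cerebral()].
#' @export
cerebral_targets <- function(flat = FALSE) {
  list(
    flat = flat,
    directions = list(
      Pa    = c(dHbO2 = -1, dHHb = -1),
      PaCO2 = c(dHbO2 = 1, dHHb = -1),
      SaO2  = c(dHbO2 = 1, dHHb = -1),
      u     = c(dHbO2 = 1, dHHb = -1)
    ),
    cmro2_monotone_u = TRUE
  )
}

#' Calibrate the cerebral compartment
#'
#' Builds the full cerebral parameter set from the configuration --
#' intercepts of the chain rate equations, the O2 diffusion constant and
#' the proton-consumption coefficient are solved analytically so that the
#' configured baseline state is an exact fixed point -- and then verifies
#' the resulting steady-state sweeps against the qualitative directional
#' `targets`. The procedure is deterministic; `seed` is accepted for
#' interface uniformity but unused.
#'
#' @param targets Directional targets, see [cerebral_targets()].
#' @param config Full configuration list.
#' @param seed Unused (calibration is analytic and deterministic).
#' @param verify If `FALSE`, skip the target verification sweep.
#' @return Calibrated cerebral parameter list.
#' @export
calibrate_cerebral <- function(targets = cerebral_targets(),
                               config = default_config(),
                               seed = NULL, verify = TRUE) {
  if (isTRUE(targets$flat)) {
    config$cerebral$a_P <- 0
    config$cerebral$g_CO2f <- 0
    config$cerebral$g_uf <- 0
    config$cerebral$g_O2f <- 0
    config$cerebral$g_saf <- 0
    return(cerebral_params(config))
  }
  p <- cerebral_params(config)
  if (!verify) return(p)

  violations <- character(0)
  up <- config$ranges
  for (nm in names(targets$directions)) {
    inp <- list()
    inp[[nm]] <- up[[nm]][2]
    ss <- cerebral_steady_state(inp, p)
    want <- targets$directions[[nm]]
    if (sign(ss$dHbO2) != want[["dHbO2"]]) {
      violations <- c(violations, sprintf(
        "%s step: sign(dHbO2) = %+d, target %+d", nm, sign(ss$dHbO2), want[["dHbO2"]]))
    }
    if (sign(ss$dHHb) != want[["dHHb"]]) {
      violations <- c(violations, sprintf(
        "%s step: sign(dHHb) = %+d, target %+d", nm, sign(ss$dHHb), want[["dHHb"]]))
    }
  }
  if (isTRUE(targets$cmro2_monotone_u)) {
    us <- seq(up$u[1], up$u[2], length.out = 11)
    cm <- vapply(us, function(u) cerebral_steady_state(list(u = u), p)$CMRO2,
                 numeric(1))
    if (any(diff(cm) < -1e-12)) {
      violations <- c(violations, "CMRO2 not monotone non-decreasing in u")
    }
  }
  if (length(violations) > 0) {
    stop("calibrate_cerebral: targets violated:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  p
}
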