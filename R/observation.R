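#' Haemoglobin signals for one compartment
#'
#' Converts volume and saturation time series into NIRS-comparable
#' haemoglobin changes: absolute amounts are blood volume times saturation
#' (HbO2) or desaturation (HHb), scaled by the shared haematocrit /
#' vessel-density factor `hb_scale`; changes are taken against the
#' first-sample baseline, so every output series starts at exactly 0.
#'
#' @param t Time grid (s).
#' @param Va,Vv Arterial and venous normalised volumes (same length as `t`).
#' @param Sa,Sv Arterial and venous saturations (%, same length or scalar).
#' @param hb_scale uM haemoglobin per unit normalised volume of fully
#'   saturated blood.
#' @param compartment Label: "cerebral", "scalp" or "merged".
#' @return Data frame `t`, `dHbO2`, `dHHb` (uM), `compartment`.
#' @export
compartment_haemoglobin <- function(t, Va, Vv, Sa, Sv, hb_scale = 100,
                                    compartment = "cerebral") {
  n <- length(t)
  Sa <- rep_len(Sa, n); Sv <- rep_len(Sv, n)
  if (length(Va) != n || length(Vv) != n) {
    stop("compartment_haemoglobin: series lengths do not match the time grid",
         call. = FALSE)
  }
  sa <- Sa / 100; sv <- Sv / 100
  HbO2 <- hb_scale * (Va * sa + Vv * sv)
  HHb <- hb_scale * (Va * (1 - sa) + Vv * (1 - sv))
  data.frame(t = t, dHbO2 = HbO2 - HbO2[1], dHHb = HHb - HHb[1],
             compartment = compartment)
}

#' Merge cerebral and scalp signals
#'
#' Weighted sum of the per-compartment haemoglobin outputs,
#' `merged = w_cerebral * cerebral + w_scalp * scalp`, elementwise. Pure
#' post-processing: merging never feeds back into the model dynamics.
#'
#' @param cerebral,scalp Data frames from [compartment_haemoglobin()],
#'   aligned on the same time grid.
#' @param w Named list/vector with non-negative `w_scalp` and `w_cerebral`.
#' @return Data frame with `compartment = "merged"`.
#' @export
merge_signals <- function(cerebral, scalp, w) {
  w <- as.list(w)
  if (w$w_scalp < 0 || w$w_cerebral < 0) {
    stop("merge_signals: weights must be non-negative", call. = FALSE)
  }
  if (nrow(cerebral) != nrow(scalp) ||
      any(abs(cerebral$t - scalp$t) > 1e-9)) {
    stop("merge_signals: series are not aligned", call. = FALSE)
  }
  data.frame(
    t = cerebral$t,
    dHbO2 = w$w_cerebral * cerebral$dHbO2 + w$w_scalp * scalp$dHbO2,
    dHHb = w$w_cerebral * cerebral$dHHb + w$w_scalp * scalp$dHHb,
    compartment = "merged"
  )
}

#' Cytochrome-c-oxidase redox output
#'
#' The NIRS-visible CCO redox change is reported as the change in the
#' oxidised CuA pool from its first-sample baseline, scaled to uM.
#'
#' @param t Time grid (s).
#' @param CuA_ox Oxidised CuA concentration trajectory (mM).
#' @param cco_scale Dimensionless output scaling.
#' @return Data frame `t`, `doxCCO` (uM).
#' @export
cco_output <- function(t, CuA_ox, cco_scale = 1) {
  data.frame(t = t, doxCCO = cco_scale * 1000 * (CuA_ox - CuA_ox[1]))
}
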