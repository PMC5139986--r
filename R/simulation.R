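input_names <- c("Pa", "PaCO2", "SaO2", "u", "Flux_y")

blank_timeline <- function(t, baseline) {
  tl <- data.frame(t = t)
  for (nm in input_names) tl[[nm]] <- baseline[[nm]]
  tl
}

#' Build a step-change input protocol
#'
#' A square wave on one or more systemic inputs (all others held at
#' baseline): baseline until `t_on`, the `high` level until `t_off`, then
#' back to baseline.
#'
#' @param variable Character vector of input names
#'   (`Pa`, `PaCO2`, `SaO2`, `u`, `Flux_y`).
#' @param high Step level(s), recycled along `variable`. Defaults to the
#'   upper end of each input's normal range.
#' @param t_on,t_off,t_end Step timing and protocol length (s).
#' @param dt Time grid spacing (s).
#' @param config Configuration (for baselines and ranges).
#' @return An input timeline: data frame `t`, `Pa`, `PaCO2`, `SaO2`, `u`,
#'   `Flux_y` with a `protocol` attribute.
#' @export
build_step_protocol <- function(variable, high = NULL,
                                t_on = 120, t_off = 420, t_end = 600,
                                dt = 1, config = default_config()) {
  stopifnot(all(variable %in% input_names))
  if (is.null(high)) {
    high <- vapply(variable, function(v) config$ranges[[v]][2], numeric(1))
  }
  high <- rep_len(high, length(variable))
  tl <- blank_timeline(seq(0, t_end, by = dt), config$baseline)
  on <- tl$t >= t_on & tl$t < t_off
  for (k in seq_along(variable)) tl[[variable[k]]][on] <- high[k]
  attr(tl, "protocol") <- paste0("step_", paste(variable, collapse = "+"))
  tl
}

#' Build a multi-frequency input protocol
#'
#' Every input oscillates during a common segment, each at its own
#' frequency, so the input deviations are (near-)orthogonal and the
#' compartment responses they drive are linearly independent. Default
#' frequencies are distinct harmonics of the segment length, making the
#' deviations exactly uncorrelated over the segment.
#'
#' @param frequencies Named vector of frequencies (Hz), one per input; all
#'   must be distinct.
#' @param amplitudes Named vector of oscillation amplitudes (input units),
#'   defaults chosen inside the normal ranges.
#' @param t_start,t_stop Oscillatory segment (s).
#' @param t_end Protocol length (s).
#' @param dt Grid spacing (s).
#' @param config Configuration.
#' @return An input timeline (see [build_step_protocol()]).
#' @export
build_multifrequency_protocol <- function(frequencies = NULL, amplitudes = NULL,
                                          t_start = 120, t_stop = 620,
                                          t_end = 740, dt = 1,
                                          config = default_config()) {
  seg <- t_stop - t_start
  if (is.null(frequencies)) {
    frequencies <- c(Pa = 2, PaCO2 = 3, SaO2 = 4, u = 5, Flux_y = 6) / seg
  }
  if (is.null(amplitudes)) {
    amplitudes <- c(Pa = 15, PaCO2 = 2, SaO2 = 3, u = 0.2, Flux_y = 0.2)
  }
  stopifnot(all(names(frequencies) %in% input_names))
  if (anyDuplicated(frequencies[amplitudes[names(frequencies)] > 0])) {
    stop("build_multifrequency_protocol: frequencies must be distinct",
         call. = FALSE)
  }
  tl <- blank_timeline(seq(0, t_end, by = dt), config$baseline)
  on <- tl$t >= t_start & tl$t < t_stop
  for (nm in names(frequencies)) {
    tl[[nm]][on] <- tl[[nm]][on] +
      amplitudes[[nm]] * sin(2 * pi * frequencies[[nm]] * (tl$t[on] - t_start))
  }
  attr(tl, "protocol") <- "multifrequency"
  tl
}

#' Run a joint cerebral + scalp simulation
#'
#' Integrates the cerebral compartment and both scalp variants
#' (pressure-based and flux-based) over an input timeline with a stiff-safe
#' solver (`deSolve::lsoda`, atol 1e-8 / rtol 1e-6), then converts the
#' trajectories into per-compartment and merged haemoglobin signals and
#' the CCO redox output. Output sampling is decoupled from the solver's
#' internal steps. Deterministic: identical timeline and configuration give
#' identical output.
#'
#' @param timeline Input timeline from [build_step_protocol()] /
#'   [build_multifrequency_protocol()] / [read_timeseries_csv()].
#' @param model Calibrated model from [build_model()].
#' @param sample_rate Output sampling rate (Hz); default from the
#'   configuration (1 Hz).
#' @return List of class `fnirs_simulation`: `time`, `states` (data frame
#'   of raw state trajectories and auxiliaries), `signals` (data frame with
#'   columns `t`, `dHbO2_cerebral`, `dHHb_cerebral`, `dHbO2_scalp`,
#'   `dHHb_scalp`, `dHbO2_merged`, `dHHb_merged`, `doxCCO`; the scalp
#'   columns follow the configured variant), and `scalp_variants` with the
#'   signals of both scalp variants.
#' @export
run_simulation <- function(timeline, model, sample_rate = NULL) {
  cfg <- model$config
  p <- model$cerebral
  sp <- model$scalp
  if (is.null(sample_rate)) sample_rate <- cfg$signal$sample_rate

  interp <- lapply(input_names, function(nm) {
    stats::approxfun(timeline$t, timeline[[nm]], method = "linear", rule = 2)
  })
  names(interp) <- input_names

  y0 <- c(cerebral_baseline_state(p),
          Pv_x = sp$Pv_n, Pv_y = sp$Pv_n)

  rhs <- function(t, y, parms) {
    inp <- lapply(interp, function(f) f(t))
    cer <- cerebral_derivatives(y[1:8], inp, p)
    Fx <- scalp_flow_pressure(inp$Pa, sp)
    Fy <- scalp_flow_flux(inp$Flux_y, sp)
    dx <- scalp_derivatives(c(Pv = y[["Pv_x"]]), inp$Pa, Fx, sp)
    dy <- scalp_derivatives(c(Pv = y[["Pv_y"]]), inp$Pa, Fy, sp)
    list(c(cer$deriv, dx$deriv, dy$deriv))
  }

  times <- seq(timeline$t[1], timeline$t[nrow(timeline)], by = 1 / sample_rate)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-6, atol = 1e-8, hmax = 1, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("run_simulation: solver failure near t = ",
         sol[nrow(sol), 1], " s", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  t <- sol$time

  inp <- lapply(interp, function(f) f(t))
  Sa <- inp$SaO2
  F_c <- sol$r^4 * inp$Pa / p$Pa_n
  Sv_c <- vapply(seq_along(t), function(i) {
    100 * venous_saturation(F_c[i], Sa[i] / 100, sol$O2[i], p)
  }, numeric(1))
  Va_c <- p$Va_n * sol$r^2
  Vv_c <- rep(p$Vv_n, length(t))

  cer_sig <- compartment_haemoglobin(t, Va_c, Vv_c, Sa, Sv_c,
                                     p$hb_scale, "cerebral")

  scalp_sig <- function(Pv, flow) {
    G <- flow / inp$Pa
    r <- (G / sp$G_n)^0.25
    compartment_haemoglobin(t, sp$Va_n * r^2, sp$Vv_nc + sp$Cv_vol * Pv,
                            Sa, sp$SvO2_n, sp$hb_scale, "scalp")
  }
  sig_x <- scalp_sig(sol$Pv_x, scalp_flow_pressure(inp$Pa, sp))
  sig_y <- scalp_sig(sol$Pv_y, scalp_flow_flux(inp$Flux_y, sp))
  sca <- if (identical(cfg$scalp$model, "flux")) sig_y else sig_x

  merged <- merge_signals(cer_sig, sca, cfg$merge)
  cco <- cco_output(t, sol$CuA_ox, p$cco_scale)

  signals <- data.frame(
    t = t,
    dHbO2_cerebral = cer_sig$dHbO2, dHHb_cerebral = cer_sig$dHHb,
    dHbO2_scalp = sca$dHbO2, dHHb_scalp = sca$dHHb,
    dHbO2_merged = merged$dHbO2, dHHb_merged = merged$dHHb,
    doxCCO = cco$doxCCO
  )
  states <- cbind(sol, F_c = F_c, SvO2_c = Sv_c, Va_c = Va_c, Vv_c = Vv_c,
                  as.data.frame(inp))
  structure(list(time = t, states = states, signals = signals,
                 scalp_variants = list(pressure = sig_x, flux = sig_y),
                 timeline = timeline),
            class = "fnirs_simulation")
}

#' @export
print.fnirs_simulation <- function(x, ...) {
  cat("<fnirs_simulation>", length(x$time), "samples,",
      x$time[length(x$time)] - x$time[1], "s, protocol:",
      attr(x$timeline, "protocol") %||% "custom", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise a laser-Doppler flux series to its baseline
#'
#' Divides the series by the median over an initial baseline window (median
#' rather than mean, for robustness to transients in the window), so the
#' windowed normalised values have median 1.
#'
#' @param t Time grid (s).
#' @param flux Raw flux series.
#' @param window Baseline window length (s) from the start of the record.
#' @return Normalised flux series.
#' @export
normalise_flux <- function(t, flux, window = 120) {
  idx <- t <= t[1] + window
  if (!any(idx)) stop("normalise_flux: empty baseline window", call. = FALSE)
  flux / stats::median(flux[idx])
}

#' Centered moving-average smoothing
#'
#' Sliding-window mean with the window centered on each sample; at the
#' edges the window shrinks symmetrically-as-available rather than
#' trimming the series, so short baseline segments are preserved.
#'
#' @param x Series to smooth.
#' @param window Window length (s).
#' @param dt Sampling interval (s).
#' @return Smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window = 60, dt = 1) {
  if (window < dt) stop("moving_average: window below sampling interval",
                        call. = FALSE)
  half <- floor(window / dt / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Linear resampling onto a uniform grid
#'
#' @param t Source time grid (uniform).
#' @param x Series values.
#' @param target_dt Target sampling interval (s).
#' @return List with the new `t` and interpolated `x`; endpoints preserved.
#' @export
resample_linear <- function(t, x, target_dt) {
  out_t <- seq(t[1], t[length(t)], by = target_dt)
  list(t = out_t, x = stats::approx(t, x, xout = out_t)$y)
}
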