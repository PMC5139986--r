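#' Default model configuration
#'
#' Returns the full nested list of defaults for every component of the
#' simulator: baseline systemic inputs and their admissible ranges, the
#' cerebral compartment (regulation gains, metabolic chain coefficients,
#' oxygen transport constants), the scalp Windkessel compartment, signal
#' conditioning options, merge weights and scenario-search settings.
#'
#' Baselines and ranges follow the standard simulation protocol: mean
#' arterial pressure 100 (75--125) mmHg, PaCO2 40 (37.5--42.5) mmHg,
#' SaO2 96 (90--100) %, relative demand u 1.0 (0.75--1.25), normalised
#' laser-Doppler flux 1.0 (0.75--1.25). The scalp split parameters default
#' to `Volc_frac = 0.1`, `Rfrac_v = 0.1` and a 3:1 venous:arterial volume
#' ratio. Signal conditioning defaults: 1 Hz output sampling, 60 s moving
#' average, 120 s baseline window for flux normalisation, 150 s (2.5 min)
#' maximum cross-correlation lag.
#'
#' @return A nested list; see sections in the source for individual entries.
#' @export
default_config <- function() {
  list(
    baseline = list(Pa = 100, PaCO2 = 40, SaO2 = 96, u = 1.0, Flux_y = 1.0),
    ranges = list(
      Pa = c(75, 125), PaCO2 = c(37.5, 42.5), SaO2 = c(90, 100),
      u = c(0.75, 1.25), Flux_y = c(0.75, 1.25)
    ),
    # spontaneous SaO2 increases are implausible in functional experiments,
    # so optimisation caps SaO2 at its baseline value
    optim_upper = list(SaO2 = 96),
    cerebral = list(
      # regulation: demanded flow and its gains (fractional per fractional input)
      a_P     = 0.20,  # residual passive pressure slope of achieved flow
      g_CO2f  = 2.0,   # flow gain on fractional PaCO2 change (~5 %/mmHg)
      g_uf    = 0.8,   # flow gain on demand (flow +20 % at u = 1.25)
      g_O2f   = 0.15,  # negative feedback from (slow-sensed) tissue O2
      g_saf   = 1.0,   # desaturation-driven dilation
      tau_r   = 10,    # s, radius relaxation
      tau_fb  = 60,    # s, tissue-O2 sensor for the slow feedback channel
      vratio  = 3,     # venous:arterial cerebral volume ratio
      SvO2_n  = 70,    # %, baseline cerebral venous saturation (assumption)
      O2_n    = 0.024, # mM, baseline tissue O2
      CMRO2_n = 0.02,  # mM/s, baseline tissue O2 consumption
      phi     = 0.06,  # mM, capillary O2 proxy per unit mean saturation
      # metabolic chain: pool sizes, baseline state and rate coefficients
      CuA_tot = 0.0022,  # mM
      a3_tot  = 0.0022,  # mM
      CuA_ox_frac_n = 2 / 3,
      a3_ox_frac_n  = 2 / 3,
      f_n   = 0.01,   # mM/s, baseline electron transfer rate
      dp_n  = 145,    # mV, baseline proton motive force
      kp    = 2e4,    # mV per mM transferred, proton pumping
      C_dp  = 4,      # buffering of the proton motive force
      # elasticities: fractional rate change per unit log-concentration or
      # per fractional change in proton motive force (signs fixed by the
      # chain thermodynamics: dp opposes all forward rates)
      e1p = 1.5, e1a = 2.5,
      e2p = 1.0, e2a = 1.0, e2b = 2.0,
      e3p = 0.5, e3b = 2.0, e3O = 1.0,
      hb_scale  = 100, # uM haemoglobin per unit normalised blood volume
      cco_scale = 1    # scaling of the oxidised-CuA NIRS output
    ),
    scalp = list(
      model     = "pressure", # "pressure" or "flux"
      Volc_frac = 0.1,
      Rfrac_v   = 0.1,
      vratio    = 3,
      Cv        = 2.0,  # venous compliance (normalised flow / mmHg); tau = Cv/(G+Gv)
      lam_Fx    = NULL, # pressure->flow intercept; NULL = fit packaged table
      lam_Fx_p  = NULL, # pressure->flow slope
      Fy_n      = NULL  # normal flow for the flux variant; NULL = pressure baseline
    ),
    signal = list(
      sample_rate = 1, smooth_window = 60,
      baseline_window = 120, ccf_max_lag = 150
    ),
    merge = list(w_scalp = 0.5, w_cerebral = 0.5),
    scenario = list(
      grid_n = 21, match_frac = 0.15,
      de_pop = 20, de_gens = 40, de_F = 0.8, de_CR = 0.9
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it (recursively) over the package
#' defaults, so a partial -- or empty -- user file is always valid.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A full configuration list as from [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Assemble a calibrated model
#'
#' Calibrates the cerebral and scalp compartments from a configuration and
#' returns the model object used by the simulation, scenario-search and
#' attribution functions.
#'
#' @param config Configuration list, see [default_config()].
#' @return An object of class `fnirs_model`: a list with elements `config`,
#'   `cerebral` (calibrated cerebral parameters) and `scalp` (calibrated
#'   scalp parameters and baseline state).
#' @export
build_model <- function(config = default_config()) {
  cer <- calibrate_cerebral(config = config)
  sca <- calibrate_scalp(config$scalp, baseline = config$baseline,
                         SvO2_n = config$cerebral$SvO2_n,
                         hb_scale = config$cerebral$hb_scale)
  structure(list(config = config, cerebral = cer, scalp = sca),
            class = "fnirs_model")
}

#' @export
print.fnirs_model <- function(x, ...) {
  cat("<fnirs_model>\n")
  cat("  cerebral: flow gains (P,CO2,u,O2,Sa) =",
      with(x$cerebral, sprintf("%.2f/%.2f/%.2f/%.2f/%.2f",
                               a_P, g_CO2f, g_uf, g_O2f, g_saf)), "\n")
  cat("  scalp:   ", x$config$scalp$model, "variant, Volc_frac =",
      x$scalp$Volc_frac, ", Rfrac_v =", x$scalp$Rfrac_v, "\n")
  cat("  baseline inputs: Pa =", x$config$baseline$Pa,
      "PaCO2 =", x$config$baseline$PaCO2,
      "SaO2 =", x$config$baseline$SaO2, "\n")
  invisible(x)
}
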