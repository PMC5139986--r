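#' Response templates for activation and its false-negative variants
#'
#' The activation template is the model's own steady-state response to a
#' pure demand increase (u at the top of its normal range, all systemic
#' inputs at baseline): a rise in HbO2 with a fall in HHb. The three
#' non-activation (false-negative) templates are: FN1 -- no haemodynamic
#' change at all; FN2 -- the HbO2 rise without any HHb change; FN3 -- the
#' HbO2 rise with an HHb rise of the same magnitude as the activation fall.
#'
#' @param model Calibrated model from [build_model()].
#' @param u_act Demand level defining activation (default: upper end of the
#'   normal range).
#' @return Data frame with columns `label`, `dHbO2`, `dHHb` (uM), rows in
#'   the fixed classification order activation, FN1, FN2, FN3.
#' @export
response_templates <- function(model, u_act = NULL) {
  if (is.null(u_act)) u_act <- model$config$ranges$u[2]
  act <- cerebral_steady_state(list(u = u_act), model$cerebral)
  data.frame(
    label = c("activation", "FN1", "FN2", "FN3"),
    dHbO2 = c(act$dHbO2, 0, act$dHbO2, act$dHbO2),
    dHHb = c(act$dHHb, 0, 0, -act$dHHb)
  )
}

#' Classify a steady-state response against the templates
#'
#' Assigns the label of the template with the lowest total absolute error
#' `|dHbO2 - target| + |dHHb - target|`. Ties are broken by the fixed
#' template order (activation, FN1, FN2, FN3).
#'
#' @param dHbO2,dHHb Steady-state changes (uM).
#' @param templates Template data frame from [response_templates()].
#' @return List: `label`, `distance` (to the winning template) and the
#'   named vector of all per-template `distances`.
#' @export
classify_response <- function(dHbO2, dHHb, templates) {
  stopifnot(nrow(templates) > 0)
  d <- abs(dHbO2 - templates$dHbO2) + abs(dHHb - templates$dHHb)
  names(d) <- templates$label
  k <- which.min(d)
  list(label = templates$label[k], distance = d[[k]], distances = d)
}

#' Steady-state response surface over pressure and CO2
#'
#' Step-change simulations across the normal ranges of arterial pressure
#' and PaCO2 (transients ignored; only the final steady state is kept),
#' each grid point classified against the response templates. At `u = 1`
#' a cell classified "activation" is a false positive; at an elevated `u`
#' a cell classified as any FN template is a false negative.
#'
#' @param model Calibrated model.
#' @param u Demand level held during the sweep.
#' @param Pa_range,PaCO2_range Ranges (default: normal ranges).
#' @param n Grid points per axis.
#' @param templates Optional precomputed templates.
#' @return Data frame `Pa`, `PaCO2`, `dHbO2`, `dHHb`, `label`, `distance`.
#' @export
sweep_response_surface <- function(model, u = 1, Pa_range = NULL,
                                   PaCO2_range = NULL, n = NULL,
                                   templates = NULL) {
  cfg <- model$config
  if (is.null(Pa_range)) Pa_range <- cfg$ranges$Pa
  if (is.null(PaCO2_range)) PaCO2_range <- cfg$ranges$PaCO2
  if (is.null(n)) n <- cfg$scenario$grid_n
  if (is.null(templates)) templates <- response_templates(model)
  grid <- expand.grid(Pa = seq(Pa_range[1], Pa_range[2], length.out = n),
                      PaCO2 = seq(PaCO2_range[1], PaCO2_range[2], length.out = n))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ss <- cerebral_steady_state(
      list(Pa = grid$Pa[i], PaCO2 = grid$PaCO2[i], u = u), model$cerebral)
    cl <- classify_response(ss$dHbO2, ss$dHHb, templates)
    data.frame(dHbO2 = ss$dHbO2, dHHb = ss$dHHb,
               label = cl$label, distance = cl$distance)
  })
  cbind(grid, do.call(rbind, res))
}

#' Search for input combinations producing false responses
#'
#' Seeded global optimisation (differential evolution) over step amplitudes
#' of the chosen free inputs, minimising the total absolute error between
#' the resulting steady-state (dHbO2, dHHb) and a response template. A
#' false-positive (`"FP"`) search targets the activation template with
#' demand held at baseline; the FN searches target the corresponding
#' non-activation template with demand raised to the activation level.
#' When scalp contamination is included (`Flux_y` and the merge weights
#' among the free variables), the compared output is the weighted sum of
#' the cerebral and (flux-variant) scalp steady responses.
#'
#' The search is stochastic under its seed; results are neither unique nor
#' necessarily optimal, so acceptance is based on the achieved objective,
#' not the argument values.
#'
#' @param model Calibrated model.
#' @param template `"FP"`, `"FN1"`, `"FN2"` or `"FN3"`.
#' @param free Character vector of free variables among `Pa`, `PaCO2`,
#'   `SaO2`, `Flux_y`, `w_scalp`, `w_cerebral`.
#' @param seed Integer seed for the optimiser.
#' @param u_act Demand level representing activation.
#' @param templates Optional precomputed templates.
#' @return List of class `scenario_result`: optimised `inputs` (named),
#'   `weights`, achieved `output` (dHbO2, dHHb), `distance`,
#'   `classification` (vs all templates), logical `matched` (distance
#'   below `match_frac` of the activation magnitude), `baseline_distance`
#'   and the `template` row targeted.
#' @export
optimise_scenario <- function(model, template = c("FP", "FN1", "FN2", "FN3"),
                              free = c("Pa", "PaCO2"), seed = 1,
                              u_act = NULL, templates = NULL) {
  template <- match.arg(template)
  cfg <- model$config
  p <- model$cerebral
  sp <- model$scalp
  if (is.null(u_act)) u_act <- cfg$ranges$u[2]
  if (is.null(templates)) templates <- response_templates(model, u_act)

  u <- if (template == "FP") 1 else u_act
  tgt_label <- if (template == "FP") "activation" else template
  tgt <- templates[templates$label == tgt_label, ]

  weight_vars <- c("w_scalp", "w_cerebral")
  input_vars <- setdiff(free, weight_vars)
  stopifnot(all(input_vars %in% c("Pa", "PaCO2", "SaO2", "Flux_y")))
  use_scalp <- any(c("Flux_y", weight_vars) %in% free)

  lower <- upper <- numeric(0)
  for (v in free) {
    if (v %in% weight_vars) {
      lower <- c(lower, 0); upper <- c(upper, 1)
    } else {
      rng <- cfg$ranges[[v]]
      hi <- rng[2]
      if (!is.null(cfg$optim_upper[[v]])) hi <- min(hi, cfg$optim_upper[[v]])
      lower <- c(lower, rng[1]); upper <- c(upper, hi)
    }
  }
  names(lower) <- names(upper) <- free

  bl <- cfg$baseline
  Sa0 <- bl$SaO2 / 100
  scalp0 <- scalp_steady_state(sp$Pa_n, sp$Fy_n, sp)

  evaluate <- function(x) {
    x <- as.list(x)
    # exact name lookup: $ would partial-match Pa against PaCO2
    pick <- function(nm, fallback) x[[nm]] %||% fallback
    inp <- list(Pa = pick("Pa", bl$Pa), PaCO2 = pick("PaCO2", bl$PaCO2),
                SaO2 = pick("SaO2", bl$SaO2), u = u)
    ss <- tryCatch(cerebral_steady_state(inp, p), error = function(e) NULL)
    if (is.null(ss)) return(NULL)
    out <- c(ss$dHbO2, ss$dHHb)
    if (use_scalp) {
      flux <- pick("Flux_y", bl$Flux_y)
      st <- scalp_steady_state(inp$Pa, scalp_flow_flux(flux, sp), sp)
      sa <- inp$SaO2 / 100; sv <- sp$SvO2_n / 100
      dHbO2_s <- sp$hb_scale * ((st[["Va"]] * sa + st[["Vv"]] * sv) -
                                  (scalp0[["Va"]] * Sa0 + scalp0[["Vv"]] * sv))
      dHHb_s <- sp$hb_scale * ((st[["Va"]] * (1 - sa) + st[["Vv"]] * (1 - sv)) -
                                 (scalp0[["Va"]] * (1 - Sa0) + scalp0[["Vv"]] * (1 - sv)))
      wc <- pick("w_cerebral", cfg$merge$w_cerebral)
      ws <- pick("w_scalp", cfg$merge$w_scalp)
      out <- wc * out + ws * c(dHbO2_s, dHHb_s)
    }
    out
  }
  objective <- function(x) {
    names(x) <- free
    out <- evaluate(x)
    if (is.null(out)) return(1e6)
    abs(out[1] - tgt$dHbO2) + abs(out[2] - tgt$dHHb)
  }

  base_x <- vapply(free, function(v) {
    if (v %in% weight_vars) {
      if (v == "w_cerebral") 1 else 0
    } else bl[[v]]
  }, numeric(1))
  baseline_distance <- objective(base_x)

  de <- de_optimise(objective, lower, upper, seed = seed,
                    pop = cfg$scenario$de_pop, gens = cfg$scenario$de_gens,
                    F = cfg$scenario$de_F, CR = cfg$scenario$de_CR)
  par <- de$par
  names(par) <- free
  if (de$value >= baseline_distance) {
    warning("optimise_scenario: no improvement over the baseline inputs; ",
            "returning the baseline", call. = FALSE)
    par <- base_x
    de$value <- baseline_distance
  }

  out <- evaluate(par)
  act_scale <- sum(abs(templates[templates$label == "activation",
                                 c("dHbO2", "dHHb")]))
  structure(list(
    template = tgt, free = free,
    inputs = par[intersect(free, c("Pa", "PaCO2", "SaO2", "Flux_y"))],
    weights = par[intersect(free, weight_vars)],
    u = u, output = c(dHbO2 = out[1], dHHb = out[2]),
    distance = de$value,
    classification = classify_response(out[1], out[2], templates),
    matched = de$value < cfg$scenario$match_frac * act_scale,
    baseline_distance = baseline_distance,
    seed = seed, evals = de$evals
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> target %s: distance %.4f (baseline %.4f), %s\n",
              x$template$label, x$distance, x$baseline_distance,
              if (x$matched) "matched" else "not matched"))
  if (length(x$inputs)) {
    cat("  inputs: ", paste(names(x$inputs), signif(x$inputs, 4),
                            sep = "=", collapse = ", "), "\n")
  }
  if (length(x$weights)) {
    cat("  weights:", paste(names(x$weights), signif(x$weights, 3),
                            sep = "=", collapse = ", "), "\n")
  }
  cat("  achieved (dHbO2, dHHb) = (",
      sprintf("%+.3f, %+.3f", x$output[1], x$output[2]),
      ") uM, classified as", x$classification$label, "\n")
  invisible(x)
}
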