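test_that("flow estimates follow their linear relations", {
  p <- list(lam_Fx = 10, lam_Fx_p = 0.4, Fy_n = 50)
  expect_equal(scalp_flow_pressure(100, p), 50)
  p0 <- list(lam_Fx = 10, lam_Fx_p = 0)
  expect_equal(scalp_flow_pressure(c(80, 100, 120), p0), rep(10, 3))
  expect_equal(scalp_flow_flux(1, p), 50)
  expect_equal(scalp_flow_flux(1.2, p), 60)
  expect_error(scalp_flow_pressure(100, list(lam_Fx = -100, lam_Fx_p = 0.4)),
               "non-positive flow")
})

test_that("fitted pressure coefficients give flow increasing with pressure", {
  fit <- fit_scalp_flow()
  expect_gt(fit$lam_Fx_p, 0)
  sp <- test_model()$scalp
  expect_gt(scalp_flow_pressure(125, sp), scalp_flow_pressure(100, sp))
  # flux-variant normal flow matches the pressure-model baseline
  expect_equal(sp$Fy_n, scalp_flow_pressure(100, sp))
})

test_that("baseline calibration satisfies the volume and resistance splits", {
  sp <- test_model()$scalp
  st <- sp$state0
  expect_equal(unname(st[["Va"]] + st[["Vv"]]), 1)
  expect_equal(unname(st[["Vv"]] / st[["Va"]]), 3)
  expect_equal(unname(st[["Va"]]), 0.25)
  expect_equal(unname(st[["Vv"]]), 0.75)
  # venous pressure divider = venous resistance share
  expect_equal(unname(st[["Pv"]]) / sp$Pa_n, sp$Rfrac_v)
  expect_equal(unname(st[["Pv"]]), 10, tolerance = 1e-10)
  # compliant share of the venous volume
  expect_equal(sp$Cv_vol * sp$Pv_n, 0.075)
  # baseline state is stationary
  d <- scalp_derivatives(st, sp$Pa_n, sp$F_n, sp)
  expect_equal(unname(d$deriv[["Pv"]]), 0, tolerance = 1e-12)
})

test_that("symmetric and off-default calibrations behave analytically", {
  cfg <- default_config()$scalp
  cfg$vratio <- 1
  cal <- calibrate_scalp(cfg)
  expect_equal(unname(cal$state0[["Va"]]), 0.5)
  expect_equal(unname(cal$state0[["Vv"]]), 0.5)

  # G = Gv when the venous share is half the total resistance
  cfg <- default_config()$scalp
  cfg$Rfrac_v <- 0.5
  cal <- calibrate_scalp(cfg)
  expect_equal(cal$G_n, cal$Gv)
  expect_equal(unname(scalp_steady_state(100, cal$F_n, cal)[["Pv"]]), 50)

  bad <- default_config()$scalp
  bad$Volc_frac <- 1.5
  expect_error(calibrate_scalp(bad), "Volc_frac")
})

test_that("steady state solves the venous pressure balance", {
  sp <- test_model()$scalp
  for (Pa in c(80, 100, 120)) {
    F <- scalp_flow_pressure(Pa, sp)
    st <- scalp_steady_state(Pa, F, sp)
    G <- F / Pa
    expect_equal(unname(st[["Pv"]]), G * Pa / (G + sp$Gv), tolerance = 1e-12)
    d <- scalp_derivatives(st, Pa, F, sp)
    expect_equal(unname(d$deriv[["Pv"]]), 0, tolerance = 1e-12)
  }
})

test_that("pressure step relaxes exponentially with time constant Cv/(G+Gv)", {
  sp <- test_model()$scalp
  Pa1 <- 125
  F1 <- scalp_flow_pressure(Pa1, sp)
  G1 <- F1 / Pa1
  tau <- sp$Cv / (G1 + sp$Gv)
  Pv_inf <- G1 * Pa1 / (G1 + sp$Gv)
  Pv0 <- sp$Pv_n

  rhs <- function(t, y, parms) {
    list(scalp_derivatives(c(Pv = y[[1]]), Pa1, F1, sp)$deriv)
  }
  times <- seq(0, 5 * tau, length.out = 200)
  sol <- deSolve::lsoda(c(Pv = Pv0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  analytic <- Pv_inf + (Pv0 - Pv_inf) * exp(-times / tau)
  expect_lt(max(abs(sol[, "Pv"] - analytic)) / abs(Pv_inf - Pv0), 0.01)
  # venous volume is an affine map of Pv, so it matches the same exponential
  Vv_sim <- sp$Vv_nc + sp$Cv_vol * sol[, "Pv"]
  Vv_ana <- sp$Vv_nc + sp$Cv_vol * analytic
  expect_lt(max(abs(Vv_sim - Vv_ana)) / diff(range(Vv_ana)), 0.01)
})

test_that("without saturation changes the scalp haemoglobin species co-vary", {
  m <- test_model()
  for (proto in list(build_step_protocol("Flux_y"),
                     build_step_protocol("Pa"))) {
    sim <- run_simulation(proto, m)
    for (sig in sim$scalp_variants) {
      on <- sim$time > 300 & sim$time < 420 # settled step segment
      expect_true(all(sign(sig$dHbO2[on]) == sign(sig$dHHb[on])))
    }
  }
})

test_that("scalp and cerebral compartments are conditionally independent", {
  m <- test_model()
  # demand drives only the cerebral compartment
  sim_u <- run_simulation(build_step_protocol("u"), m)
  expect_lt(max(abs(sim_u$scalp_variants$pressure$dHbO2)), 1e-9)
  expect_lt(max(abs(sim_u$scalp_variants$flux$dHbO2)), 1e-9)
  # laser-Doppler flux drives only the flux-variant scalp
  sim_f <- run_simulation(build_step_protocol("Flux_y"), m)
  expect_lt(max(abs(sim_f$signals$dHbO2_cerebral)), 1e-3)
  expect_gt(max(abs(sim_f$scalp_variants$flux$dHbO2)), 0.5)
})

test_that("step-response shape is insensitive to the split parameters", {
  base_shape <- function(Volc_frac, Rfrac_v) {
    cfg <- default_config()
    cfg$scalp$Volc_frac <- Volc_frac
    cfg$scalp$Rfrac_v <- Rfrac_v
    sp <- calibrate_scalp(cfg$scalp)
    Pa1 <- 125
    F1 <- scalp_flow_pressure(Pa1, sp)
    rhs <- function(t, y, parms) {
      list(scalp_derivatives(c(Pv = y[[1]]), Pa1, F1, sp)$deriv)
    }
    sol <- deSolve::lsoda(c(Pv = sp$Pv_n), 0:120, rhs, NULL,
                          rtol = 1e-8, atol = 1e-8)
    Vv <- sp$Vv_nc + sp$Cv_vol * sol[, "Pv"]
    (Vv - Vv[1]) / (Vv[length(Vv)] - Vv[1]) # normalised response shape
  }
  ref <- base_shape(0.1, 0.1)
  for (vc in c(0.05, 0.15)) for (rv in c(0.05, 0.15)) {
    expect_lt(max(abs(base_shape(vc, rv) - ref)), 0.3)
  }
})

test_that("scalp oxygen passes arterial saturation through, venous fixed", {
  sp <- test_model()$scalp
  ox <- scalp_oxygen(sp$state0, 96, sp)
  expect_equal(ox$arterial, 96)
  ox2 <- scalp_oxygen(sp$state0, c(96, 100, 90), sp)
  expect_equal(ox2$arterial, c(96, 100, 90))
  expect_equal(ox2$venous, rep(sp$SvO2_n, 3))
})
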