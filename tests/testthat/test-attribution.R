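test_that("cross-correlation peaks at zero lag for a series with itself", {
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(300), rep(1, 10), sides = 1))[10:300]
  r <- cross_correlate(x, x, max_lag = 150)
  expect_equal(r$max_corr, 1, tolerance = 1e-10)
  expect_equal(r$lag_at_max, 0)
  expect_equal(r$pearson, 1, tolerance = 1e-10)
  expect_true(all(abs(r$ccf) <= 1 + 1e-12))
})

test_that("cross-correlation recovers a constructed delay", {
  t <- 0:499
  x <- sin(2 * pi * t / 100)
  y <- sin(2 * pi * (t - 30) / 100) # copy delayed by 30 s
  r <- cross_correlate(x, y, max_lag = 150)
  expect_equal(r$lag_at_max, 30)
  # the (n-denominator) normalisation attenuates finite-series
  # correlations at non-zero lags, so the peak sits slightly below 1
  expect_gt(r$max_corr, 0.9)
})

test_that("white-noise pairs have small maximum cross-correlation", {
  set.seed(99)
  for (i in 1:5) {
    r <- cross_correlate(rnorm(200), rnorm(200), max_lag = 150)
    expect_lt(abs(r$max_corr), 0.3)
  }
})

test_that("min-max rescaling maps exactly onto the measured range", {
  set.seed(2)
  measured <- cumsum(rnorm(100))
  model <- rnorm(100, sd = 4)
  out <- rescale_to_range(model, measured)
  expect_equal(min(out), min(measured))
  expect_equal(max(out), max(measured))

  # affine invariance: a scaled copy of the measurement maps onto it exactly
  expect_equal(rescale_to_range(2 * measured, measured), measured)
  # near-identity when already in range (endpoints match exactly)
  inrange <- rescale_to_range(measured, measured)
  expect_equal(inrange, measured)

  expect_error(rescale_to_range(model, rep(1, 100)), "constant")
  expect_error(rescale_to_range(rep(1, 100), measured), "constant")
})

test_that("identical series warp and distance are exactly zero", {
  set.seed(3)
  x <- cumsum(rnorm(50))
  r <- dtw_compare(x, x)
  expect_identical(r$W, 0)
  expect_identical(r$D, 0)
  expect_identical(r$index_query, r$index_reference)
})

test_that("a shifted step aligns with warping but negligible distance", {
  x <- c(rep(0, 9), rep(1, 21))
  y <- c(rep(0, 14), rep(1, 16))
  r <- dtw_compare(x, y)
  expect_gt(r$W, 0)
  expect_equal(r$D, 0)
  expect_equal(r$D, dtw_oracle_D(x, y))
})

test_that("DTW distance matches the brute-force oracle exactly", {
  set.seed(21)
  for (i in 1:30) {
    x <- rnorm(20)
    y <- rnorm(sample(10:20, 1))
    expect_identical(dtw_compare(x, y)$D, dtw_oracle_D(x, y))
  }
})

test_that("a diagonal optimal path gives the unwarped accumulated distance", {
  set.seed(4)
  x <- sort(rnorm(25))
  r <- dtw_compare(x, x + 1e-3)
  # monotone series with a tiny offset: the diagonal is optimal
  expect_identical(r$index_query, r$index_reference)
  expect_equal(r$D, sum(abs(x - (x + 1e-3))), tolerance = 1e-12)
  # and in general D never exceeds the feasible diagonal cost
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    expect_lte(dtw_compare(a, b)$D, sum(abs(a - b)))
  }
})

test_that("noiseless mixtures are recovered to numerical precision", {
  m <- test_model()
  sim <- run_simulation(build_step_protocol(c("u", "Flux_y")), m)
  cer <- data.frame(dHbO2 = sim$signals$dHbO2_cerebral,
                    dHHb = sim$signals$dHHb_cerebral)
  sca <- data.frame(dHbO2 = sim$scalp_variants$flux$dHbO2,
                    dHHb = sim$scalp_variants$flux$dHHb)
  meas <- data.frame(dHbO2 = 0.3 * sca$dHbO2 + 0.7 * cer$dHbO2,
                     dHHb = 0.3 * sca$dHHb + 0.7 * cer$dHHb)
  fit <- attribute_compartments(meas, cer, sca)
  expect_equal(fit$S, 0.3, tolerance = 1e-6)
  expect_equal(fit$C, 0.7, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-6 * sqrt(sum(meas$dHbO2^2 + meas$dHHb^2)))
})

test_that("boundary solutions activate the non-negativity constraint", {
  set.seed(8)
  n <- 100
  sca <- data.frame(dHbO2 = sin(1:n / 5), dHHb = cos(1:n / 7))
  cer <- data.frame(dHbO2 = sin(1:n / 11), dHHb = cos(1:n / 3))

  fit <- attribute_compartments(sca, cer, sca) # measured = scalp only
  expect_equal(fit$S, 1, tolerance = 1e-6)
  expect_equal(fit$C, 0, tolerance = 1e-6)

  neg <- data.frame(dHbO2 = -sca$dHbO2, dHHb = -sca$dHHb)
  fit2 <- attribute_compartments(neg, cer, sca)
  expect_equal(fit2$S, 0, tolerance = 1e-6)
  # residual cannot beat the norm of the (unfittable) measurement by much
  expect_gte(fit2$residual,
             0.9 * sqrt(sum(neg$dHbO2^2 + neg$dHHb^2)) *
               sqrt(1 - stats::cor(c(neg$dHbO2, neg$dHHb),
                                   c(cer$dHbO2, cer$dHHb))^2))

  expect_error(attribute_compartments(sca, cer,
                                      data.frame(dHbO2 = rep(0, n),
                                                 dHHb = rep(0, n))),
               "zero-norm")
  expect_error(attribute_compartments(
    sca, data.frame(dHbO2 = 2 * sca$dHbO2, dHHb = 2 * sca$dHHb), sca),
    "collinear")
})

test_that("two-compartment residual never exceeds the best single fit", {
  set.seed(31)
  for (i in 1:20) {
    n <- 60
    cer <- data.frame(dHbO2 = cumsum(rnorm(n)), dHHb = cumsum(rnorm(n)))
    sca <- data.frame(dHbO2 = cumsum(rnorm(n)), dHHb = cumsum(rnorm(n)))
    meas <- data.frame(dHbO2 = cumsum(rnorm(n)), dHHb = cumsum(rnorm(n)))
    fit <- attribute_compartments(meas, cer, sca)
    expect_lte(fit$residual,
               min(fit$residual_scalp_only, fit$residual_cerebral_only) + 1e-8)
  }
})

test_that("weight recovery is unbiased under noise and improves with n", {
  set.seed(77)
  w_true <- c(S = 0.4, C = 0.6)
  base <- function(n) {
    list(cer = data.frame(dHbO2 = sin(1:n / 9), dHHb = -0.4 * sin(1:n / 9.5)),
         sca = data.frame(dHbO2 = cos(1:n / 4), dHHb = 0.3 * cos(1:n / 4.2)))
  }
  run <- function(n, reps) {
    b <- base(n)
    rng <- diff(range(w_true["S"] * b$sca$dHbO2 + w_true["C"] * b$cer$dHbO2))
    sapply(seq_len(reps), function(i) {
      meas <- data.frame(
        dHbO2 = w_true["S"] * b$sca$dHbO2 + w_true["C"] * b$cer$dHbO2 +
          rnorm(n, 0, 0.1 * rng),
        dHHb = w_true["S"] * b$sca$dHHb + w_true["C"] * b$cer$dHHb +
          rnorm(n, 0, 0.1 * rng))
      fit <- attribute_compartments(meas, b$cer, b$sca)
      c(fit$S, fit$C)
    })
  }
  r200 <- run(200, 100)
  bias <- rowMeans(r200) - w_true
  se <- apply(r200, 1, stats::sd) / sqrt(ncol(r200))
  expect_true(all(abs(bias) < 3.5 * se + 1e-3))

  r800 <- run(800, 40)
  rmse <- function(r) sqrt(mean((r - w_true)^2))
  expect_lt(rmse(r800), rmse(r200))
})
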