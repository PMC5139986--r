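#' Cross-correlation between measured and modelled series
#'
#' Normalised cross-correlation over lags up to `max_lag` seconds (default
#' 2.5 min), both series demeaned internally. A positive reported lag
#' means the modelled series is delayed relative to the measured one. The
#' lag-0 value is the Pearson correlation coefficient.
#'
#' @param measured,modelled Equal-length, equally-sampled numeric series.
#' @param max_lag Maximum lag (s).
#' @param dt Sampling interval (s).
#' @return List of class `ccf_result`: `lags` (s), `ccf`, `max_corr`,
#'   `lag_at_max` (s), `pearson`.
#' @export
cross_correlate <- function(measured, modelled, max_lag = 150, dt = 1) {
  stopifnot(length(measured) == length(modelled))
  k <- min(floor(max_lag / dt), length(measured) - 1)
  cc <- stats::ccf(modelled, measured, lag.max = k, plot = FALSE,
                   demean = TRUE)
  lags <- drop(cc$lag) * dt
  vals <- drop(cc$acf)
  i <- which.max(vals)
  structure(list(lags = lags, ccf = vals,
                 max_corr = vals[i], lag_at_max = lags[i],
                 pearson = vals[lags == 0]),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> max r = %.3f at lag %g s (Pearson r = %.3f)\n",
              x$max_corr, x$lag_at_max, x$pearson))
  invisible(x)
}

#' Rescale a modelled series into the range of a measurement
#'
#' Affine min--max mapping so that the rescaled series spans exactly
#' `[min(measured), max(measured)]`; used to put modelled and measured
#' signals on an equal footing before dynamic time warping, which (unlike
#' correlation) is scale-sensitive.
#'
#' @param model Modelled series (must be non-constant).
#' @param measured Measured series (must be non-constant).
#' @return The rescaled model series.
#' @export
rescale_to_range <- function(model, measured) {
  rm_ <- range(measured)
  if (diff(rm_) == 0) stop("rescale_to_range: measured series is constant",
                           call. = FALSE)
  rmod <- range(model)
  if (diff(rmod) == 0) stop("rescale_to_range: model series is constant",
                            call. = FALSE)
  (model - rmod[1]) / diff(rmod) * diff(rm_) + rm_[1]
}

#' Dynamic time warping comparison
#'
#' Aligns two series with classic dynamic programming (symmetric steps:
#' diagonal, vertical, horizontal; local cost = absolute difference; no
#' global window; closed-end alignment of both endpoints). Two summary
#' metrics are reported: the degree of warping `W`, the mean absolute
#' difference between the two alignment index vectors (in samples), and
#' the final accumulated distance `D`. Both are non-negative and both are
#' zero iff the optimal alignment is a perfect diagonal match.
#'
#' @param measured Query series (non-empty).
#' @param modelled Reference series (non-empty; rescale first with
#'   [rescale_to_range()] when scales differ).
#' @return List of class `dtw_result`: `index_query`, `index_reference`
#'   (the warping path), `W`, `D`.
#' @export
dtw_compare <- function(measured, modelled) {
  n <- length(measured); m <- length(modelled)
  stopifnot(n > 0, m > 0)
  cost <- abs(outer(measured, modelled, "-"))
  g <- matrix(Inf, n, m)
  g[1, 1] <- cost[1, 1]
  # plain double additions (not cumsum) keep the accumulation order
  # identical to the textbook recursion
  for (j in seq_len(m)[-1]) g[1, j] <- cost[1, j] + g[1, j - 1]
  for (i in seq_len(n)[-1]) g[i, 1] <- cost[i, 1] + g[i - 1, 1]
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(m)[-1]) {
      g[i, j] <- cost[i, j] + min(g[i - 1, j - 1], g[i - 1, j], g[i, j - 1])
    }
  }
  # backtrack, preferring the diagonal on ties
  i <- n; j <- m
  qi <- i; rj <- j
  while (i > 1 || j > 1) {
    if (i == 1) {
      j <- j - 1
    } else if (j == 1) {
      i <- i - 1
    } else {
      cand <- c(g[i - 1, j - 1], g[i - 1, j], g[i, j - 1])
      k <- which.min(cand)
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) i <- i - 1
      else j <- j - 1
    }
    qi <- c(i, qi); rj <- c(j, rj)
  }
  structure(list(index_query = qi, index_reference = rj,
                 W = mean(abs(qi - rj)), D = g[n, m]),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> W = %.3f samples, D = %.4f (path length %d)\n",
              x$W, x$D, length(x$index_query)))
  invisible(x)
}

#' Attribute a measurement between the scalp and cerebral compartments
#'
#' Fits the measured haemoglobin signals as a non-negative weighted sum of
#' the modelled compartment signals, with a single weight pair (S, C)
#' shared by the HbO2 and HHb channels (assuming both are contaminated by
#' scalp to the same degree): minimises the Euclidean error over the
#' concatenated channels subject to S, C >= 0 (box-constrained L-BFGS-B,
#' started from the clipped unconstrained least-squares solution plus the
#' single-compartment solutions). Deterministic.
#'
#' @param measured Data frame (or list) with `dHbO2` and `dHHb`.
#' @param cerebral,scalp Modelled compartment signals, same format and
#'   length, aligned with the measurement.
#' @return List of class `attribution_result`: `S` (scalp weight), `C`
#'   (cerebral weight), `fitted` (data frame `dHbO2`, `dHHb`), `residual`
#'   (Euclidean norm of the misfit), `residual_scalp_only`,
#'   `residual_cerebral_only`.
#' @export
attribute_compartments <- function(measured, cerebral, scalp) {
  y <- c(measured$dHbO2, measured$dHHb)
  a_s <- c(scalp$dHbO2, scalp$dHHb)
  a_c <- c(cerebral$dHbO2, cerebral$dHHb)
  if (length(a_s) != length(y) || length(a_c) != length(y)) {
    stop("attribute_compartments: series are not aligned", call. = FALSE)
  }
  ns <- sum(a_s^2); nc <- sum(a_c^2)
  if (ns == 0 || nc == 0) {
    stop("attribute_compartments: degenerate (zero-norm) model signal",
         call. = FALSE)
  }
  rho <- sum(a_s * a_c) / sqrt(ns * nc)
  if (abs(rho) > 1 - 1e-10) {
    stop("attribute_compartments: degenerate (collinear) model signals",
         call. = FALSE)
  }
  sse <- function(w) sum((y - w[1] * a_s - w[2] * a_c)^2)
  # closed-form single-compartment optima and clipped unconstrained start
  w_s1 <- max(0, sum(y * a_s) / ns)
  w_c1 <- max(0, sum(y * a_c) / nc)
  A <- cbind(a_s, a_c)
  w_ls <- pmax(0, drop(solve(crossprod(A), crossprod(A, y))))
  starts <- list(w_ls, c(w_s1, 0), c(0, w_c1))
  fits <- lapply(starts, function(w0) {
    stats::optim(w0, sse, method = "L-BFGS-B", lower = c(0, 0))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  w <- best$par
  structure(list(
    S = w[1], C = w[2],
    fitted = data.frame(
      dHbO2 = w[1] * scalp$dHbO2 + w[2] * cerebral$dHbO2,
      dHHb = w[1] * scalp$dHHb + w[2] * cerebral$dHHb
    ),
    residual = sqrt(best$value),
    residual_scalp_only = sqrt(sse(c(w_s1, 0))),
    residual_cerebral_only = sqrt(sse(c(0, w_c1)))
  ), class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> S = %.3f, C = %.3f, residual = %.4f\n",
              x$S, x$C, x$residual))
  invisible(x)
}
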