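#' Seeded differential-evolution optimiser
#'
#' Minimal population-based global minimiser (DE/rand/1/bin) used by the
#' false-positive/false-negative scenario search. Box-constrained;
#' reproducible under a fixed seed.
#'
#' @param fn Objective, a function of a numeric vector.
#' @param lower,upper Bounds (equal length).
#' @param seed Integer seed.
#' @param pop Population size (default `max(15, 10 * d)` capped at 40).
#' @param gens Number of generations.
#' @param F Differential weight.
#' @param CR Crossover probability.
#' @return List with `par`, `value` and `evals`.
#' @export
de_optimise <- function(fn, lower, upper, seed = 1, pop = NULL, gens = 40,
                        F = 0.8, CR = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  if (is.null(pop)) pop <- min(max(15, 10 * d), 40)
  set.seed(seed)
  X <- matrix(stats::runif(pop * d, lower, upper), nrow = pop, byrow = TRUE)
  # include the mid-point so the baseline neighbourhood is always sampled
  X[1, ] <- (lower + upper) / 2
  val <- apply(X, 1, fn)
  evals <- pop
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3)
      donor <- X[idx[1], ] + F * (X[idx[2], ] - X[idx[3], ])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, donor, X[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      v <- fn(trial)
      evals <- evals + 1
      if (v <= val[i]) {
        X[i, ] <- trial
        val[i] <- v
      }
    }
  }
  best <- which.min(val)
  list(par = X[best, ], value = val[best], evals = evals)
}
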