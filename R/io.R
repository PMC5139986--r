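#' Read a systemic input time series from CSV
#'
#' Expects a header row with a `t` column (seconds, strictly increasing)
#' and any subset of the input columns `Pa`, `PaCO2`, `SaO2`, `u`,
#' `Flux_y`. Missing inputs are filled with their baseline values (and a
#' message is emitted); unknown columns are an error.
#'
#' @param path CSV file path.
#' @param config Configuration (for baselines).
#' @return An input timeline data frame.
#' @export
read_timeseries_csv <- function(path, config = default_config()) {
  df <- utils::read.csv(path)
  if (!"t" %in% names(df)) {
    stop("read_timeseries_csv: no 't' column in ", path, call. = FALSE)
  }
  if (any(diff(df$t) <= 0)) {
    stop("read_timeseries_csv: time column is not strictly increasing",
         call. = FALSE)
  }
  unknown <- setdiff(names(df), c("t", input_names))
  if (length(unknown) > 0) {
    stop("read_timeseries_csv: unknown columns: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(input_names, names(df))
  if (length(missing) > 0) {
    message("read_timeseries_csv: filling ",
            paste(missing, collapse = ", "), " with baseline values")
    for (nm in missing) df[[nm]] <- config$baseline[[nm]]
  }
  df <- df[, c("t", input_names)]
  # read.csv infers integer for integer-valued columns; keep doubles so a
  # write/read round trip is type-stable
  for (nm in names(df)) df[[nm]] <- as.numeric(df[[nm]])
  attr(df, "protocol") <- basename(path)
  df
}

#' Write a time series to CSV at full precision
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces doubles exactly.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_timeseries_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], function(v) formatC(v, digits = 17,
                                                         format = "g"),
                          character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fixture_names <- c("step_Pa", "step_PaCO2", "step_SaO2", "step_u",
                   "step_flux", "multifreq", "noisy_mixture")

#' Generate a deterministic test fixture
#'
#' Writes an input protocol CSV (and, for `noisy_mixture`, a measured
#' signal CSV plus a JSON manifest with the true mixing weights) into
#' `dir`. All fixtures are reproducible bit-for-bit from the seed.
#'
#' @param name One of `step_Pa`, `step_PaCO2`, `step_SaO2`, `step_u`,
#'   `step_flux`, `multifreq`, `noisy_mixture`.
#' @param seed Integer seed (only `noisy_mixture` uses randomness).
#' @param dir Output directory.
#' @param config Configuration.
#' @return (Invisibly) a list of the files written and, for
#'   `noisy_mixture`, the manifest.
#' @export
generate_fixture <- function(name, seed = 1, dir = tempdir(),
                             config = default_config()) {
  name <- match.arg(name, fixture_names)
  files <- character(0)
  manifest <- NULL
  if (startsWith(name, "step")) {
    var <- sub("step_", "", name)
    if (var == "flux") var <- "Flux_y"
    tl <- build_step_protocol(var, config = config)
    f <- file.path(dir, paste0(name, ".csv"))
    write_timeseries_csv(tl, f)
    files <- f
  } else if (name == "multifreq") {
    tl <- build_multifrequency_protocol(config = config)
    f <- file.path(dir, "multifreq.csv")
    write_timeseries_csv(tl, f)
    files <- f
  } else { # noisy_mixture
    model <- build_model(config)
    tl <- build_step_protocol(c("u", "Flux_y"), config = config)
    sim <- run_simulation(tl, model)
    cer <- sim$signals[, c("t", "dHbO2_cerebral", "dHHb_cerebral")]
    sca <- data.frame(t = sim$time,
                      dHbO2_scalp = sim$scalp_variants$flux$dHbO2,
                      dHHb_scalp = sim$scalp_variants$flux$dHHb)
    set.seed(seed)
    w <- list(w_scalp = round(stats::runif(1, 0.2, 0.8), 3),
              w_cerebral = round(stats::runif(1, 0.2, 0.8), 3))
    noise_sd <- 0.1 * diff(range(cer$dHbO2_cerebral))
    meas <- data.frame(
      t = sim$time,
      dHbO2 = w$w_scalp * sca$dHbO2_scalp + w$w_cerebral * cer$dHbO2_cerebral +
        stats::rnorm(length(sim$time), 0, noise_sd),
      dHHb = w$w_scalp * sca$dHHb_scalp + w$w_cerebral * cer$dHHb_cerebral +
        stats::rnorm(length(sim$time), 0, noise_sd)
    )
    f1 <- file.path(dir, "noisy_mixture_inputs.csv")
    f2 <- file.path(dir, "noisy_mixture_measured.csv")
    f3 <- file.path(dir, "noisy_mixture_models.csv")
    f4 <- file.path(dir, "noisy_mixture_manifest.json")
    write_timeseries_csv(tl, f1)
    write_timeseries_csv(meas, f2)
    write_timeseries_csv(cbind(cer, sca[, -1]), f3)
    manifest <- list(name = name, seed = seed, weights = w,
                     noise_sd = noise_sd)
    jsonlite::write_json(manifest, f4, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2, f3, f4)
  }
  invisible(list(files = files, manifest = manifest))
}
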