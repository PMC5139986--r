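# The default calibrated model is deterministic; build it once per session.
.test_env <- new.env()

test_model <- function() {
  if (is.null(.test_env$model)) .test_env$model <- build_model()
  .test_env$model
}

# one-variable step steady state under default calibration
ss_step <- function(...) {
  cerebral_steady_state(list(...), test_model()$cerebral)
}
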