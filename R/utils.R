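# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and tests) can dispatch on failure mode.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "arsmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(ok, msg, class = "arsmr_validation_error") {
  if (!isTRUE(ok)) abort(msg, class)
  invisible(TRUE)
}

# Deterministic seed stream: derive per-stage seeds from one master seed,
# keeping everything below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483587L
}

expit <- stats::plogis

METABOLITES <- c("iAs", "MMA", "DMA")
SPIRO_MEASURES <- c("fev1", "fvc", "ratio", "pef")
DEFAULT_TRAITS <- c("lifetime_asthma", "current_asthma", "past_asthma",
                    "fev1_lln", "fvc_lln", "ratio_lln", "pef_lln")
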