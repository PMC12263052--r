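# Classed conditions so callers (and the CLI) can distinguish configuration
# mistakes from data problems. All inherit from "mrchainError".

.mrError <- function(msg, class, data = NULL) {
  stop(errorCondition(msg, class = c(class, "mrchainError", "error"),
                      data = data))
}

.mrWarning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "mrchainWarning", "warning")))
}

# config-type errors exit the CLI with status 2, data-type with 3
.CONFIG_ERRORS <- c("mrConfigError")
.DATA_ERRORS <- c("mrEmptyInputError", "mrEmptyOverlapError",
                  "mrDegenerateInstrumentError",
                  "mrInsufficientInstrumentsError", "mrCollinearityError",
                  "mrNoInstrumentsError", "mrPairingError", "mrIOError",
                  "mrMissingEstimateError")

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
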