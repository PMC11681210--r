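# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish bad parameters, bad data, bad shapes, bad configs and I/O.

ts_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "thromboseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_param  <- function(msg) ts_stop(msg, "ts_parameter_error")
stop_valid  <- function(msg) ts_stop(msg, "ts_validation_error")
stop_shape  <- function(msg) ts_stop(msg, "ts_shape_error")
stop_config <- function(msg) ts_stop(msg, "ts_config_error")
stop_io     <- function(msg) ts_stop(msg, "ts_io_error")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state so
# generators stay pure functions of (spec, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
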