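# Classed conditions so callers and tests can distinguish failure modes.

erad_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "erad_error"), call = call))
}

erad_schema_error    <- function(msg) erad_abort(msg, "erad_schema_error")
erad_value_error     <- function(msg) erad_abort(msg, "erad_value_error")
erad_integrity_error <- function(msg) erad_abort(msg, "erad_integrity_error")
erad_config_error    <- function(msg) erad_abort(msg, "erad_config_error")
erad_training_error  <- function(msg) erad_abort(msg, "erad_training_error")
erad_reference_error <- function(msg) erad_abort(msg, "erad_reference_error")
erad_stage_error     <- function(msg) erad_abort(msg, "erad_stage_error")
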