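# Condition helpers. Every condition carries class "ampholyte_error" plus a
# specific subclass so callers (and solve_pi_batch) can dispatch on the cause.

abort_validation <- function(message, ...) {
  abort(message, class = c("ampholyte_error_validation", "ampholyte_error"), ...)
}

abort_lookup <- function(message, ...) {
  abort(message, class = c("ampholyte_error_lookup", "ampholyte_error"), ...)
}

abort_parse <- function(message, ...) {
  abort(message, class = c("ampholyte_error_parse", "ampholyte_error"), ...)
}

abort_no_pi <- function(message, ...) {
  abort(message,
        class = c("ampholyte_error_no_isoelectric_point", "ampholyte_error"),
        ...)
}

abort_not_applicable <- function(message, ...) {
  abort(message,
        class = c("ampholyte_error_not_applicable", "ampholyte_error"), ...)
}

abort_convergence <- function(message, ...) {
  abort(message,
        class = c("ampholyte_error_convergence", "ampholyte_error"), ...)
}

# Map a caught condition to the failure_reason enum of prediction records.
failure_reason_of <- function(cnd) {
  if (inherits(cnd, "ampholyte_error_no_isoelectric_point")) {
    "no_isoelectric_point"
  } else if (inherits(cnd, "ampholyte_error_not_applicable")) {
    "not_applicable"
  } else {
    "invalid_sequence"
  }
}
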