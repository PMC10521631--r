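# Classed conditions so callers can distinguish contract violations
# (format/domain/fit/alignment/...) from ordinary R errors.

stop_pepccs <- function(subclass, msg, ..., data = list()) {
  cond <- structure(
    class = c(subclass, "pepccs_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  for (nm in names(data)) cond[[nm]] <- data[[nm]]
  stop(cond)
}

stop_format    <- function(msg, ...) stop_pepccs("pepccs_format_error", msg, ...)
stop_domain    <- function(msg, ...) stop_pepccs("pepccs_domain_error", msg, ...)
stop_token     <- function(msg, ...) stop_pepccs("pepccs_tokenization_error", msg, ...)
stop_fit       <- function(msg, ...) stop_pepccs("pepccs_fit_error", msg, ...)
stop_alignment <- function(msg, ...) stop_pepccs("pepccs_alignment_error", msg, ...)
stop_predict   <- function(msg, ...) stop_pepccs("pepccs_prediction_error", msg, ...)
stop_config    <- function(msg, ...) stop_pepccs("pepccs_config_error", msg, ...)
stop_io        <- function(msg, ...) stop_pepccs("pepccs_io_error", msg, ...)
stop_train     <- function(msg, ...) stop_pepccs("pepccs_training_error", msg, ...)
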