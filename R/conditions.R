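# Structured conditions so the pipeline (and the CLI wrapper) can map
# failures to stable categories: format (bad file), data (bad values),
# calibration (bad fixture/plane), alignment (stride matching), contract
# (programming error at a module boundary).

fc_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "footclear_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

fc_format_error <- function(message, ...) {
  fc_error("footclear_format_error", message, ...)
}

fc_data_error <- function(message, ...) {
  fc_error("footclear_data_error", message, ...)
}

fc_calibration_error <- function(message, ...) {
  fc_error("footclear_calibration_error", message, ...)
}

fc_alignment_error <- function(message, ...) {
  fc_error("footclear_alignment_error", message, ...)
}

fc_contract_error <- function(message, ...) {
  fc_error("footclear_contract_error", message, ...)
}

#' @noRd
fc_assert <- function(cond, message) {
  if (!isTRUE(cond)) fc_contract_error(message)
  invisible(TRUE)
}
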