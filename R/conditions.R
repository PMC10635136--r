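# Classed conditions so callers (and the CLI) can map failures to exit codes.

abort_invalid <- function(msg, class = "capsid_invalid_input") {
  stop(errorCondition(msg, class = c(class, "capsid_error")))
}

abort_not_t_number <- function(T) {
  abort_invalid(
    sprintf("%s is not a triangulation number: no integer steps (h, k) satisfy h^2 + h*k + k^2 = %s", T, T),
    class = c("capsid_not_t_number", "capsid_invalid_input")
  )
}

abort_no_centered_hexamer <- function(T) {
  abort_invalid(
    sprintf("T = %d is not divisible by 3: the capsid has no hexamer centered on a global 3-fold axis", T),
    class = c("capsid_no_centered_hexamer", "capsid_invalid_input")
  )
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("capsid_io_error", "capsid_error")))
}
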