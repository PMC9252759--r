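# Classed conditions so callers can distinguish failure modes programmatically.
# Every error is c("guidelm_<class>", "guidelm_error", ...).

gl_abort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("guidelm_", class), "guidelm_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

gl_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("guidelm_", class), "guidelm_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}
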