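# Classed conditions so callers can distinguish failure modes programmatically.

dmn_stop <- function(subclass, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("dmnfc_", subclass), "dmnfc_error"),
                      call = call))
}

dmn_assert <- function(cond, subclass, msg) {
  if (!isTRUE(cond)) dmn_stop(subclass, msg, call = sys.call(-1))
  invisible(TRUE)
}
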