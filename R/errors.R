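## Structured condition helpers. Every error raised by the package carries the
## class "biopaxnetError" plus a specific subclass so callers can dispatch.

bpStop <- function(subclass, msg, call. = FALSE) {
  cnd <- structure(
    class = c(subclass, "biopaxnetError", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cnd)
}

bpWarn <- function(subclass, msg) {
  cnd <- structure(
    class = c(subclass, "biopaxnetWarning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cnd)
}
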