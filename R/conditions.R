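# Structured error conditions. Every error raised by the package carries the
# class "g4snp_error" plus one specific subclass so callers (and the CLI) can
# dispatch on failure kind rather than on message text.

g4_abort <- function(class, msg, ..., call. = sys.call(-1L)) {
  cond <- structure(
    class = c(class, "g4snp_error", "error", "condition"),
    list(message = msg, call = call., ...)
  )
  stop(cond)
}

g4_warn <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "g4snp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1L), ...)
  )
  warning(cond)
}
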