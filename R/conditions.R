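# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., ShapeMismatchError = ...) rather than matching messages.

tt_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "twintower_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

tt_assert <- function(cond, class, message) {
  if (!isTRUE(cond)) tt_stop(class, message, call = sys.call(-1))
  invisible(TRUE)
}
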