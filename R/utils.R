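## Internal helpers: classed conditions shared by all modules.

ts_error <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("toposeize_", class), "toposeize_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

ts_warning <- function(class, message, ...) {
  warning(structure(
    class = c(paste0("toposeize_", class), "toposeize_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pad/truncate an ASCII field to a fixed width (EDF headers).
edf_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}
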