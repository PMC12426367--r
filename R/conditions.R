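# Typed conditions.  Degenerate statistics (zero variance, zero mean,
# perfect compensation) are signalled as classed errors carrying a short
# machine-readable `code`, so batch drivers can catch them and record the
# region-year as missing instead of propagating infinities.

fs_condition <- function(message, class, code = NULL, data = NULL) {
  structure(
    class = c(class, "finstab_error", "error", "condition"),
    list(message = message, call = sys.call(-2), code = code, data = data)
  )
}

stop_validation <- function(message, code = "invalid", data = NULL) {
  stop(fs_condition(message, "finstab_validation_error", code, data))
}

stop_degenerate <- function(message, code, data = NULL) {
  stop(fs_condition(message, "finstab_degeneracy_error", code, data))
}

condition_code <- function(cond) {
  if (inherits(cond, "finstab_error")) cond$code else NA_character_
}

fs_log <- function(...) {
  if (isTRUE(getOption("finstab.verbose", TRUE))) message(...)
  invisible(NULL)
}
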