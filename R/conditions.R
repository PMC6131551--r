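# Classed conditions so callers and tests can discriminate failure modes.

bdb_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "bdb_error"), call = call))
}

bdb_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "bdb_warning")))
}

# numeric scalar check used by constructors
chk_num <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    bdb_stop(sprintf("'%s' must be a finite numeric scalar", name),
             "bdb_invalid_spec")
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    bdb_stop(sprintf("'%s' = %g is outside the valid range %s%g, %g%s",
                     name, x, if (strict) "(" else "[", lower, upper,
                     if (strict) ")" else "]"),
             "bdb_invalid_spec")
  invisible(x)
}
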