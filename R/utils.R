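# shared internal helpers

# round half away from zero; base round() uses banker's rounding, which
# would make normalised counts depend on parity of the digit before .5
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assertProportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single number in [0, 1]", name)
  invisible(x)
}

.assertPositive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) .stopf("'%s' must be a single %s number", name,
                  if (strict) "positive" else "non-negative")
  invisible(x)
}
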