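# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with call.=FALSE and sprintf semantics
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# column key used in ASV tables: "<treatment>_<fraction_number>"
fraction_key <- function(treatment, fraction_number) {
  paste(treatment, fraction_number, sep = "_")
}
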