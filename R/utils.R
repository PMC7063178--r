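# Internal helpers: structured error conditions and small utilities.

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "erins_error")))
}

validation_error <- function(msg, ...) abort(msg, "erins_validation_error", ...)
lookup_error     <- function(msg, ...) abort(msg, "erins_lookup_error", ...)
config_error     <- function(msg, ...) abort(msg, "erins_config_error", ...)
numerical_error  <- function(msg, ...) abort(msg, "erins_numerical_error", ...)
integration_error <- function(msg, ...) abort(msg, "erins_integration_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# collapse a character vector for messages
cstr <- function(x) paste(x, collapse = ", ")
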