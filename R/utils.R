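# Condition helpers: every user-facing error carries a paeseg_* class so
# callers (and the CLI) can branch on failure modes.

abort_paeseg <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "paeseg_error"), ...)
}

stop_parse <- function(message, ...) abort_paeseg(message, "paeseg_parse_error", ...)
stop_shape <- function(message, ...) abort_paeseg(message, "paeseg_shape_error", ...)
stop_domain <- function(message, ...) abort_paeseg(message, "paeseg_domain_error", ...)
stop_dialect <- function(message, ...) abort_paeseg(message, "paeseg_dialect_error", ...)
stop_format <- function(message, ...) abort_paeseg(message, "paeseg_format_error", ...)
stop_reconcile <- function(message, ...) abort_paeseg(message, "paeseg_reconcile_error", ...)
stop_config <- function(message, ...) abort_paeseg(message, "paeseg_config_error", ...)
stop_generate <- function(message, ...) abort_paeseg(message, "paeseg_generate_error", ...)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
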