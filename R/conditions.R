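# classed conditions so callers (and the CLI) can react to error kinds

#' @keywords internal
fk_stop <- function(class, msg, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "fk_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

fk_usage_error       <- function(msg) fk_stop("fk_usage_error", msg)
fk_lookup_error      <- function(msg) fk_stop("fk_lookup_error", msg)
fk_bound_error       <- function(msg) fk_stop("fk_bound_error", msg)
fk_syntax_error      <- function(msg) fk_stop("fk_syntax_error", msg)
fk_format_error      <- function(msg) fk_stop("fk_format_error", msg)
fk_identifier_error  <- function(msg) fk_stop("fk_identifier_conflict", msg)
fk_capability_error  <- function(msg) fk_stop("fk_capability_error", msg)
fk_dimension_error   <- function(msg) fk_stop("fk_dimension_error", msg)
fk_index_error       <- function(msg) fk_stop("fk_index_error", msg)
fk_registry_error    <- function(msg) fk_stop("fk_registry_error", msg)
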