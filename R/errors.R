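# Classed conditions so callers (and the CLI) can distinguish failure modes.

ft_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ft_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ft_structural_error <- function(msg) ft_error(msg, "ft_structural_error")
ft_timing_error     <- function(msg) ft_error(msg, "ft_timing_error")
ft_usage_error      <- function(msg) ft_error(msg, "ft_usage_error")
ft_domain_error     <- function(msg) ft_error(msg, "ft_domain_error")
ft_schema_error     <- function(msg) ft_error(msg, "ft_schema_error")
ft_parse_error      <- function(msg) ft_error(msg, "ft_parse_error")
ft_validation_error <- function(msg) ft_error(msg, "ft_validation_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
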