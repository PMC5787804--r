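# Condition helpers. Three classes map onto CLI exit codes:
#   dfspec_input_error   -> 2  (bad files, bad configuration, empty inputs)
#   dfspec_domain_error  -> 2  (argument outside a function's domain)
#   dfspec_numeric_error -> 3  (non-convergence, model violation)

stop_input <- function(msg, ...) {
  stop(structure(
    class = c("dfspec_input_error", "dfspec_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_domain <- function(msg, ...) {
  stop(structure(
    class = c("dfspec_domain_error", "dfspec_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_numeric <- function(msg, ...) {
  stop(structure(
    class = c("dfspec_numeric_error", "dfspec_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain("`%s` must be a single finite positive number", name)
  invisible(x)
}
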