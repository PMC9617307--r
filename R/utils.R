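# Internal helpers: classed error conditions and seed bookkeeping.

#' @noRd
mrlap_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mrlap_error"), call = call))
}

#' @noRd
mrlap_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "mrlap_warning")))
}

# Derive a per-case child seed from a master seed.  Kept below 2^31 so the
# value is always a valid R integer seed.
#' @noRd
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + as.numeric(i) * 104729) %% 2147483647L)
}

#' @noRd
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @noRd
stopifnot_scalar <- function(x, name, class = "mrlap_domain_error") {
  if (!is_scalar_number(x)) {
    mrlap_error(sprintf("`%s` must be a single finite number", name), class)
  }
  invisible(x)
}
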