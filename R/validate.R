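# Internal argument checking shared by all user-facing functions.
# All probabilities are decimals in [0,1]; percentages are rejected loudly so
# 0.95 can never be confused with 95.

check_probability <- function(x, name, lo = 0, hi = 1,
                              lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    rlang::abort(sprintf("`%s` must be a numeric probability with no NA.", name),
                 class = "seqppv_argument_error")
  }
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!all(lo_ok & hi_ok)) {
    rlang::abort(sprintf(
      "`%s` must lie in %s%g, %g%s (a decimal, not a percentage); got %s.",
      name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
      paste(format(x[!(lo_ok & hi_ok)]), collapse = ", ")),
      class = "seqppv_argument_error")
  }
  invisible(x)
}

check_test_characteristics <- function(sensitivity, specificity) {
  check_probability(sensitivity, "sensitivity", lo = 0, hi = 1, lo_open = TRUE)
  check_probability(specificity, "specificity", lo = 0, hi = 1, lo_open = TRUE)
  invisible(NULL)
}

# Recycle scalar arguments against the longest one, erroring on length clashes.
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != n
  if (any(bad)) {
    rlang::abort(sprintf(
      "Arguments %s cannot be recycled to a common length %d.",
      paste0("`", names(args)[bad], "`", collapse = ", "), n),
      class = "seqppv_argument_error")
  }
  lapply(args, rep_len, n)
}

# Equality tolerance for probability comparisons (e.g. a + b = 1 detection).
PROB_TOL <- 1e-12
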