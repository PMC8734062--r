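# Independent oracles used to freeze expected values. All are written in plain
# arithmetic, deliberately avoiding the package's log-odds code paths.

# One Bayes step from the definition of conditional probability.
oracle_update_once <- function(a, b, prior, positive = TRUE) {
  if (positive) {
    num <- a * prior
    den <- a * prior + (1 - b) * (1 - prior)
  } else {
    num <- (1 - a) * prior
    den <- (1 - a) * prior + b * (1 - prior)
  }
  num / den
}

# n-fold composition of single-step updating (chained posteriors).
oracle_sequential <- function(a, b, phi, n) {
  p <- phi
  for (i in seq_len(n)) p <- oracle_update_once(a, b, p, positive = TRUE)
  p
}

# Exhaustive enumeration over disease states for a mixed outcome sequence.
oracle_enumeration <- function(a, b, phi, outcomes_positive) {
  lik_d <- prod(ifelse(outcomes_positive, a, 1 - a))
  lik_nd <- prod(ifelse(outcomes_positive, 1 - b, b))
  lik_d * phi / (lik_d * phi + lik_nd * (1 - phi))
}

# Direct-formula PPV/NPV and their crossing found by root bisection.
oracle_ppv <- function(a, b, phi) a * phi / (a * phi + (1 - b) * (1 - phi))
oracle_npv <- function(a, b, phi) b * (1 - phi) / ((1 - a) * phi + b * (1 - phi))
oracle_intersection <- function(a, b) {
  stats::uniroot(function(phi) oracle_ppv(a, b, phi) - oracle_npv(a, b, phi),
                 c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# Smallest integer n whose chained posterior meets the target, by scanning.
oracle_required_n <- function(a, b, phi, target, n_max = 10000) {
  p <- phi
  for (n in seq_len(n_max)) {
    p <- oracle_update_once(a, b, p, positive = TRUE)
    if (p >= target) return(n)
  }
  NA_integer_
}

# Direct power-form posterior evaluated at a real-valued n.
oracle_power_form <- function(a, b, phi, n) {
  a^n * phi / (a^n * phi + (1 - b)^n * (1 - phi))
}

halfup2 <- function(x) floor(x * 100 + 0.5) / 100

read_published_table <- function(target) {
  path <- system.file(
    sprintf("extdata/published_iterations_ppv%02.0f.csv", target * 100),
    package = "seqppv")
  read_reference_table(path)
}
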