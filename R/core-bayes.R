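#' Positive predictive value of a screening test
#'
#' The probability of disease given one positive test, as a function of the
#' test's sensitivity \eqn{a}, specificity \eqn{b} and the disease prevalence
#' (or pre-test probability) \eqn{\phi}:
#' \deqn{\rho(\phi) = \frac{a\phi}{a\phi + (1-b)(1-\phi)}.}
#' Because screening populations usually have low prevalence, \eqn{\rho} can be
#' far below the test's sensitivity; it runs from 0 at \eqn{\phi = 0} to 1 at
#' \eqn{\phi = 1}.
#'
#' All arguments are vectorised and recycled against each other.
#'
#' @param sensitivity Probability a diseased subject tests positive, in (0, 1].
#' @param specificity Probability a disease-free subject tests negative, in
#'   (0, 1].
#' @param prevalence Prior probability of disease, in \[0, 1\].
#' @return Numeric vector of positive predictive values in \[0, 1\].
#' @seealso [npv()], [sequential_ppv()], [intersection_prevalence()]
#' @examples
#' ppv(0.9, 0.8, 0.1) # 1/3: two of three positives are false at 10% prevalence
#' @export
ppv <- function(sensitivity, specificity, prevalence) {
  check_test_characteristics(sensitivity, specificity)
  check_probability(prevalence, "prevalence")
  args <- recycle_args(a = sensitivity, b = specificity, phi = prevalence)
  degenerate <- args$b >= 1 - PROB_TOL & args$phi <= 0
  if (any(degenerate)) {
    rlang::abort(
      "PPV is undefined (0/0) when specificity = 1 and prevalence = 0: no positive test can occur.",
      class = "seqppv_undefined_result")
  }
  with(args, a * phi / (a * phi + (1 - b) * (1 - phi)))
}

#' Negative predictive value of a screening test
#'
#' The probability of being disease-free given one negative test:
#' \deqn{\sigma(\phi) = \frac{b(1-\phi)}{(1-a)\phi + b(1-\phi)}.}
#' It runs from 1 at \eqn{\phi = 0} to 0 at \eqn{\phi = 1} and decreases with
#' prevalence, mirroring [ppv()].
#'
#' @inheritParams ppv
#' @return Numeric vector of negative predictive values in \[0, 1\].
#' @examples
#' npv(0.9, 0.8, 0.1) # 72/73
#' @export
npv <- function(sensitivity, specificity, prevalence) {
  check_test_characteristics(sensitivity, specificity)
  check_probability(prevalence, "prevalence")
  args <- recycle_args(a = sensitivity, b = specificity, phi = prevalence)
  degenerate <- args$a >= 1 - PROB_TOL & args$phi >= 1
  if (any(degenerate)) {
    rlang::abort(
      "NPV is undefined (0/0) when sensitivity = 1 and prevalence = 1: no negative test can occur.",
      class = "seqppv_undefined_result")
  }
  with(args, b * (1 - phi) / ((1 - a) * phi + b * (1 - phi)))
}

#' Positive likelihood ratio
#'
#' \eqn{LR^+ = a / (1 - b)}: the factor by which one positive result multiplies
#' the pre-test odds of disease. A ratio near 1 means a positive result barely
#' changes the odds; the larger it is, the fewer repeat tests are needed to
#' reach any target predictive value.
#'
#' @inheritParams ppv
#' @return Numeric vector of positive likelihood ratios (> 0).
#' @examples
#' positive_likelihood_ratio(0.9, 0.8) # 4.5
#' @export
positive_likelihood_ratio <- function(sensitivity, specificity) {
  check_test_characteristics(sensitivity, specificity)
  args <- recycle_args(a = sensitivity, b = specificity)
  if (any(args$b >= 1 - PROB_TOL)) {
    rlang::abort(
      "The positive likelihood ratio is infinite when specificity = 1 (no false positives); supply specificity < 1.",
      class = "seqppv_undefined_result")
  }
  with(args, a / (1 - b))
}

# log LR+ = log(a) - log(1 - b); -Inf/Inf handled by callers.
log_lr_positive <- function(sensitivity, specificity) {
  log(sensitivity) - log1p(-specificity)
}

#' Posterior probability of disease after n consecutive positive tests
#'
#' Bayesian updating with the same test repeated independently: each positive
#' result multiplies the disease odds by \eqn{LR^+ = a/(1-b)}, so after
#' \eqn{n} positives
#' \deqn{\rho_n(\phi) = \frac{a^n\phi}{a^n\phi + (1-b)^n(1-\phi)}.}
#' The value is computed on the log-odds scale,
#' \eqn{\mathrm{logit}(\rho_n) = \mathrm{logit}(\phi) + n\,\ln LR^+}, which is
#' exact and stable for any `n` (no underflow for n well beyond 10^4).
#'
#' As \eqn{n \to \infty} the posterior tends to 1 when \eqn{a > 1-b}, stays at
#' \eqn{\phi} when \eqn{a = 1-b} (an uninformative test), and tends to 0 when
#' \eqn{a < 1-b}; see [convergence_class()].
#'
#' @inheritParams ppv
#' @param n Number of consecutive positive test iterations (integer >= 1).
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @examples
#' sequential_ppv(0.9, 0.8, 0.1, n = 1:4)
#' @export
sequential_ppv <- function(sensitivity, specificity, prevalence, n) {
  check_test_characteristics(sensitivity, specificity)
  check_probability(prevalence, "prevalence")
  if (!is.numeric(n) || anyNA(n) || any(n < 1) || any(n != floor(n))) {
    rlang::abort("`n` must be an integer number of test iterations >= 1.",
                 class = "seqppv_argument_error")
  }
  args <- recycle_args(a = sensitivity, b = specificity, phi = prevalence, n = n)
  out <- with(args, stats::plogis(stats::qlogis(phi) + n * log_lr_positive(a, b)))
  if (anyNA(out)) {
    rlang::abort(
      "Posterior is undefined (0/0): specificity = 1 with prevalence = 0 leaves no probability on an all-positive sequence.",
      class = "seqppv_undefined_result")
  }
  out
}

#' Posterior after an arbitrary sequence of test results
#'
#' Folds Bayes' rule over an ordered record of positive and negative results,
#' using the likelihoods P(+|D) = a, P(+|not D) = 1-b, P(-|D) = 1-a,
#' P(-|not D) = b. Under independent repeats of one test the posterior depends
#' only on the counts of positives and negatives, not on their order. An empty
#' record returns the prior unchanged. Updating for a negative result divides
#' the odds by the negative likelihood ratio \eqn{(1-a)/b}.
#'
#' @inheritParams ppv
#' @param prior Prior probability of disease, in \[0, 1\].
#' @param outcomes Character vector of results, each `"+"`/`"positive"` or
#'   `"-"`/`"negative"`; alternatively a logical vector (`TRUE` = positive).
#'   May be empty.
#' @return A one-row tibble with columns `posterior`, `prior`, `n_positive`,
#'   `n_negative`.
#' @examples
#' posterior_after_sequence(0.9, 0.8, 0.1, c("+", "+"))
#' posterior_after_sequence(0.9, 0.8, 0.1, c("+", "-"))
#' @export
posterior_after_sequence <- function(sensitivity, specificity, prior, outcomes) {
  check_test_characteristics(sensitivity, specificity)
  check_probability(prior, "prior")
  stopifnot(length(sensitivity) == 1, length(specificity) == 1, length(prior) == 1)
  pos <- parse_outcomes(outcomes)
  k_pos <- sum(pos)
  k_neg <- sum(!pos)
  log_odds <- stats::qlogis(prior)
  if (k_pos > 0) log_odds <- log_odds + k_pos * (log(sensitivity) - log1p(-specificity))
  if (k_neg > 0) log_odds <- log_odds + k_neg * (log1p(-sensitivity) - log(specificity))
  posterior <- stats::plogis(log_odds)
  if (is.nan(posterior) || is.nan(log_odds)) {
    rlang::abort(
      "Posterior is undefined (0/0): the observed sequence has probability zero under both disease states.",
      class = "seqppv_undefined_result")
  }
  tibble::tibble(posterior = posterior, prior = prior,
                 n_positive = k_pos, n_negative = k_neg)
}

parse_outcomes <- function(outcomes) {
  if (length(outcomes) == 0) return(logical(0))
  if (is.logical(outcomes)) {
    if (anyNA(outcomes)) rlang::abort("`outcomes` must not contain NA.",
                                      class = "seqppv_argument_error")
    return(outcomes)
  }
  x <- tolower(as.character(outcomes))
  pos <- x %in% c("+", "pos", "positive")
  neg <- x %in% c("-", "neg", "negative")
  if (!all(pos | neg)) {
    rlang::abort("`outcomes` entries must each be \"+\"/\"positive\" or \"-\"/\"negative\".",
                 class = "seqppv_argument_error")
  }
  pos
}

#' Long-run behaviour of repeated positive testing
#'
#' Classifies what the posterior after n consecutive positives converges to as
#' n grows, determined solely by comparing the sensitivity \eqn{a} with the
#' false-positive rate \eqn{1-b}: `"converges_to_one"` when \eqn{a > 1-b}
#' (equivalently \eqn{a+b > 1}, an informative test), `"stays_at_prior"` when
#' \eqn{a = 1-b} (each positive leaves the odds unchanged; equality judged at
#' tolerance 1e-12), and `"converges_to_zero"` when \eqn{a < 1-b} (a test worse
#' than chance, where positives are evidence against disease).
#'
#' @inheritParams ppv
#' @return Character vector with values among `"converges_to_one"`,
#'   `"stays_at_prior"`, `"converges_to_zero"`.
#' @examples
#' convergence_class(0.9, 0.8)
#' convergence_class(0.5, 0.5)
#' @export
convergence_class <- function(sensitivity, specificity) {
  check_test_characteristics(sensitivity, specificity)
  check_probability(specificity, "specificity", hi_open = TRUE, lo_open = TRUE)
  args <- recycle_args(a = sensitivity, b = specificity)
  d <- with(args, a - (1 - b))
  dplyr::case_when(
    abs(d) <= PROB_TOL ~ "stays_at_prior",
    d > 0 ~ "converges_to_one",
    TRUE ~ "converges_to_zero"
  )
}

#' Prevalence at which PPV and NPV cross
#'
#' [ppv()] increases and [npv()] decreases with prevalence, so for any test
#' with 0 < a, b < 1 the two curves cross exactly once, at
#' \deqn{\phi_i = \frac{-b^2 + b - \sqrt{ab\,(ab - a + 1 - b)}}{a^2 - b^2 - a + b}.}
#' Below \eqn{\phi_i} the NPV exceeds the PPV — at low prevalence a negative
#' result is more trustworthy than a positive one. The denominator factors as
#' \eqn{(a-b)(a+b-1)} and vanishes when \eqn{a = b} or \eqn{a + b = 1}; in both
#' cases the curves cross at \eqn{\phi_i = 1/2} by symmetry, and that limit is
#' returned in place of the indeterminate closed form.
#'
#' For clinically useful tests the crossover often sits at mid-range
#' prevalence, but it is not confined there: a = 0.99, b = 0.51 puts it near
#' 0.83.
#'
#' @inheritParams ppv
#' @return Numeric vector of crossover prevalences in (0, 1).
#' @examples
#' intersection_prevalence(0.9, 0.8) # 4/7
#' @export
intersection_prevalence <- function(sensitivity, specificity) {
  check_probability(sensitivity, "sensitivity", lo_open = TRUE, hi_open = TRUE)
  check_probability(specificity, "specificity", lo_open = TRUE, hi_open = TRUE)
  args <- recycle_args(a = sensitivity, b = specificity)
  with(args, {
    denom <- (a - b) * (a + b - 1)
    num <- -b^2 + b - sqrt(a * b * (a * b - a + 1 - b))
    ifelse(abs(denom) <= PROB_TOL, 0.5, num / denom)
  })
}

#' Add Bayesian screening summaries to a table of test scenarios
#'
#' Data-frame-first wrapper over the closed forms: for each row of a table with
#' columns `sensitivity`, `specificity` and `prevalence`, appends the single-test
#' PPV and NPV, the positive likelihood ratio and its log, the long-run
#' convergence class, and the PPV/NPV crossover prevalence.
#'
#' @param data A data frame with numeric columns `sensitivity`, `specificity`,
#'   `prevalence`.
#' @return `data` as a tibble with columns `ppv`, `npv`, `lr_positive`,
#'   `log_lr_positive`, `convergence`, `intersection_prevalence` appended.
#' @examples
#' library(tibble)
#' tibble(sensitivity = 0.9, specificity = 0.8, prevalence = c(0.01, 0.1, 0.5)) |>
#'   predictive_values()
#' @export
predictive_values <- function(data) {
  required <- c("sensitivity", "specificity", "prevalence")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(sprintf("`data` is missing column(s): %s.",
                         paste(missing, collapse = ", ")),
                 class = "seqppv_argument_error")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    ppv = ppv(.data$sensitivity, .data$specificity, .data$prevalence),
    npv = npv(.data$sensitivity, .data$specificity, .data$prevalence),
    lr_positive = positive_likelihood_ratio(.data$sensitivity, .data$specificity),
    log_lr_positive = log(.data$lr_positive),
    convergence = convergence_class(.data$sensitivity, .data$specificity),
    intersection_prevalence = intersection_prevalence(.data$sensitivity, .data$specificity)
  )
}
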