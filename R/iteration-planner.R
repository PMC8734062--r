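#' Continuous number of positive test iterations to reach a target PPV
#'
#' Algebraic inverse of the sequential-updating posterior: the (real-valued)
#' number of consecutive positive results needed for the posterior to reach a
#' target PPV \eqn{\rho} from prevalence \eqn{\phi},
#' \deqn{n = \frac{\ln\!\left[\rho(\phi - 1) / (\phi(\rho - 1))\right]}
#'                {\ln\!\left[a/(1-b)\right]}
#'         = \frac{\mathrm{logit}(\rho) - \mathrm{logit}(\phi)}{\ln LR^+}.}
#' The formula depends on the test only through the positive likelihood ratio,
#' so either `sensitivity`/`specificity` or a direct `log_lr_positive` value
#' may be supplied. The value may be zero (when \eqn{\phi = \rho}) or negative
#' (when \eqn{\phi > \rho}, or for a worse-than-chance test); use
#' [required_iterations()] for the clinically usable integer count and
#' feasibility classification.
#'
#' @param prevalence Prior probability of disease, in (0, 1).
#' @param target Desired positive predictive value, in (0, 1). A target of 1 is
#'   unreachable for any prevalence below 1 and is rejected.
#' @param sensitivity,specificity Test characteristics in (0, 1\]; supply these
#'   or `log_lr_positive`, not both.
#' @param log_lr_positive Natural log of the positive likelihood ratio,
#'   \eqn{\ln[a/(1-b)]}; must be nonzero (a test with \eqn{a + b = 1} carries
#'   no information and never moves the posterior).
#' @return Numeric vector of continuous iteration counts.
#' @examples
#' required_iterations_continuous(0.02, 0.99, log_lr_positive = 0.5) # 16.97...
#' required_iterations_continuous(0.1, 0.95, sensitivity = 0.9, specificity = 0.8)
#' @export
required_iterations_continuous <- function(prevalence, target,
                                           sensitivity = NULL, specificity = NULL,
                                           log_lr_positive = NULL) {
  check_probability(prevalence, "prevalence", lo_open = TRUE, hi_open = TRUE)
  check_target(target)
  llr <- resolve_log_lr(sensitivity, specificity, log_lr_positive)
  if (any(abs(llr) <= PROB_TOL)) {
    rlang::abort(
      "ln(LR+) is zero (sensitivity + specificity = 1): an uninformative test cannot reach any target PPV.",
      class = "seqppv_undefined_result")
  }
  args <- recycle_args(phi = prevalence, rho = target, llr = llr)
  with(args, (stats::qlogis(rho) - stats::qlogis(phi)) / llr)
}

check_target <- function(target) {
  if (!is.numeric(target) || length(target) == 0 || anyNA(target)) {
    rlang::abort("`target` must be a numeric probability.",
                 class = "seqppv_argument_error")
  }
  if (any(target >= 1)) {
    rlang::abort(
      "A target PPV of 1 (or more) is unreachable: no finite number of imperfect tests attains a perfect predictive value unless prevalence is 1.",
      class = "seqppv_argument_error")
  }
  if (any(target <= 0)) {
    rlang::abort("`target` must lie in (0, 1).", class = "seqppv_argument_error")
  }
  invisible(target)
}

resolve_log_lr <- function(sensitivity, specificity, log_lr_positive) {
  have_ab <- !is.null(sensitivity) || !is.null(specificity)
  if (have_ab && !is.null(log_lr_positive)) {
    rlang::abort("Supply either `sensitivity`/`specificity` or `log_lr_positive`, not both.",
                 class = "seqppv_argument_error")
  }
  if (have_ab) {
    if (is.null(sensitivity) || is.null(specificity)) {
      rlang::abort("Both `sensitivity` and `specificity` are required.",
                   class = "seqppv_argument_error")
    }
    check_test_characteristics(sensitivity, specificity)
    check_probability(specificity, "specificity", lo_open = TRUE, hi_open = TRUE)
    return(log_lr_positive(sensitivity, specificity))
  }
  if (is.null(log_lr_positive) || !is.numeric(log_lr_positive) || anyNA(log_lr_positive)) {
    rlang::abort("Supply `sensitivity`/`specificity` or a numeric `log_lr_positive`.",
                 class = "seqppv_argument_error")
  }
  log_lr_positive
}

#' Integer test-iteration requirement with feasibility classification
#'
#' Converts the continuous iteration count into the smallest whole number of
#' consecutive positive, independent tests achieving the target PPV, via the
#' ceiling function: when 2.8 tests are "needed", 3 tests guarantee the target
#' while 2 fall short. Cases where no ceiling applies are classified instead:
#'
#' * `already_satisfied` — prevalence already meets the target; 0 tests needed.
#' * `infeasible_uninformative` — \eqn{a + b = 1} (at tolerance 1e-12); positive
#'   results never move the posterior.
#' * `infeasible_negative` — \eqn{a + b < 1}; positives push the posterior away
#'   from the target, the continuous count is negative.
#' * `unreachable` — prevalence 0; the posterior stays at 0 for any n.
#' * `feasible` — otherwise; `n_i = ceiling(continuous_n) >= 1`, and the
#'   posterior at `n_i` meets the target while at `n_i - 1` it does not.
#'
#' @inheritParams ppv
#' @param prevalence Prior probability of disease, in \[0, 1\].
#' @param target Desired positive predictive value, in (0, 1).
#' @return A tibble of class `"iteration_plan"`, one row per scenario, with
#'   columns `sensitivity`, `specificity`, `prevalence`, `target_ppv`,
#'   `log_lr_positive`, `continuous_n`, `n_i` (integer; `NA` when infeasible),
#'   `feasibility`, and `achieved_ppv` (the posterior after `n_i` positives;
#'   `NA` when infeasible).
#' @examples
#' required_iterations(0.9, 0.8, 0.1, 0.95) # 4 tests
#' required_iterations(0.3, 0.3, 0.1, 0.95) # infeasible: a + b < 1
#' @export
required_iterations <- function(sensitivity, specificity, prevalence, target) {
  check_test_characteristics(sensitivity, specificity)
  check_probability(prevalence, "prevalence")
  check_target(target)
  args <- recycle_args(a = sensitivity, b = specificity,
                       phi = prevalence, rho = target)
  llr <- log_lr_positive(args$a, args$b)

  continuous_n <- ifelse(
    abs(llr) <= PROB_TOL | args$phi <= 0 | args$phi >= 1,
    NA_real_,
    (stats::qlogis(args$rho) - stats::qlogis(args$phi)) / llr
  )
  feasibility <- dplyr::case_when(
    args$phi >= args$rho ~ "already_satisfied",
    args$phi <= 0 ~ "unreachable",
    abs(llr) <= PROB_TOL ~ "infeasible_uninformative",
    args$a + args$b < 1 ~ "infeasible_negative",
    TRUE ~ "feasible"
  )
  n_i <- dplyr::case_when(
    feasibility == "already_satisfied" ~ 0L,
    feasibility == "feasible" ~ as.integer(ceiling(continuous_n)),
    TRUE ~ NA_integer_
  )
  achieved <- rep(NA_real_, length(n_i))
  done <- feasibility == "already_satisfied"
  achieved[done] <- args$phi[done]
  ok <- feasibility == "feasible"
  if (any(ok)) {
    achieved[ok] <- sequential_ppv(args$a[ok], args$b[ok], args$phi[ok], n_i[ok])
  }
  out <- tibble::tibble(
    sensitivity = args$a, specificity = args$b, prevalence = args$phi,
    target_ppv = args$rho, log_lr_positive = llr,
    continuous_n = continuous_n, n_i = n_i,
    feasibility = feasibility, achieved_ppv = achieved
  )
  class(out) <- c("iteration_plan", class(out))
  out
}

#' Plan iteration requirements for a table of scenarios
#'
#' Data-frame-first companion to [required_iterations()]: takes a table with
#' columns `sensitivity`, `specificity`, `prevalence` (and optionally
#' `target_ppv`) and appends the iteration plan columns.
#'
#' @param data A data frame of test scenarios.
#' @param target Target PPV used for rows without a `target_ppv` column.
#' @return A tibble of class `"iteration_plan"`.
#' @examples
#' library(tibble)
#' tibble(sensitivity = 0.9, specificity = 0.8, prevalence = c(0.02, 0.1)) |>
#'   plan_iterations(target = 0.95)
#' @export
plan_iterations <- function(data, target = 0.95) {
  required <- c("sensitivity", "specificity", "prevalence")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(sprintf("`data` is missing column(s): %s.",
                         paste(missing, collapse = ", ")),
                 class = "seqppv_argument_error")
  }
  rho <- if ("target_ppv" %in% names(data)) data$target_ppv else target
  required_iterations(data$sensitivity, data$specificity, data$prevalence, rho)
}

# Display rounding for reference tables: half-up, so 2.005 -> 2.01.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Reference table of iteration counts by ln(LR+) and prevalence
#'
#' Regenerates the reference grids of continuous iteration counts needed to
#' reach a target PPV, keyed by rows of \eqn{\ln LR^+} and columns of
#' prevalence. The defaults reproduce the published grids for targets 0.99,
#' 0.95, 0.75 and 0.50: rows \eqn{\ln LR^+ = 0.5, 1.0, \ldots, 5.0} and
#' prevalences 0.02, 0.05, 0.07, 0.1, 0.15, 0.2. Cells are the continuous
#' counts rounded half-up to 2 decimals; for a whole number of tests apply the
#' ceiling to the continuous value (see [required_iterations()]). Counts
#' decrease along both axes: better tests and higher prevalence need fewer
#' iterations.
#'
#' @param target Target PPV, in (0, 1).
#' @param log_lr_positive Row keys: positive ln(LR+) values.
#' @param prevalence Column keys: prevalences in (0, 1).
#' @return A tibble of class `"reference_table"`: first column
#'   `log_lr_positive`, then one column per prevalence. Attributes `target_ppv`
#'   and `prevalence` carry the metadata.
#' @examples
#' reference_table(0.99)
#' @export
reference_table <- function(target,
                            log_lr_positive = seq(0.5, 5, by = 0.5),
                            prevalence = c(0.02, 0.05, 0.07, 0.1, 0.15, 0.2)) {
  check_target(target)
  stopifnot(length(target) == 1)
  if (length(log_lr_positive) == 0 || length(prevalence) == 0) {
    rlang::abort("Row and column grids must be non-empty.",
                 class = "seqppv_argument_error")
  }
  if (!is.numeric(log_lr_positive) || any(log_lr_positive <= 0)) {
    rlang::abort("`log_lr_positive` row keys must all be positive.",
                 class = "seqppv_argument_error")
  }
  check_probability(prevalence, "prevalence", lo_open = TRUE, hi_open = TRUE)
  cells <- outer(log_lr_positive, prevalence, function(llr, phi) {
    round_half_up(required_iterations_continuous(phi, target,
                                                 log_lr_positive = llr), 2)
  })
  out <- tibble::as_tibble(as.data.frame(cells),
                           .name_repair = ~ format_num(prevalence))
  out <- dplyr::bind_cols(tibble::tibble(log_lr_positive = log_lr_positive), out)
  structure(out,
            class = c("reference_table", class(out)),
            target_ppv = target,
            prevalence = prevalence)
}

format_num <- function(x) vapply(x, function(v) format(v, trim = TRUE), "")

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Reference iteration table for target PPV = %s\n",
              format_num(attr(x, "target_ppv"))))
  cat("(rows: ln LR+; columns: prevalence; cells: continuous n, 2 dp)\n")
  NextMethod()
}

#' Tidy a reference table into long form
#'
#' @param x A [reference_table()].
#' @param ... Unused.
#' @return A tibble with columns `log_lr_positive`, `prevalence`, `n`,
#'   `target_ppv`.
#' @export
tidy.reference_table <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -"log_lr_positive",
                              names_to = "prevalence", values_to = "n")
  long$prevalence <- as.numeric(long$prevalence)
  long$target_ppv <- attr(x, "target_ppv")
  long[c("log_lr_positive", "prevalence", "n", "target_ppv")]
}

#' @rdname tidy.reference_table
#' @param object A [reference_table()].
#' @return For `glance()`: a one-row tibble with the target and grid extents.
#' @export
glance.reference_table <- function(object, ...) {
  td <- tidy.reference_table(object)
  tibble::tibble(
    target_ppv = attr(object, "target_ppv"),
    n_rows = length(unique(td$log_lr_positive)),
    n_cols = length(unique(td$prevalence)),
    min_n = min(td$n), max_n = max(td$n)
  )
}

#' Heatmap of a reference iteration table
#'
#' @param object A [reference_table()].
#' @param ... Unused.
#' @return A ggplot: tiles of the continuous iteration count over
#'   ln(LR+) x prevalence, labelled with the 2-dp cell values.
#' @export
autoplot.reference_table <- function(object, ...) {
  long <- tidy.reference_table(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$prevalence), y = factor(.data$log_lr_positive),
    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$n)), size = 3) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "Prevalence", y = "ln(LR+)", fill = "n",
      title = sprintf("Test iterations needed for PPV ≥ %s",
                      format_num(attr(object, "target_ppv")))) +
    ggplot2::theme_minimal()
}

#' Iteration-count surface over sensitivity, specificity and prevalence
#'
#' Evaluates [required_iterations()] on the full cross of the three parameter
#' grids for a fixed target PPV — the "tablecloth" surface of integer test
#' counts. Infeasible combinations (a + b <= 1, or prevalence 0) carry `NA`
#' in `n_i` with the reason in `feasibility`; they are never reported as
#' negative counts.
#'
#' @param target Target PPV, in (0, 1).
#' @param sensitivity,specificity,prevalence Numeric grids in (0, 1).
#' @return A tibble of class `"tablecloth"` (and `"iteration_plan"`): the grid
#'   cross with the iteration-plan columns. Attribute `target_ppv` carries the
#'   target.
#' @examples
#' tablecloth(0.95, sensitivity = c(0.7, 0.9), specificity = c(0.7, 0.9),
#'            prevalence = c(0.02, 0.1))
#' @export
tablecloth <- function(target,
                       sensitivity = seq(0.55, 0.95, by = 0.1),
                       specificity = seq(0.55, 0.95, by = 0.1),
                       prevalence = c(0.02, 0.05, 0.1, 0.2)) {
  check_target(target)
  stopifnot(length(target) == 1)
  if (length(sensitivity) == 0 || length(specificity) == 0 || length(prevalence) == 0) {
    rlang::abort("Parameter grids must be non-empty.",
                 class = "seqppv_argument_error")
  }
  check_probability(sensitivity, "sensitivity", lo_open = TRUE, hi_open = TRUE)
  check_probability(specificity, "specificity", lo_open = TRUE, hi_open = TRUE)
  check_probability(prevalence, "prevalence", lo_open = TRUE, hi_open = TRUE)
  grid <- tidyr::expand_grid(sensitivity = sensitivity,
                             specificity = specificity,
                             prevalence = prevalence)
  out <- required_iterations(grid$sensitivity, grid$specificity,
                             grid$prevalence, target)
  structure(out, class = c("tablecloth", class(out)), target_ppv = target)
}

#' Tile plot of the iteration-count surface
#'
#' @param object A [tablecloth()].
#' @param ... Unused.
#' @return A ggplot: `n_i` tiles over sensitivity x specificity, faceted by
#'   prevalence; infeasible cells are blanked.
#' @export
autoplot.tablecloth <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sensitivity, y = .data$specificity, fill = .data$n_i)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~prevalence, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(direction = -1, na.value = "grey85") +
    ggplot2::labs(
      fill = "tests",
      title = sprintf("Tests needed for PPV ≥ %s (grey: infeasible)",
                      format_num(attr(object, "target_ppv")))) +
    ggplot2::theme_minimal()
}
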