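# Writers and readers for reference tables and simulation reports.
# CSV dialect: comma separator, "." decimal, "#"-prefixed metadata lines,
# cells formatted to 2 dp, infeasible cells as the literal token "INF".
# Every writer has a reader and write -> read -> write is byte-identical.

format_cell <- function(x) ifelse(is.na(x), "INF", sprintf("%.2f", x))

#' Write and read reference iteration tables
#'
#' `write_reference_table()` serialises a [reference_table()] to CSV (the
#' dialect above) or JSON (`target_ppv`, `row_keys`, `column_keys`, `cells`,
#' with infeasible cells as `null`). `read_reference_table()` inverts it; the
#' format is inferred from the file extension when not given.
#'
#' @param x A [reference_table()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `write_reference_table()` returns `path` invisibly;
#'   `read_reference_table()` returns a [reference_table()].
#' @examples
#' tab <- reference_table(0.95)
#' f <- tempfile(fileext = ".csv")
#' write_reference_table(tab, f)
#' identical(tidy(read_reference_table(f)), tidy(tab))
#' @export
write_reference_table <- function(x, path, format = c("csv", "json")) {
  stopifnot(inherits(x, "reference_table"))
  format <- match.arg(format, several.ok = FALSE)
  target <- attr(x, "target_ppv")
  prev <- attr(x, "prevalence")
  cells <- as.matrix(tibble::as_tibble(x)[, -1, drop = FALSE])
  if (format == "csv") {
    lines <- c(
      "# reference_table: test iterations needed to reach a target PPV",
      sprintf("# target_ppv=%s", format_num(target)),
      paste(c("ln_LR+", format_num(prev)), collapse = ","))
    for (i in seq_len(nrow(cells))) {
      lines <- c(lines, paste(c(sprintf("%.2f", x$log_lr_positive[i]),
                                format_cell(cells[i, ])), collapse = ","))
    }
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(target_ppv = target,
           row_keys = x$log_lr_positive,
           column_keys = prev,
           cells = lapply(seq_len(nrow(cells)), function(i)
             unname(as.list(cells[i, ])))),
      path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cells <- obj$cells
    if (is.list(cells)) {
      cells <- do.call(rbind, lapply(cells, function(r)
        vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)))
    }
    return(rebuild_reference_table(obj$target_ppv, obj$row_keys,
                                   obj$column_keys, cells))
  }
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  target_line <- grep("target_ppv=", meta, value = TRUE)
  if (length(target_line) != 1) {
    rlang::abort("Not a reference-table CSV: missing '# target_ppv=' metadata.",
                 class = "seqppv_argument_error")
  }
  target <- as.numeric(sub(".*target_ppv=", "", target_line))
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  prev <- as.numeric(header[-1])
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  row_keys <- vapply(rows, function(r) as.numeric(r[1]), 0)
  cells <- t(vapply(rows, function(r) {
    v <- r[-1]
    ifelse(v == "INF", NA_real_, suppressWarnings(as.numeric(v)))
  }, numeric(length(prev))))
  rebuild_reference_table(target, row_keys, prev, cells)
}

rebuild_reference_table <- function(target, row_keys, prevalence, cells) {
  cells <- matrix(as.numeric(cells), nrow = length(row_keys))
  out <- tibble::as_tibble(as.data.frame(cells),
                           .name_repair = ~ format_num(prevalence))
  out <- dplyr::bind_cols(tibble::tibble(log_lr_positive = row_keys), out)
  structure(out, class = c("reference_table", class(out)),
            target_ppv = target, prevalence = prevalence)
}

#' Write and read simulation reports
#'
#' JSON report with the full configuration echo (including the seed), the
#' counts, empirical and analytic values and Monte-Carlo standard errors.
#'
#' @param x A `"sequential_simulation"` from [simulate_sequential_testing()].
#' @param path Output file path.
#' @return `write_simulation_report()` returns `path` invisibly;
#'   `read_simulation_report()` returns the report as a list with the same
#'   fields.
#' @export
write_simulation_report <- function(x, path) {
  stopifnot(inherits(x, "sequential_simulation"))
  report <- list(
    config = as.list(x$config),
    counts = list(
      n_diseased = x$n_diseased,
      n_all_positive = x$n_all_positive,
      n_all_positive_diseased = x$n_all_positive_diseased),
    empirical_ppv = x$empirical_ppv,
    analytic_ppv = x$analytic_ppv,
    single_test_ppv = x$single_test_ppv,
    mc_standard_error = x$mc_standard_error,
    all_positive_fraction = x$all_positive_fraction,
    expected_all_positive_fraction = x$expected_all_positive_fraction,
    fraction_standard_error = x$fraction_standard_error)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_report
#' @export
read_simulation_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a tablecloth grid
#'
#' CSV: the long grid with `n_i` as an integer or the token `"INF"` for
#' infeasible cells; JSON mirrors the columns with `null` for infeasible.
#'
#' @param x A [tablecloth()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_tablecloth <- function(x, path, format = c("csv", "json")) {
  stopifnot(inherits(x, "tablecloth"))
  format <- match.arg(format)
  df <- tibble::as_tibble(x)[, c("sensitivity", "specificity", "prevalence",
                                 "target_ppv", "n_i", "feasibility")]
  if (format == "csv") {
    out <- df
    out$n_i <- ifelse(is.na(df$n_i), "INF", as.character(df$n_i))
    lines <- c("# tablecloth: integer test iterations needed to reach target_ppv",
               paste(names(out), collapse = ","),
               do.call(paste, c(lapply(out, as.character), sep = ",")))
    writeLines(lines, path)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  invisible(path)
}
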