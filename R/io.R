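#' Read an assessment table from CSV
#'
#' Columns: `therapeutic_id`, `criterion_id`, `characteristic_id` and
#' optionally `rater_id`, `assessed_on` (ISO-8601), `source_note`. UTF-8
#' with a header row.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_assessments <- function(path) {
  a <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if ("assessed_on" %in% names(a)) a$assessed_on <- as.Date(a$assessed_on)
  a
}

#' Read panel responses from CSV
#'
#' Columns: `item_id`, `item_kind` (`ordinal`|`statement`), `rater_id`,
#' `value` (Likert 1-5).
#'
#' @param path CSV file path.
#' @return A tibble for [evaluate_panel()].
#' @export
read_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    item_id = readr::col_character(),
                    item_kind = readr::col_character(),
                    rater_id = readr::col_character(),
                    value = readr::col_integer()
                  ))
}

#' Write a ranking report
#'
#' CSV: `rank`, `therapeutic_id`, `overall_benefit`, `excluded` and one
#' column per criterion contribution. Markdown: a pipe table of the same
#' plus the adjacent-pair interval statements.
#'
#' @param ranking An `rst_ranking`.
#' @param path Output path.
#' @param format `"csv"` (default) or `"md"`.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, format = c("csv", "md")) {
  format <- match.arg(format)
  e <- ranking$entries
  if (format == "csv") {
    readr::write_csv(e, path)
  } else {
    hdr <- paste0("| ", paste(names(e), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(e)), collapse = "|"), "|")
    body <- apply(e, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    stmts <- ranking$interval_statements
    stmt_lines <- if (nrow(stmts) > 0) {
      c("", "## Interval statements (adjacent pairs)", "",
        sprintf("- %s vs %s: %s (delta %d)",
                stmts$id_a, stmts$id_b, stmts$category, stmts$delta))
    } else character()
    writeLines(c(sprintf("# Portfolio ranking (rubric v%s)", ranking$rubric_version),
                 "", hdr, sep, body, stmt_lines), path)
  }
  invisible(path)
}
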