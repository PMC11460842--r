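#' Consensus on a single Likert item
#'
#' A panel item reaches consensus agreement when at least
#' `consensus_min_raters` of the raters respond "agree" or "strongly
#' agree", i.e. give a value at or above `agree_cutoff` on the 5-point
#' scale (1 = strongly disagree ... 4 = agree, 5 = strongly agree).
#'
#' @param values Integer Likert responses for one item, one per rater.
#' @param agree_cutoff Lowest value counted as agreement (default 4).
#' @param consensus_min_raters Raters required at or above the cutoff
#'   (default 2, the 2-of-3 rule).
#' @param n_raters Expected panel size (default 3); a different number of
#'   responses is an error.
#' @return Logical scalar.
#' @export
#' @examples
#' item_consensus(c(5, 4, 1))   # TRUE
#' item_consensus(c(5, 3, 3))   # FALSE
item_consensus <- function(values, agree_cutoff = 4, consensus_min_raters = 2,
                           n_raters = 3) {
  if (length(values) != n_raters) {
    rlang::abort(sprintf("expected %d responses for the item, got %d",
                         n_raters, length(values)))
  }
  if (anyNA(values) || !all(values %in% 1:5)) {
    rlang::abort("Likert values must be integers in 1..5")
  }
  sum(values >= agree_cutoff) >= consensus_min_raters
}

#' Evaluate a validation panel
#'
#' A three-member panel reviews a ranking: one ordinal item (agreement with
#' the ordinal ranking as a whole) and a set of interval statements
#' describing score gaps between ranked therapeutics. The ranking is
#' validated when the ordinal item reaches consensus (2-of-3 agreeing or
#' strongly agreeing) *and* the share of statements with consensus meets
#' the threshold (75% by default). The pass rule compares the exact
#' fraction; the percentage is rounded to the nearest integer only for
#' display.
#'
#' @param panel A data frame with columns `item_id`, `item_kind`
#'   (`"ordinal"` or `"statement"`), `rater_id` and `value` (Likert 1-5):
#'   exactly 3 distinct raters, each answering every item once, with
#'   exactly one ordinal item and at least one statement.
#' @inheritParams item_consensus
#' @param statement_threshold_pct Pass threshold on the statement
#'   consensus percentage (default 75).
#' @return An object of class `rst_validation` with elements
#'   `ordinal_consensus`, `statements_with_consensus`, `statement_total`,
#'   `statement_pct` (exact), `statement_pct_display` (rounded), `passed`
#'   and `items` (per-item consensus tibble).
#' @export
#' @examples
#' res <- evaluate_panel(stage_three_fixture())
#' glance(res)
evaluate_panel <- function(panel, agree_cutoff = 4, consensus_min_raters = 2,
                           statement_threshold_pct = 75) {
  req <- c("item_id", "item_kind", "rater_id", "value")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("panel table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  p <- tibble::as_tibble(panel)
  raters <- unique(p$rater_id)
  if (length(raters) != 3) {
    rlang::abort(sprintf("panel must have exactly 3 distinct raters, got %d",
                         length(raters)))
  }
  dup <- dplyr::filter(dplyr::count(p, .data$item_id, .data$rater_id),
                       .data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf("rater '%s' answered item '%s' more than once",
                         dup$rater_id[1], dup$item_id[1]))
  }
  kinds <- dplyr::distinct(p, .data$item_id, .data$item_kind)
  if (any(!kinds$item_kind %in% c("ordinal", "statement"))) {
    rlang::abort("item_kind must be 'ordinal' or 'statement'")
  }
  if (sum(kinds$item_kind == "ordinal") != 1) {
    rlang::abort("panel must contain exactly one ordinal item")
  }
  if (sum(kinds$item_kind == "statement") == 0) {
    rlang::abort("panel contains no interval statements")
  }
  items <- dplyr::summarise(
    dplyr::group_by(p, .data$item_id, .data$item_kind),
    n_agree = sum(.data$value >= agree_cutoff),
    consensus = item_consensus(.data$value, agree_cutoff,
                               consensus_min_raters,
                               n_raters = length(raters)),
    .groups = "drop"
  )
  stmts <- dplyr::filter(items, .data$item_kind == "statement")
  k <- sum(stmts$consensus)
  total <- nrow(stmts)
  pct <- 100 * k / total
  ordinal_ok <- items$consensus[items$item_kind == "ordinal"]
  structure(
    list(
      ordinal_consensus = ordinal_ok,
      statements_with_consensus = as.integer(k),
      statement_total = as.integer(total),
      statement_pct = pct,
      statement_pct_display = as.integer(round(pct)),
      passed = ordinal_ok && (k / total >= statement_threshold_pct / 100),
      statement_threshold_pct = statement_threshold_pct,
      items = items
    ),
    class = "rst_validation"
  )
}

#' @method tidy rst_validation
#' @export
tidy.rst_validation <- function(x, ...) x$items

#' @method glance rst_validation
#' @export
glance.rst_validation <- function(x, ...) {
  tibble::tibble(
    ordinal_consensus = x$ordinal_consensus,
    statements_with_consensus = x$statements_with_consensus,
    statement_total = x$statement_total,
    statement_pct = x$statement_pct,
    statement_pct_display = x$statement_pct_display,
    statement_threshold_pct = x$statement_threshold_pct,
    passed = x$passed
  )
}

#' @export
print.rst_validation <- function(x, ...) {
  cat(sprintf(
    "<rst_validation: ordinal consensus %s; statements %d/%d (%d%%); threshold %g%% -> %s>\n",
    if (x$ordinal_consensus) "yes" else "no",
    x$statements_with_consensus, x$statement_total, x$statement_pct_display,
    x$statement_threshold_pct, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' @method autoplot rst_validation
#' @export
autoplot.rst_validation <- function(object, ...) {
  it <- dplyr::mutate(object$items,
                      item_id = stats::reorder(.data$item_id, .data$n_agree))
  ggplot2::ggplot(it, ggplot2::aes(x = .data$n_agree, y = .data$item_id,
                                   fill = .data$consensus)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "#b2182b"),
                               name = "consensus") +
    ggplot2::labs(x = "raters agreeing (Likert >= cutoff)", y = NULL,
                  title = sprintf("Panel consensus: %d/%d statements (%d%%)",
                                  object$statements_with_consensus,
                                  object$statement_total,
                                  object$statement_pct_display)) +
    ggplot2::theme_minimal()
}

#' Percent agreement between two sets of assessments
#'
#' Inter-rater reliability as raw percent agreement: the items are all
#' (therapeutic x criterion) selections, and agreement on an item means
#' both tables select the same characteristic. Passing two time points of
#' the same rater instead measures intra-rater reliability; the arithmetic
#' is identical.
#'
#' @param entries_a,entries_b Assessment tables covering the same
#'   therapeutics.
#' @param rubric The `rst_rubric` both were made against.
#' @param mode `"inter_rater"` (default) or `"intra_rater"`; recorded in
#'   the report.
#' @return An object of class `rst_agreement`: list with `n_items`,
#'   `n_agree`, `percent_agreement` (fraction in \[0, 1\]) and `mode`.
#' @export
percent_agreement <- function(entries_a, entries_b, rubric,
                              mode = c("inter_rater", "intra_rater")) {
  mode <- match.arg(mode)
  a <- check_assessments(entries_a, rubric)
  b <- check_assessments(entries_b, rubric)
  if (nrow(a) == 0 || nrow(b) == 0) {
    rlang::abort("cannot compute agreement on an empty item set")
  }
  unpaired <- c(setdiff(unique(a$therapeutic_id), unique(b$therapeutic_id)),
                setdiff(unique(b$therapeutic_id), unique(a$therapeutic_id)))
  if (length(unpaired) > 0) {
    rlang::abort(sprintf("unpaired therapeutic(s): %s",
                         paste(unpaired, collapse = ", ")))
  }
  m <- dplyr::inner_join(
    dplyr::select(a, "therapeutic_id", "criterion_id", sel_a = "characteristic_id"),
    dplyr::select(b, "therapeutic_id", "criterion_id", sel_b = "characteristic_id"),
    by = c("therapeutic_id", "criterion_id")
  )
  structure(
    list(n_items = nrow(m), n_agree = sum(m$sel_a == m$sel_b),
         percent_agreement = mean(m$sel_a == m$sel_b), mode = mode),
    class = "rst_agreement"
  )
}

#' @method glance rst_agreement
#' @export
glance.rst_agreement <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_items = x$n_items, n_agree = x$n_agree,
                 percent_agreement = x$percent_agreement)
}

#' @export
print.rst_agreement <- function(x, ...) {
  cat(sprintf("<rst_agreement (%s): %d/%d items, percent agreement %.3f>\n",
              x$mode, x$n_agree, x$n_items, x$percent_agreement))
  invisible(x)
}

#' Cohen's kappa for one criterion's selections
#'
#' Chance-corrected agreement between two raters' characteristic selections
#' for a single criterion, computed from the standard formula
#' kappa = (p_o - p_e) / (1 - p_e), where p_o is the observed agreement and
#' p_e the agreement expected from the raters' marginal selection
#' frequencies. When the expected agreement is 1 (both raters use a single
#' identical characteristic throughout) kappa is undefined and `NA` is
#' returned.
#'
#' @inheritParams percent_agreement
#' @param criterion_id Which criterion's selections to compare.
#' @return A numeric scalar in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
cohen_kappa <- function(entries_a, entries_b, rubric, criterion_id) {
  a <- check_assessments(entries_a, rubric)
  b <- check_assessments(entries_b, rubric)
  a <- a[a$criterion_id == criterion_id, c("therapeutic_id", "characteristic_id")]
  b <- b[b$criterion_id == criterion_id, c("therapeutic_id", "characteristic_id")]
  m <- dplyr::inner_join(a, b, by = "therapeutic_id",
                         suffix = c("_a", "_b"))
  if (nrow(m) < 2) {
    rlang::abort("Cohen's kappa needs at least 2 paired items")
  }
  labels <- union(m$characteristic_id_a, m$characteristic_id_b)
  pa <- table(factor(m$characteristic_id_a, levels = labels)) / nrow(m)
  pb <- table(factor(m$characteristic_id_b, levels = labels)) / nrow(m)
  po <- mean(m$characteristic_id_a == m$characteristic_id_b)
  pe <- sum(pa * pb)
  if (isTRUE(all.equal(pe, 1))) return(NA_real_)
  (po - pe) / (1 - pe)
}
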