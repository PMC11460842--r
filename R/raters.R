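#' Detect discrepancies between two independent entries
#'
#' Two raters independently select one characteristic per criterion for the
#' same therapeutic; a discrepancy is any criterion where their selections
#' differ. The comparison is symmetric.
#'
#' @param entry_a,entry_b Assessment tables (columns `therapeutic_id`,
#'   `criterion_id`, `characteristic_id`) for one and the same therapeutic.
#' @param rubric The `rst_rubric` both entries were made against.
#' @return Character vector of discrepant criterion ids, in rubric order;
#'   empty means full agreement.
#' @export
detect_discrepancies <- function(entry_a, entry_b, rubric) {
  a <- check_assessments(entry_a, rubric, allow_empty = FALSE)
  b <- check_assessments(entry_b, rubric, allow_empty = FALSE)
  ta <- unique(a$therapeutic_id)
  tb <- unique(b$therapeutic_id)
  if (length(ta) != 1 || length(tb) != 1) {
    rlang::abort("each entry must cover exactly one therapeutic")
  }
  if (ta != tb) {
    rlang::abort(sprintf("entries are for different therapeutics ('%s' vs '%s')",
                         ta, tb))
  }
  crit_ids <- purrr::map_chr(rubric$criteria, "id")
  sel_a <- stats::setNames(a$characteristic_id, a$criterion_id)
  sel_b <- stats::setNames(b$characteristic_id, b$criterion_id)
  crit_ids[sel_a[crit_ids] != sel_b[crit_ids]]
}

#' Summarize dual-entry discrepancies across a portfolio
#'
#' Pairs the two raters' assessment tables by therapeutic and counts
#' discrepant criteria per therapeutic. Entry order follows the order of
#' first appearance in `entries_a`, which is the order used by
#' [stability_streak()].
#'
#' @param entries_a,entries_b Assessment tables covering the same set of
#'   therapeutics, one rater each.
#' @inheritParams detect_discrepancies
#' @return A tibble with one row per therapeutic: `therapeutic_id`,
#'   `n_discrepancies`, `clean`, `discrepant_criteria` (comma-separated).
#' @export
discrepancy_summary <- function(entries_a, entries_b, rubric) {
  a <- check_assessments(entries_a, rubric)
  b <- check_assessments(entries_b, rubric)
  ids_a <- unique(a$therapeutic_id)
  ids_b <- unique(b$therapeutic_id)
  unpaired <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(unpaired) > 0) {
    rlang::abort(sprintf("unpaired therapeutic(s): %s",
                         paste(unpaired, collapse = ", ")))
  }
  purrr::map_dfr(ids_a, function(tid) {
    d <- detect_discrepancies(a[a$therapeutic_id == tid, ],
                              b[b$therapeutic_id == tid, ], rubric)
    tibble::tibble(therapeutic_id = tid, n_discrepancies = length(d),
                   clean = length(d) == 0,
                   discrepant_criteria = paste(d, collapse = ","))
  })
}

#' Adjudicate a dual entry into a final assessment
#'
#' Where the two raters agree, the agreed selection stands; every
#' discrepant criterion must carry exactly one decision from the
#' adjudicating discussion (the decision may match either rater's choice or
#' be a new consensus selection). Decisions for non-discrepant criteria, or
#' a missing decision, are errors.
#'
#' @inheritParams detect_discrepancies
#' @param decisions Named character vector or two-column data frame
#'   (`criterion_id`, `characteristic_id`) resolving each discrepant
#'   criterion. May be empty when the entries fully agree.
#' @param adjudicator_id Rater id recorded on the final assessment.
#' @return The final adjudicated assessment tibble (one row per criterion),
#'   with `rater_id = adjudicator_id` and `assessed_on` carried from the
#'   later of the two entries when dates are present.
#' @export
adjudicate <- function(entry_a, entry_b, rubric, decisions = character(),
                       adjudicator_id = "consensus") {
  disc <- detect_discrepancies(entry_a, entry_b, rubric)
  if (is.data.frame(decisions)) {
    decisions <- stats::setNames(as.character(decisions$characteristic_id),
                                 as.character(decisions$criterion_id))
  }
  extra <- setdiff(names(decisions), disc)
  if (length(extra) > 0) {
    rlang::abort(sprintf("decision given for non-discrepant criterion(s): %s",
                         paste(extra, collapse = ", ")))
  }
  missing_d <- setdiff(disc, names(decisions))
  if (length(missing_d) > 0) {
    rlang::abort(sprintf("missing decision for discrepant criterion(s): %s",
                         paste(missing_d, collapse = ", ")))
  }
  a <- check_assessments(entry_a, rubric, allow_empty = FALSE)
  final <- a
  for (cid in disc) {
    final$characteristic_id[final$criterion_id == cid] <- decisions[[cid]]
  }
  final$rater_id <- adjudicator_id
  if ("assessed_on" %in% names(entry_a) && "assessed_on" %in% names(entry_b)) {
    final$assessed_on <- max(as.Date(entry_a$assessed_on),
                             as.Date(entry_b$assessed_on))
  }
  # decisions must name real characteristics of their criterion
  check_assessments(final, rubric, allow_empty = FALSE)
}

#' Trailing run of discrepancy-free dual entries
#'
#' Pilot testing treats the instrument as internally consistent and
#' reliable once a fixed number of consecutive therapeutics (10 by default)
#' have been entered without any discrepancy between the two independent
#' raters. The streak is the length of the trailing run of clean entries in
#' entry order; any discrepant entry resets it to zero.
#'
#' @param history A logical vector (`TRUE` = clean entry, in entry order),
#'   or a data frame with a logical `clean` column or an integer
#'   `n_discrepancies` column, as produced by [discrepancy_summary()].
#' @param threshold Streak length at which the criterion is met (default 10).
#' @return A one-row tibble: `streak`, `met`, `threshold`, `n_entries`.
#' @export
#' @examples
#' stability_streak(rep(TRUE, 10))                  # met
#' stability_streak(c(rep(TRUE, 9), FALSE, TRUE))   # streak 1, not met
stability_streak <- function(history, threshold = 10) {
  clean <- if (is.data.frame(history)) {
    if ("clean" %in% names(history)) as.logical(history$clean)
    else if ("n_discrepancies" %in% names(history)) history$n_discrepancies == 0
    else rlang::abort("history data frame needs a 'clean' or 'n_discrepancies' column")
  } else {
    as.logical(history)
  }
  if (anyNA(clean)) rlang::abort("history contains missing values")
  streak <- 0L
  if (length(clean) > 0) {
    rl <- rle(rev(clean))
    streak <- if (rl$values[1]) rl$lengths[1] else 0L
  }
  tibble::tibble(streak = as.integer(streak),
                 met = streak >= threshold,
                 threshold = as.integer(threshold),
                 n_entries = length(clean))
}

#' Next review date under the six-month reassessment rule
#'
#' Therapeutics are reassessed whenever new information arises or every six
#' calendar months, whichever occurs first. Month arithmetic clamps to the
#' end of the month (e.g., Aug 31 + 6 months is Feb 28).
#'
#' @param last_assessed Date (or coercible) of the last assessment;
#'   vectorized.
#' @param new_information_on Optional date new information arose; `NA` where
#'   none. Must not precede `last_assessed`.
#' @return Date vector of due dates.
#' @export
#' @examples
#' next_review(as.Date("2022-10-01"))                    # 2023-04-01
#' next_review(as.Date("2022-10-01"), as.Date("2022-12-15"))
next_review <- function(last_assessed, new_information_on = NULL) {
  last <- as.Date(last_assessed)
  six <- lubridate::add_with_rollback(last, months(6))
  if (is.null(new_information_on)) return(six)
  news <- as.Date(new_information_on)
  news <- rep_len(news, length(last))
  bad <- !is.na(news) & news < last
  if (any(bad)) {
    rlang::abort("new_information_on precedes last_assessed")
  }
  due <- six
  has_news <- !is.na(news)
  due[has_news] <- pmin(news[has_news], six[has_news])
  due
}

#' Build a review schedule for a portfolio
#'
#' @param therapeutics A data frame with columns `therapeutic_id`,
#'   `last_assessed` and optionally `new_information_on`.
#' @return A tibble adding a `due` column per [next_review()].
#' @export
review_schedule <- function(therapeutics) {
  req <- c("therapeutic_id", "last_assessed")
  missing_cols <- setdiff(req, names(therapeutics))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("schedule table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  t <- tibble::as_tibble(therapeutics)
  news <- if ("new_information_on" %in% names(t)) t$new_information_on else NULL
  dplyr::mutate(t, due = next_review(.data$last_assessed, news))
}
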