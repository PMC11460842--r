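# Run code under a fixed seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a portfolio of assessments
#'
#' Generates one complete assessment per therapeutic: for every criterion a
#' characteristic is drawn uniformly from the criterion's non-exclusion
#' characteristics; then, with probability `exclusion_prob`, one randomly
#' chosen selection is replaced by a characteristic of exclusion. The
#' generator emulates only structural properties of a real portfolio
#' (selection patterns and exclusion rate), never clinical content. The
#' default portfolio size of 69 therapeutics matches the scale of a
#' pandemic triage pilot.
#'
#' @param rubric An `rst_rubric`.
#' @param n_therapeutics Number of therapeutics to simulate (default 69).
#' @param exclusion_prob Per-therapeutic probability of carrying one
#'   exclusion characteristic (default 0.1). Requires the rubric to contain
#'   at least one exclusion characteristic when positive.
#' @param seed Integer seed; identical inputs give identical output.
#' @param rater_id Rater id stamped on the assessments.
#' @param assessed_on Assessment date stamped on the assessments.
#' @return An assessment tibble (`therapeutic_id`, `criterion_id`,
#'   `characteristic_id`, `rater_id`, `assessed_on`) valid against `rubric`.
#' @export
#' @examples
#' a <- simulate_portfolio(default_rubric(), n_therapeutics = 3, seed = 7)
#' score_assessments(a, default_rubric())
simulate_portfolio <- function(rubric, n_therapeutics = 69,
                               exclusion_prob = 0.1, seed = 1,
                               rater_id = "rater_1",
                               assessed_on = as.Date("2023-01-01")) {
  if (exclusion_prob < 0 || exclusion_prob > 1) {
    rlang::abort("exclusion_prob must be in [0, 1]")
  }
  if (n_therapeutics < 0) rlang::abort("n_therapeutics must be >= 0")
  lookup <- tidy(rubric)
  excl <- lookup[lookup$is_exclusion, ]
  if (exclusion_prob > 0 && nrow(excl) == 0) {
    rlang::abort("rubric has no exclusion characteristics but exclusion_prob > 0")
  }
  crit_ids <- purrr::map_chr(rubric$criteria, "id")
  pools <- purrr::map(rubric$criteria, function(cr) {
    ids <- purrr::map_chr(cr$characteristics, "id")
    ids[!purrr::map_lgl(cr$characteristics, ~ isTRUE(.x$is_exclusion))]
  })
  names(pools) <- crit_ids
  if (any(lengths(pools) == 0)) {
    rlang::abort("every criterion needs at least one non-exclusion characteristic")
  }
  if (n_therapeutics == 0) {
    return(tibble::tibble(therapeutic_id = character(),
                          criterion_id = character(),
                          characteristic_id = character(),
                          rater_id = character(),
                          assessed_on = as.Date(character())))
  }
  tids <- sprintf("T%03d", seq_len(n_therapeutics))
  with_local_seed(seed, {
    rows <- purrr::map_dfr(tids, function(tid) {
      sel <- purrr::map_chr(pools, ~ .x[sample.int(length(.x), 1)])
      if (exclusion_prob > 0 && stats::runif(1) < exclusion_prob) {
        i <- sample.int(nrow(excl), 1)
        sel[[excl$criterion_id[i]]] <- excl$characteristic_id[i]
      }
      tibble::tibble(therapeutic_id = tid, criterion_id = crit_ids,
                     characteristic_id = unname(sel[crit_ids]))
    })
    dplyr::mutate(rows, rater_id = rater_id, assessed_on = assessed_on)
  })
}

#' Simulate a second, noisy rater
#'
#' Takes a truth set of assessments and resamples each criterion selection,
#' independently and with probability `disagreement_prob`, to a *different*
#' characteristic of the same criterion (uniformly among the alternatives).
#' With probability 0 the output selections equal the truth; with
#' probability 1 every selection on a criterion with at least two
#' characteristics differs.
#'
#' @param truth An assessment tibble (e.g. from [simulate_portfolio()]).
#' @param rubric The generating `rst_rubric`.
#' @param disagreement_prob Per-selection flip probability (default 0.05,
#'   a low rate consistent with trained raters in a pilot).
#' @param seed Integer seed.
#' @param rater_id Rater id stamped on the output.
#' @return An assessment tibble paired row-for-row with `truth`.
#' @export
simulate_second_rater <- function(truth, rubric, disagreement_prob = 0.05,
                                  seed = 1, rater_id = "rater_2") {
  if (disagreement_prob < 0 || disagreement_prob > 1) {
    rlang::abort("disagreement_prob must be in [0, 1]")
  }
  a <- check_assessments(truth, rubric)
  all_chars <- split(tidy(rubric)$characteristic_id, tidy(rubric)$criterion_id)
  with_local_seed(seed, {
    flip <- stats::runif(nrow(a)) < disagreement_prob
    new_sel <- a$characteristic_id
    for (i in which(flip)) {
      alts <- setdiff(all_chars[[a$criterion_id[i]]], a$characteristic_id[i])
      if (length(alts) > 0) {
        new_sel[i] <- alts[sample.int(length(alts), 1)]
      }
    }
    out <- a
    out$characteristic_id <- new_sel
    out$rater_id <- rater_id
    out
  })
}

#' Deterministic validation-panel fixture
#'
#' A fixed three-rater panel record over one ordinal-ranking item and 12
#' interval statements, constructed so that the ordinal item reaches
#' consensus (responses 5, 4, 4) and exactly 10 of the 12 statements have
#' at least two responses of "agree" or better while the remaining 2 have
#' exactly one. Evaluating it therefore yields consensus on 10 of 12
#' statements, a displayed 83%, and a pass under the 75% threshold.
#'
#' @return A panel tibble (`item_id`, `item_kind`, `rater_id`, `value`)
#'   for [evaluate_panel()].
#' @export
#' @examples
#' glance(evaluate_panel(stage_three_fixture()))
stage_three_fixture <- function() {
  raters <- c("panel_1", "panel_2", "panel_3")
  resp <- rbind(
    c(5, 4, 4),  # ordinal ranking item
    c(4, 4, 3), c(5, 4, 2), c(4, 5, 3), c(5, 5, 1), c(4, 4, 2),
    c(5, 4, 3), c(4, 4, 4), c(5, 5, 4), c(4, 5, 2), c(5, 4, 4),
    c(4, 3, 2), c(3, 4, 1)  # the two statements without consensus
  )
  items <- c("ordinal_ranking", sprintf("statement_%02d", 1:12))
  kinds <- c("ordinal", rep("statement", 12))
  tibble::tibble(
    item_id = rep(items, each = 3),
    item_kind = rep(kinds, each = 3),
    rater_id = rep(raters, times = length(items)),
    value = as.integer(t(resp))
  )
}
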