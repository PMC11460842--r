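# Fixture builders shared across test files. Everything is constructed in
# code; no external data.

chr <- function(id, score, label = paste("label", id), excl = FALSE) {
  list(id = id, label = label, score = as.integer(score), is_exclusion = excl)
}

crit <- function(id, ...) {
  list(id = id, name = paste("criterion", id), characteristics = list(...))
}

# Small three-criterion rubric: c1 has an exclusion characteristic.
mini_rubric <- function() {
  rubric(
    criteria = list(
      crit("c1", chr("a1", 2), chr("a2", 0), chr("a3", -100, excl = TRUE)),
      crit("c2", chr("b1", 5), chr("b2", -3)),
      crit("c3", chr("d1", 1), chr("d2", 0), chr("d3", -1))
    ),
    version = "test-mini"
  )
}

# One assessment as a long tibble from a named selection vector.
assess <- function(tid, sel, rater = "r1", date = as.Date("2023-01-15")) {
  tibble::tibble(
    therapeutic_id = tid,
    criterion_id = names(sel),
    characteristic_id = unname(sel),
    rater_id = rater,
    assessed_on = date
  )
}

# All-zero ("Unknown") selection for the default rubric.
default_unknown_selection <- function() {
  c(quality_of_evidence = "qoe_unknown", clinical_impact = "ci_unknown",
    safety = "safety_unknown", patient_preference = "pp_unknown",
    treatment_alternatives = "ta_unknown", authorization_canada = "ac_unknown",
    regulatory_other = "ro_unknown", domestic_landscape = "dl_unknown")
}

# Enumerate every possible assessment of a rubric (one row per combo).
enumerate_assessments <- function(rubric) {
  pools <- lapply(rubric$criteria, function(cr)
    vapply(cr$characteristics, `[[`, "", "id"))
  names(pools) <- vapply(rubric$criteria, `[[`, "", "id")
  grid <- expand.grid(pools, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    sel <- unlist(grid[i, , drop = FALSE])
    names(sel) <- names(pools)
    assess(sprintf("E%04d", i), sel)
  })
}

# A random valid rubric for round-trip property tests.
random_rubric <- function() {
  n_crit <- sample(1:4, 1)
  crits <- lapply(seq_len(n_crit), function(i) {
    n_chr <- sample(2:4, 1)
    chars <- lapply(seq_len(n_chr), function(j) {
      excl <- j == n_chr && stats::runif(1) < 0.3
      chr(sprintf("c%d_x%d", i, j),
          if (excl) -100L else sample(-10:10, 1),
          label = sprintf("random characteristic %d-%d", i, j),
          excl = excl)
    })
    do.call(crit, c(list(sprintf("c%d", i)), chars))
  })
  rubric(crits, version = sprintf("rand-%d", sample.int(1e6, 1)))
}
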