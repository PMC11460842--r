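#' Construct a score scale
#'
#' The universal characteristic scoring scale. Every non-exclusion
#' characteristic score must lie in `[min, max]`; most characteristics are
#' expected to fall inside the narrower `typical` band. Characteristics of
#' exclusion carry the `exclusion_sentinel` instead, a value far below the
#' scale so that a single exclusion dominates any additive total.
#'
#' @param min,max Integer scale bounds. Defaults `-10` and `10`.
#' @param typical Length-2 integer vector, the band most scores fall in,
#'   strictly inside `[min, max]`. Default `c(-5, 5)`.
#' @param exclusion_sentinel Integer assigned to characteristics of
#'   exclusion; must be below `min`. Default `-100`.
#' @return A list of class `rst_scale`.
#' @export
#' @examples
#' score_scale()
score_scale <- function(min = -10L, max = 10L, typical = c(-5L, 5L),
                        exclusion_sentinel = -100L) {
  scale <- list(
    min = as.integer(min), max = as.integer(max),
    typical = as.integer(typical),
    exclusion_sentinel = as.integer(exclusion_sentinel)
  )
  if (!(scale$min < 0 && 0 < scale$max)) {
    rlang::abort("score scale must straddle zero (min < 0 < max)")
  }
  if (scale$exclusion_sentinel >= scale$min) {
    rlang::abort("exclusion_sentinel must lie below the scale minimum")
  }
  if (length(scale$typical) != 2 ||
      !(scale$min < scale$typical[1] && scale$typical[2] < scale$max)) {
    rlang::abort("typical band must be a pair strictly inside [min, max]")
  }
  structure(scale, class = "rst_scale")
}

#' Construct a scoring rubric
#'
#' A rubric is an ordered set of criteria; each criterion holds mutually
#' exclusive characteristics, each carrying an integer score on the rubric's
#' scale (or the exclusion sentinel). Assessors select exactly one
#' characteristic per criterion per therapeutic; the overall benefit score is
#' the sum of the selected scores.
#'
#' @param criteria A list of criteria. Each criterion is a list with elements
#'   `id` (short string), `name` (free text) and `characteristics`, a list of
#'   lists with elements `id`, `label`, `score` and `is_exclusion`.
#' @param scale A [score_scale()].
#' @param version Version string recorded in serialized files and logs.
#' @param notes Free-text notes.
#' @return An object of class `rst_rubric`.
#' @seealso [validate_rubric()], [read_rubric()], [default_rubric()]
#' @export
rubric <- function(criteria, scale = score_scale(), version = "custom",
                   notes = "") {
  r <- structure(
    list(version = as.character(version), notes = as.character(notes),
         scale = scale, criteria = criteria),
    class = "rst_rubric"
  )
  v <- validate_rubric(r)
  if (nrow(v) > 0) {
    rlang::abort(c("invalid rubric",
                   stats::setNames(v$message, rep("x", nrow(v)))))
  }
  r
}

#' Flatten a rubric to one row per characteristic
#'
#' @param x An `rst_rubric`.
#' @param ... Unused.
#' @return A tibble with columns `criterion_id`, `criterion_name`,
#'   `characteristic_id`, `label`, `score`, `is_exclusion`.
#' @method tidy rst_rubric
#' @export
tidy.rst_rubric <- function(x, ...) {
  purrr::map_dfr(x$criteria, function(cr) {
    tibble::tibble(
      criterion_id = cr$id %||% NA_character_,
      criterion_name = cr$name %||% NA_character_,
      characteristic_id = purrr::map_chr(cr$characteristics,
                                         ~ as.character(.x$id %||% NA)),
      label = purrr::map_chr(cr$characteristics,
                             ~ as.character(.x$label %||% NA)),
      score = purrr::map_int(cr$characteristics,
                             ~ as.integer(.x$score %||% NA)),
      is_exclusion = purrr::map_lgl(cr$characteristics,
                                    ~ isTRUE(.x$is_exclusion))
    )
  })
}

#' @method glance rst_rubric
#' @export
glance.rst_rubric <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    version = x$version,
    n_criteria = length(x$criteria),
    n_characteristics = nrow(td),
    n_exclusion = sum(td$is_exclusion),
    scale_min = x$scale$min,
    scale_max = x$scale$max,
    exclusion_sentinel = x$scale$exclusion_sentinel
  )
}

#' @export
print.rst_rubric <- function(x, ...) {
  cat(sprintf("<rst_rubric v%s: %d criteria, scale %d..%d, sentinel %d>\n",
              x$version, length(x$criteria), x$scale$min, x$scale$max,
              x$scale$exclusion_sentinel))
  td <- tidy(x)
  smry <- dplyr::summarise(
    dplyr::group_by(td, .data$criterion_id),
    n = dplyr::n(), n_exclusion = sum(.data$is_exclusion), .groups = "drop"
  )
  print(smry, n = Inf)
  invisible(x)
}

#' Validate a rubric, returning violations as data
#'
#' Checks every structural rule a rubric must satisfy: scale sanity,
#' at least one criterion, at least two characteristics per criterion,
#' unique criterion ids, unique characteristic ids and labels within a
#' criterion, non-empty labels, non-exclusion scores within the scale, and
#' exclusion characteristics scored exactly at the sentinel. Violations are
#' returned as rows, never raised as conditions, so callers can report them
#' all at once.
#'
#' @param rubric An `rst_rubric` (or a bare list with the same shape).
#' @return A tibble with columns `scope` (`"scale"`, `"rubric"`,
#'   `"criterion"` or `"characteristic"`), `where` (the offending id path)
#'   and `message`. Zero rows means the rubric is valid.
#' @export
#' @examples
#' validate_rubric(default_rubric())   # zero rows
validate_rubric <- function(rubric) {
  viol <- function(scope, where, message) {
    tibble::tibble(scope = scope, where = where, message = message)
  }
  out <- list()
  sc <- rubric$scale
  if (is.null(sc) || !all(c("min", "max", "exclusion_sentinel") %in% names(sc))) {
    return(viol("scale", "scale", "missing or incomplete scale block"))
  }
  if (!(sc$min < 0 && 0 < sc$max)) {
    out <- c(out, list(viol("scale", "scale", "scale must satisfy min < 0 < max")))
  }
  if (sc$exclusion_sentinel >= sc$min) {
    out <- c(out, list(viol("scale", "scale",
                            "exclusion sentinel must lie below the scale minimum")))
  }
  if (!is.null(sc$typical) &&
      !(length(sc$typical) == 2 && sc$min < sc$typical[1] && sc$typical[2] < sc$max)) {
    out <- c(out, list(viol("scale", "scale",
                            "typical band must be nested strictly inside [min, max]")))
  }
  crits <- rubric$criteria
  if (length(crits) == 0) {
    out <- c(out, list(viol("rubric", "criteria", "rubric has no criteria")))
  }
  cids <- purrr::map_chr(crits, ~ as.character(.x$id %||% NA))
  dup <- unique(cids[duplicated(cids)])
  for (d in dup) {
    out <- c(out, list(viol("rubric", d, sprintf("duplicate criterion id '%s'", d))))
  }
  for (cr in crits) {
    cid <- as.character(cr$id %||% "<missing id>")
    chars <- cr$characteristics
    if (length(chars) < 2) {
      out <- c(out, list(viol("criterion", cid,
                              sprintf("criterion '%s' needs at least 2 characteristics", cid))))
    }
    ids <- purrr::map_chr(chars, ~ as.character(.x$id %||% NA))
    labs <- purrr::map_chr(chars, ~ as.character(.x$label %||% ""))
    for (d in unique(ids[duplicated(ids)])) {
      out <- c(out, list(viol("criterion", cid,
                              sprintf("criterion '%s': duplicate characteristic id '%s'", cid, d))))
    }
    for (d in unique(labs[duplicated(labs)])) {
      out <- c(out, list(viol("criterion", cid,
                              sprintf("criterion '%s': duplicate characteristic label '%s'", cid, d))))
    }
    for (ch in chars) {
      where <- paste0(cid, "/", as.character(ch$id %||% "?"))
      if (!nzchar(trimws(as.character(ch$label %||% "")))) {
        out <- c(out, list(viol("characteristic", where, "empty characteristic label")))
      }
      s <- ch$score
      if (is.null(s) || is.na(suppressWarnings(as.numeric(s))) ||
          as.numeric(s) != as.integer(as.numeric(s))) {
        out <- c(out, list(viol("characteristic", where, "score must be an integer")))
        next
      }
      s <- as.integer(s)
      if (isTRUE(ch$is_exclusion)) {
        if (s != sc$exclusion_sentinel) {
          out <- c(out, list(viol("characteristic", where,
                                  sprintf("exclusion characteristic scored %d, expected sentinel %d",
                                          s, sc$exclusion_sentinel))))
        }
      } else if (s < sc$min || s > sc$max) {
        out <- c(out, list(viol("characteristic", where,
                                sprintf("score %d outside scale %d..%d", s, sc$min, sc$max))))
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(scope = character(), where = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read a rubric from a YAML file
#'
#' The on-disk format mirrors the rubric structure: top-level keys
#' `version`, `notes`, `scale` (`min`, `max`, `typical`,
#' `exclusion_sentinel`) and `criteria`, a list of criteria each with `id`,
#' `name` and `characteristics` (`id`, `label`, `score`, `is_exclusion`).
#' Reading validates the rubric and aborts with the full violation list if
#' it is not valid; `read_rubric(write_rubric(r, f))` round-trips.
#'
#' @param path Path to a UTF-8 YAML rubric file.
#' @return An `rst_rubric`.
#' @export
#' @examples
#' path <- system.file("extdata", "default_rubric.yaml", package = "rapidscore")
#' r <- read_rubric(path)
#' glance(r)
read_rubric <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("rubric file not found: %s", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      rlang::abort(sprintf("cannot parse rubric file '%s': %s",
                           path, conditionMessage(e)))
    }
  )
  for (k in c("scale", "criteria")) {
    if (is.null(raw[[k]])) {
      rlang::abort(sprintf("rubric file '%s': missing top-level key '%s'", path, k))
    }
  }
  sc <- raw$scale
  scale <- tryCatch(
    score_scale(min = sc$min, max = sc$max,
                typical = sc$typical %||% c(sc$min + 1L, sc$max - 1L),
                exclusion_sentinel = sc$exclusion_sentinel),
    error = function(e) {
      rlang::abort(sprintf("rubric file '%s', scale block: %s",
                           path, conditionMessage(e)))
    }
  )
  criteria <- purrr::map(raw$criteria, function(cr) {
    list(
      id = as.character(cr$id), name = as.character(cr$name %||% cr$id),
      characteristics = purrr::map(cr$characteristics, function(ch) {
        list(id = as.character(ch$id), label = as.character(ch$label),
             score = as.integer(ch$score),
             is_exclusion = isTRUE(ch$is_exclusion))
      })
    )
  })
  r <- structure(
    list(version = as.character(raw$version %||% "unversioned"),
         notes = as.character(raw$notes %||% ""),
         scale = scale, criteria = criteria),
    class = "rst_rubric"
  )
  v <- validate_rubric(r)
  if (nrow(v) > 0) {
    rlang::abort(c(
      sprintf("rubric file '%s' failed validation (%d violations)", path, nrow(v)),
      stats::setNames(paste0(v$where, ": ", v$message), rep("x", nrow(v)))
    ))
  }
  r
}

#' Write a rubric to a YAML file
#'
#' @param rubric An `rst_rubric`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rubric <- function(rubric, path) {
  doc <- list(
    version = rubric$version,
    notes = rubric$notes,
    scale = list(
      min = rubric$scale$min, max = rubric$scale$max,
      typical = rubric$scale$typical,
      exclusion_sentinel = rubric$scale$exclusion_sentinel
    ),
    criteria = purrr::map(rubric$criteria, function(cr) {
      list(id = cr$id, name = cr$name,
           characteristics = purrr::map(cr$characteristics, function(ch) {
             list(id = ch$id, label = ch$label, score = ch$score,
                  is_exclusion = ch$is_exclusion)
           }))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The bundled default rubric
#'
#' Eight criteria for the preliminary assessment of investigational
#' therapeutics: quality of evidence, clinical impact, safety, patient
#' preference, availability of authorized treatment alternatives,
#' authorization status in Canada, regulatory status in other jurisdictions,
#' and the domestic development landscape. The safety criterion ships the
#' five published characteristics scoring 2, 1, 0, -2, -3. The other seven
#' criteria's characteristic sets are authored by this package from the
#' published "elements considered" and are *non-canonical*: they are an
#' editable starting point (scores within the typical -5..+5 band), not the
#' original instrument's wording. Three characteristics of exclusion
#' (scored -100) are included as editable placeholders.
#'
#' @return An `rst_rubric` with 8 criteria.
#' @export
#' @examples
#' glance(default_rubric())
default_rubric <- function() {
  path <- system.file("extdata", "default_rubric.yaml", package = "rapidscore")
  read_rubric(path)
}

#' Plot characteristic scores by criterion
#'
#' Dot plot of every characteristic's score, one facet row per criterion,
#' with exclusion sentinels highlighted. Useful when editing a rubric to see
#' whether the score spread still covers the intended range.
#'
#' @param rubric An `rst_rubric`.
#' @param include_exclusions Show sentinel-scored characteristics (default
#'   `FALSE`; their -100 score crushes the scale).
#' @return A ggplot object.
#' @export
plot_rubric <- function(rubric, include_exclusions = FALSE) {
  td <- tidy(rubric)
  if (!include_exclusions) td <- dplyr::filter(td, !.data$is_exclusion)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$score, y = .data$criterion_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_exclusion),
                        size = 3, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166ac", `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "characteristic score", y = NULL,
                  title = "Rubric characteristic scores") +
    ggplot2::theme_minimal()
}
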