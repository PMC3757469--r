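#' Parse a mutant identifier string
#'
#' A mutant is identified by the unordered set of its point substitutions,
#' written as `"-"`-separated tokens of the form
#' `<wt letter><position><new letter>` (e.g. `"G39A-T103G-W104F-L278A"`).
#' `parse_mutant()` validates the tokens and returns one row per substitution,
#' sorted by position — the canonical order. The wild type is the empty
#' mutant of order 0 and is written `"WT"`.
#'
#' @param text A single mutant identifier string, or `"WT"`.
#' @return A tibble with columns `position` (integer), `wt_residue`,
#'   `new_residue` (one-letter codes) and `token`, ordered by ascending
#'   position. The wild type parses to a zero-row tibble.
#' @examples
#' parse_mutant("L278A-G39A")
#' @seealso [format_mutant()], [canonical_mutant()], [mutant_order()]
#' @export
parse_mutant <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    abort("`text` must be a single non-missing string.")
  }
  empty <- tibble::tibble(
    position = integer(), wt_residue = character(),
    new_residue = character(), token = character()
  )
  if (identical(toupper(trimws(text)), "WT") || trimws(text) == "") {
    return(empty)
  }
  tokens <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  m <- stringr::str_match(tokens, "^([A-Za-z])(\\d+)([A-Za-z])$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(sprintf(
      "Malformed mutation token(s) in '%s': %s",
      text, paste(tokens[bad], collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    position = as.integer(m[, 3]),
    wt_residue = toupper(m[, 2]),
    new_residue = toupper(m[, 4])
  )
  bad_code <- !(out$wt_residue %in% AA_CODES) | !(out$new_residue %in% AA_CODES)
  if (any(bad_code)) {
    abort(sprintf(
      "Non-standard amino-acid code in token(s): %s",
      paste(tokens[bad_code], collapse = ", ")
    ))
  }
  if (any(out$wt_residue == out$new_residue)) {
    i <- out$wt_residue == out$new_residue
    abort(sprintf(
      "Substitution equals wild type in token(s): %s",
      paste(tokens[i], collapse = ", ")
    ))
  }
  if (anyDuplicated(out$position)) {
    abort(sprintf(
      "Duplicate position(s) in '%s': %s",
      text, paste(unique(out$position[duplicated(out$position)]), collapse = ", ")
    ))
  }
  out <- dplyr::arrange(out, .data$position)
  out$token <- paste0(out$wt_residue, out$position, out$new_residue)
  out
}

#' Format a parsed mutant back to its canonical string
#'
#' @param mutations A tibble as returned by [parse_mutant()].
#' @return The canonical identifier: tokens joined with `"-"` in ascending
#'   position order; `"WT"` for the empty mutant.
#' @export
format_mutant <- function(mutations) {
  if (nrow(mutations) == 0) {
    return("WT")
  }
  mutations <- dplyr::arrange(mutations, .data$position)
  paste0(
    mutations$wt_residue, mutations$position, mutations$new_residue,
    collapse = "-"
  )
}

#' Canonicalize mutant identifier strings
#'
#' Vectorized parse-and-reformat: token order in the input is irrelevant,
#' the output sorts tokens by ascending position.
#'
#' @param x Character vector of mutant identifiers.
#' @return Character vector of canonical identifiers.
#' @examples
#' canonical_mutant(c("L278A-G39A", "WT"))
#' @export
canonical_mutant <- function(x) {
  vapply(x, function(s) format_mutant(parse_mutant(s)), character(1),
    USE.NAMES = FALSE
  )
}

#' Number of simultaneous substitutions in a mutant
#'
#' @param x Character vector of mutant identifiers.
#' @return Integer vector of orders; the wild type has order 0.
#' @export
mutant_order <- function(x) {
  vapply(x, function(s) nrow(parse_mutant(s)), integer(1), USE.NAMES = FALSE)
}

#' Long table of the substitutions in a set of mutants
#'
#' @param x Character vector of mutant identifiers.
#' @return A tibble with one row per (mutant, substitution): columns
#'   `mutant` (canonical), `position`, `wt_residue`, `new_residue`, `token`.
#' @export
mutation_table <- function(x) {
  purrr::map_dfr(x, function(s) {
    parsed <- parse_mutant(s)
    dplyr::bind_cols(tibble::tibble(mutant = rep(format_mutant(parsed), nrow(parsed))), parsed)
  })
}

#' Intersect two collections of mutants by canonical identity
#'
#' Identity is the full substitution set: a single mutant never matches a
#' multi-mutant that merely contains it.
#'
#' @param a,b Character vectors of mutant identifiers (any token order).
#' @return Character vector of canonical identifiers present in both,
#'   duplicate-free, sorted.
#' @examples
#' intersect_mutants(c("G39A-L278A", "G39A"), "L278A-G39A")
#' @export
intersect_mutants <- function(a, b) {
  sort(intersect(unique(canonical_mutant(a)), unique(canonical_mutant(b))))
}
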