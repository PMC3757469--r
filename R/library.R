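#' Build a per-position substitution library
#'
#' A mutation library lists, for each mutable backbone position, the wild-type
#' residue and the substitutions allowed there. The number of allowed
#' substitutions at position i is its multiplicity g_i; combination counts
#' are elementary symmetric sums of the g_i (see [count_by_order()]).
#'
#' @param position Integer vector of residue positions (enzyme numbering).
#' @param wt_residue Character vector of one-letter wild-type codes.
#' @param substitutions Allowed new residues per position: either a list of
#'   character vectors or a character vector of comma-separated letters
#'   (e.g. `"F,Q,Y"`).
#' @return A tibble of class `mutation_library` with columns `position`,
#'   `wt_residue`, `substitutions` (list column) and `multiplicity`, sorted
#'   by position.
#' @examples
#' mutation_library(
#'   position = c(39, 104),
#'   wt_residue = c("G", "W"),
#'   substitutions = c("A", "F,Q,Y")
#' )
#' @export
mutation_library <- function(position, wt_residue, substitutions) {
  if (is.character(substitutions)) {
    substitutions <- lapply(
      strsplit(substitutions, ","),
      function(s) toupper(trimws(s))
    )
  }
  stopifnot(
    length(position) == length(wt_residue),
    length(position) == length(substitutions)
  )
  position <- as.integer(position)
  wt_residue <- toupper(wt_residue)
  if (any(is.na(position)) || any(position < 1)) {
    abort("Positions must be integers >= 1.")
  }
  if (anyDuplicated(position)) {
    abort(sprintf(
      "Duplicate library position(s): %s",
      paste(unique(position[duplicated(position)]), collapse = ", ")
    ))
  }
  for (i in seq_along(position)) {
    subs <- substitutions[[i]]
    codes <- c(wt_residue[[i]], subs)
    if (!all(codes %in% AA_CODES)) {
      abort(sprintf("Non-standard amino-acid code at position %d.", position[[i]]))
    }
    if (length(subs) < 1 || anyDuplicated(subs)) {
      abort(sprintf("Position %d needs >= 1 distinct substitutions.", position[[i]]))
    }
    if (wt_residue[[i]] %in% subs) {
      abort(sprintf(
        "Substitution equal to wild type at position %d.", position[[i]]
      ))
    }
  }
  out <- tibble::tibble(
    position = position,
    wt_residue = wt_residue,
    substitutions = substitutions,
    multiplicity = lengths(substitutions)
  )
  out <- dplyr::arrange(out, .data$position)
  class(out) <- c("mutation_library", class(out))
  out
}

#' Read a mutation library from a delimited file
#'
#' Expects columns `position`, `wt_residue`, `allowed_substitutions`
#' (comma-separated one-letter codes). Delimiter is inferred from the file
#' extension (`.tsv` vs `.csv`).
#'
#' @param path File path.
#' @return A `mutation_library` tibble (see [mutation_library()]).
#' @export
read_mutation_library <- function(path) {
  raw <- read_checked(path,
    cols = c("position", "wt_residue", "allowed_substitutions"),
    numeric_cols = "position"
  )
  mutation_library(raw$position, raw$wt_residue, raw$allowed_substitutions)
}

#' Read forbidden mutation pairs from a delimited file
#'
#' Expects two columns, `mutation_a` and `mutation_b`, each holding a single
#' mutation token (e.g. `"A141N"`, `"I189Y"`). Each row forbids the two
#' substitutions from co-occurring in one mutant.
#'
#' @param path File path.
#' @return A tibble with columns `mutation_a`, `mutation_b`.
#' @export
read_exclusions <- function(path) {
  raw <- read_checked(path, cols = c("mutation_a", "mutation_b"))
  exclusion_pairs(raw$mutation_a, raw$mutation_b)
}

#' Define forbidden mutation pairs
#'
#' Pairs of substitutions whose side chains cannot be accommodated in the
#' same structure. A mutant containing both members of any pair is discarded
#' from enumeration. Which pairs are sterically incompatible is input data,
#' determined upstream by molecular modelling, not computed here.
#'
#' @param mutation_a,mutation_b Character vectors of single-mutation tokens;
#'   row i of each forms one unordered forbidden pair.
#' @return A tibble with columns `mutation_a`, `mutation_b` (validated,
#'   pair members on distinct positions).
#' @examples
#' exclusion_pairs(c("A141N", "A141Q"), c("I189Y", "I189Y"))
#' @export
exclusion_pairs <- function(mutation_a = character(), mutation_b = character()) {
  stopifnot(length(mutation_a) == length(mutation_b))
  for (i in seq_along(mutation_a)) {
    pa <- parse_mutant(mutation_a[[i]])
    pb <- parse_mutant(mutation_b[[i]])
    if (nrow(pa) != 1 || nrow(pb) != 1) {
      abort("Each exclusion entry must be a single mutation token.")
    }
    if (pa$position == pb$position) {
      abort(sprintf(
        "Forbidden pair %s/%s must span two distinct positions.",
        mutation_a[[i]], mutation_b[[i]]
      ))
    }
  }
  tibble::tibble(
    mutation_a = toupper(mutation_a),
    mutation_b = toupper(mutation_b)
  )
}

# Shared delimited reader with schema checking; reports offending columns
# and rows so input errors are actionable.
read_checked <- function(path, cols, numeric_cols = character()) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: missing required column(s): %s (found: %s)",
      path, paste(missing, collapse = ", "), paste(names(raw), collapse = ", ")
    ))
  }
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: non-numeric value in column '%s' at data row(s) %s",
        path, col, paste(bad, collapse = ", ")
      ))
    }
    raw[[col]] <- parsed
  }
  raw
}
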