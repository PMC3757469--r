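#' Count combination mutants of a given order
#'
#' The number of order-o mutants constructible from a library — one
#' substitution at each of o distinct positions — is the o-th elementary
#' symmetric polynomial e_o of the per-position multiplicities g_i:
#' e_1 = sum g_i, e_2 = sum_{i<j} g_i g_j, and so on. Computed by the
#' stable Newton-girard style recurrence e <- e + shift(e) * g_i, which is
#' exact for integer multiplicities.
#'
#' @param library A [mutation_library()].
#' @param order Integer vector of orders (>= 1).
#' @return Integer vector of counts; orders exceeding the number of library
#'   positions count 0 (no error — there is simply no such combination).
#' @examples
#' lib <- mutation_library(c(39, 104), c("G", "W"), c("A", "F,Q,Y"))
#' count_by_order(lib, 1:2) # 4, 3
#' @export
count_by_order <- function(library, order) {
  stopifnot(inherits(library, "mutation_library"))
  order <- as.integer(order)
  if (any(is.na(order)) || any(order < 1)) {
    abort("`order` must contain integers >= 1.")
  }
  e <- elementary_symmetric(library$multiplicity)
  vapply(order, function(o) {
    if (o > length(library$multiplicity)) 0L else as.integer(e[[o + 1]])
  }, integer(1))
}

# e_0..e_n of the multiplicities, e_0 = 1.
elementary_symmetric <- function(g) {
  e <- c(1, rep(0, length(g)))
  for (gi in g) {
    e <- e + c(0, head(e, -1)) * gi
  }
  e
}

#' Per-order census of a library
#'
#' @param library A [mutation_library()].
#' @param max_order Highest order to tabulate (default 4).
#' @return A tibble with columns `order` and `count`.
#' @export
count_table <- function(library, max_order = 4L) {
  orders <- seq_len(max_order)
  tibble::tibble(order = orders, count = count_by_order(library, orders))
}

#' Enumerate all combination mutants under exclusion constraints
#'
#' Builds every mutant of order 1..`max_order` choosing at most one
#' substitution per library position, then drops any mutant containing both
#' members of a forbidden pair. Exclusions act on complete mutants only:
#' a mutant is discarded if and only if some forbidden pair is a subset of
#' its substitutions. The wild type (order 0) is a reference, never a
#' candidate, and is not emitted.
#'
#' @param library A [mutation_library()].
#' @param max_order Highest order to enumerate (default 4).
#' @param exclusions Optional tibble of forbidden pairs from
#'   [exclusion_pairs()] or [read_exclusions()].
#' @return A tibble with columns `mutant` (canonical identifier) and
#'   `order`, sorted by order then identifier; duplicate-free.
#' @examples
#' lib <- mutation_library(c(39, 278), c("G", "L"), c("A", "A"))
#' enumerate_mutants(lib, max_order = 2)
#' @export
enumerate_mutants <- function(library, max_order = 4L, exclusions = NULL) {
  stopifnot(inherits(library, "mutation_library"))
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 1) {
    abort("`max_order` must be an integer >= 1.")
  }
  tokens <- purrr::map2(
    library$position, seq_len(nrow(library)),
    function(pos, i) {
      paste0(library$wt_residue[[i]], pos, library$substitutions[[i]])
    }
  )
  n_pos <- nrow(library)
  per_order <- purrr::map(seq_len(min(max_order, n_pos)), function(o) {
    combos <- combn(n_pos, o)
    ids <- apply(combos, 2, function(idx) {
      grid <- expand.grid(tokens[idx], stringsAsFactors = FALSE)
      # positions ascending within idx, so row-wise join is canonical
      do.call(paste, c(grid, sep = "-"))
    })
    tibble::tibble(mutant = as.character(unlist(ids)), order = o)
  })
  out <- dplyr::bind_rows(per_order)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    keep <- !contains_forbidden_pair(out$mutant, exclusions)
    out <- out[keep, ]
  }
  dplyr::arrange(out, .data$order, .data$mutant)
}

# For each mutant string, TRUE if both members of any forbidden pair occur.
contains_forbidden_pair <- function(mutants, exclusions) {
  token_sets <- strsplit(mutants, "-", fixed = TRUE)
  purrr::map_lgl(token_sets, function(tk) {
    any(exclusions$mutation_a %in% tk & exclusions$mutation_b %in% tk)
  })
}

#' Count order-o combinations containing a given mutation pair
#'
#' Closed form: combinations containing both members of the pair are the
#' pair itself joined with any (order - 2)-subset of the remaining
#' positions, so the count is e_(order-2) of the remaining multiplicities.
#'
#' @param library A [mutation_library()].
#' @param pair Character vector of two mutation tokens on distinct library
#'   positions, e.g. `c("A141N", "I189Y")`.
#' @param order Integer vector of orders.
#' @return Integer vector: the number of order-o combinations containing
#'   both mutations; 0 whenever `order < 2`.
#' @examples
#' lib <- calb_mutation_library()
#' count_containing_pair(lib, c("A141N", "I189Y"), 2:4)
#' @export
count_containing_pair <- function(library, pair, order) {
  stopifnot(inherits(library, "mutation_library"), length(pair) == 2)
  parsed <- lapply(pair, parse_mutant)
  if (any(vapply(parsed, nrow, integer(1)) != 1)) {
    abort("`pair` must be two single-mutation tokens.")
  }
  pos <- vapply(parsed, function(p) p$position, integer(1))
  if (pos[[1]] == pos[[2]]) {
    abort("Pair members must sit on distinct positions.")
  }
  for (p in parsed) {
    row <- which(library$position == p$position)
    if (length(row) != 1 || !(p$new_residue %in% library$substitutions[[row]])) {
      abort(sprintf(
        "Mutation %s not present in the library.",
        paste0(p$wt_residue, p$position, p$new_residue)
      ))
    }
  }
  rest <- library$multiplicity[!(library$position %in% pos)]
  e <- elementary_symmetric(rest)
  order <- as.integer(order)
  vapply(order, function(o) {
    k <- o - 2L
    if (k < 0L || k > length(rest)) 0L else as.integer(e[[k + 1]])
  }, integer(1))
}
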