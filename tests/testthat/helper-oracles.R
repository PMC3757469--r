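# Independent oracles used to cross-check the package implementations.
# These deliberately use a different strategy from the package code:
# enumeration by full cartesian expansion over "mutate or skip" choices
# per position, and agreement counting by an explicit per-record loop.

# Every mutant of order 1..max_order from a library, by brute force.
brute_enumerate <- function(library, max_order, exclusions = NULL) {
  options_per_pos <- lapply(seq_len(nrow(library)), function(i) {
    c(NA_character_, paste0(
      library$wt_residue[[i]], library$position[[i]],
      library$substitutions[[i]]
    ))
  })
  grid <- expand.grid(options_per_pos, stringsAsFactors = FALSE)
  ids <- apply(grid, 1, function(row) {
    tokens <- row[!is.na(row)]
    if (length(tokens) == 0) NA_character_ else paste(tokens, collapse = "-")
  })
  orders <- apply(grid, 1, function(row) sum(!is.na(row)))
  keep <- orders >= 1 & orders <= max_order
  out <- data.frame(mutant = ids[keep], order = orders[keep])
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    has_pair <- vapply(strsplit(out$mutant, "-", fixed = TRUE), function(tk) {
      any(exclusions$mutation_a %in% tk & exclusions$mutation_b %in% tk)
    }, logical(1))
    out <- out[!has_pair, ]
  }
  out[order(out$order, out$mutant), ]
}

# Agreement count by explicit per-record classification.
brute_agreement <- function(activity, barrier, cutoff,
                            improve_min = 1.2, degrade_max = 0.8) {
  n_agree <- 0L
  for (k in seq_along(activity)) {
    ef <- if (activity[[k]] >= improve_min) {
      1L
    } else if (activity[[k]] <= degrade_max) -1L else 0L
    cf <- if (barrier[[k]] >= cutoff) -1L else 1L
    if (ef != 0L && ef == cf) n_agree <- n_agree + 1L
  }
  n_agree
}

# Random small library: 2..6 positions, 1..5 substitutions each.
random_library <- function(seed) {
  set.seed(seed)
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  n_pos <- sample(2:6, 1)
  positions <- sort(sample(1:400, n_pos))
  wt <- sample(aa, n_pos, replace = TRUE)
  subs <- lapply(seq_len(n_pos), function(i) {
    g <- sample(1:5, 1)
    sample(setdiff(aa, wt[[i]]), g)
  })
  mutation_library(positions, wt, subs)
}

# A random forbidden pair drawn from a library (or NULL if impossible).
random_exclusion <- function(library) {
  if (nrow(library) < 2) {
    return(NULL)
  }
  ij <- sample(nrow(library), 2)
  tok <- function(i) {
    paste0(
      library$wt_residue[[i]], library$position[[i]],
      sample(library$substitutions[[i]], 1)
    )
  }
  exclusion_pairs(tok(ij[[1]]), tok(ij[[2]]))
}

# Set S records without the WT reference row.
set_s_records <- function() {
  dplyr::filter(calb_set_s(), mutant != "WT")
}
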