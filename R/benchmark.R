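#' Thresholds for qualitative activity classification
#'
#' Experimentally, a mutant is called improving at `improve_min` (default
#' 1.2) fold-wild-type activity or higher and degrading at `degrade_max`
#' (default 0.8) or lower; activities strictly between the two fall in a
#' neutral band, map to factor 0 and are excluded from agreement counting.
#' Computationally, a barrier at or above `barrier_cutoff` (c_S, default
#' 12.5 kcal/mol) predicts decreased activity, below it increased activity.
#'
#' @param improve_min Fold-WT threshold for the improving call (inclusive).
#' @param degrade_max Fold-WT threshold for the degrading call (inclusive).
#' @param barrier_cutoff Barrier cutoff c_S in kcal/mol (inclusive for the
#'   degrading prediction).
#' @return An object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(improve_min = 1.2, degrade_max = 0.8,
                                      barrier_cutoff = 12.5) {
  if (!(improve_min > degrade_max && degrade_max > 0)) {
    abort("Need `improve_min` > `degrade_max` > 0.")
  }
  if (!is.numeric(barrier_cutoff) || !is.finite(barrier_cutoff)) {
    abort("`barrier_cutoff` must be a finite number (kcal/mol).")
  }
  structure(
    list(
      improve_min = as.numeric(improve_min),
      degrade_max = as.numeric(degrade_max),
      barrier_cutoff = as.numeric(barrier_cutoff)
    ),
    class = "classification_thresholds"
  )
}

#' Qualitative activity factor from experimental fold-activity
#'
#' @param activity Numeric vector of fold-wild-type activities (>= 0).
#' @param thresholds A [classification_thresholds()].
#' @return Integer vector: `+1` (improving, activity >= improve_min),
#'   `-1` (degrading, activity <= degrade_max), `0` (neutral band).
#' @examples
#' experimental_factor(c(11.2, 0.8, 1.0))
#' @export
experimental_factor <- function(activity, thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (any(activity < 0, na.rm = TRUE)) {
    abort("Activities must be >= 0 (fold-wild-type).")
  }
  dplyr::case_when(
    activity >= thresholds$improve_min ~ 1L,
    activity <= thresholds$degrade_max ~ -1L,
    TRUE ~ 0L
  )
}

#' Qualitative activity factor from a computed barrier
#'
#' @param barrier Numeric vector of barriers in kcal/mol.
#' @param cutoff Barrier cutoff c_S in kcal/mol (default 12.5).
#' @return Integer vector: `-1` (predicted degrading, barrier >= cutoff)
#'   or `+1` (predicted improving, barrier < cutoff).
#' @examples
#' computational_factor(c(12.5, 7.3, 18.9))
#' @export
computational_factor <- function(barrier, cutoff = 12.5) {
  ifelse(barrier >= cutoff, -1L, 1L)
}

#' Benchmark barrier predictions against experimental activities
#'
#' Assigns experimental and computational activity factors to each record,
#' counts agreements over records with a nonzero experimental factor, and
#' evaluates two headline subgroups: the most active mutants (activity at
#' or above `high_activity_min` fold-WT) and the least active (at or below
#' `low_activity_max`).
#'
#' @param records A data frame with columns `mutant`, `activity`
#'   (fold-WT) and `barrier` (kcal/mol); e.g. [calb_set_s()] without its
#'   WT reference row.
#' @param thresholds A [classification_thresholds()].
#' @param high_activity_min,low_activity_max Subgroup thresholds in
#'   fold-WT (defaults 3.0 and 0.5).
#' @return An object of class `activity_benchmark`; see [tidy()] for the
#'   per-mutant table and [glance()] for the one-row summary.
#' @examples
#' bench <- benchmark(dplyr::filter(calb_set_s(), mutant != "WT"))
#' glance(bench)
#' @export
benchmark <- function(records, thresholds = classification_thresholds(),
                      high_activity_min = 3.0, low_activity_max = 0.5) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (!is.data.frame(records) ||
    !all(c("mutant", "activity", "barrier") %in% names(records))) {
    abort("`records` needs columns `mutant`, `activity`, `barrier`.")
  }
  if (nrow(records) == 0) {
    abort("`records` is empty.")
  }
  if (any(!is.finite(records$barrier))) {
    abort("Every record needs a finite barrier (drop the WT reference row).")
  }
  scored <- records |>
    tibble::as_tibble() |>
    dplyr::mutate(
      experimental_factor = experimental_factor(.data$activity, thresholds),
      computational_factor = computational_factor(
        .data$barrier, thresholds$barrier_cutoff
      ),
      agree = .data$experimental_factor != 0L &
        .data$experimental_factor == .data$computational_factor
    )
  neutral <- scored$experimental_factor == 0L
  if (any(neutral)) {
    inform(sprintf(
      "%d record(s) fall in the neutral activity band and are excluded from agreement counting: %s",
      sum(neutral), paste(scored$mutant[neutral], collapse = ", ")
    ))
  }
  n_scored <- sum(!neutral)
  n_agree <- sum(scored$agree)
  subgroups <- tibble::tibble(
    subgroup = c("high_activity", "low_activity"),
    threshold = c(high_activity_min, low_activity_max),
    n = c(
      sum(scored$activity >= high_activity_min),
      sum(scored$activity <= low_activity_max)
    ),
    n_correct = c(
      sum(scored$agree & scored$activity >= high_activity_min),
      sum(scored$agree & scored$activity <= low_activity_max)
    )
  )
  structure(
    list(
      records = scored,
      thresholds = thresholds,
      n_records = nrow(scored),
      n_neutral = sum(neutral),
      n_scored = n_scored,
      n_agree = n_agree,
      agreement_rate = n_agree / n_scored,
      subgroups = subgroups
    ),
    class = "activity_benchmark"
  )
}

#' @export
print.activity_benchmark <- function(x, ...) {
  cat(sprintf(
    "Activity benchmark: %d/%d correct (%d%%) at cutoff %.1f kcal/mol\n",
    x$n_agree, x$n_scored, round(100 * x$agreement_rate),
    x$thresholds$barrier_cutoff
  ))
  for (i in seq_len(nrow(x$subgroups))) {
    s <- x$subgroups[i, ]
    cat(sprintf(
      "  %s (%s %.1f fold-WT): %d/%d correct\n",
      s$subgroup, if (s$subgroup == "high_activity") ">=" else "<=",
      s$threshold, s$n_correct, s$n
    ))
  }
  if (x$n_neutral > 0) {
    cat(sprintf("  %d neutral record(s) excluded\n", x$n_neutral))
  }
  invisible(x)
}

#' @rdname benchmark
#' @param x An `activity_benchmark` object.
#' @param ... Unused.
#' @export
tidy.activity_benchmark <- function(x, ...) {
  dplyr::select(
    x$records, "mutant", "activity", "barrier",
    "experimental_factor", "computational_factor", "agree"
  )
}

#' @rdname benchmark
#' @export
glance.activity_benchmark <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_scored = x$n_scored,
    n_neutral = x$n_neutral,
    n_agree = x$n_agree,
    agreement_rate = x$agreement_rate,
    agreement_percent = round(100 * x$agreement_rate),
    barrier_cutoff = x$thresholds$barrier_cutoff,
    high_activity_n = x$subgroups$n[[1]],
    high_activity_correct = x$subgroups$n_correct[[1]],
    low_activity_n = x$subgroups$n[[2]],
    low_activity_correct = x$subgroups$n_correct[[2]]
  )
}

#' Scan barrier cutoffs for maximum agreement with experiment
#'
#' Candidate cutoffs are every observed barrier value plus every midpoint
#' between adjacent distinct sorted barriers — between two candidates in
#' this grid no record changes side, so the scan is exhaustive for the
#' `barrier >= cutoff` rule. All candidates achieving the maximum
#' agreement are reported, not a single value.
#'
#' @inheritParams benchmark
#' @return An object of class `cutoff_scan` with the full scan table
#'   (via [tidy()]), `max_agreement` and `optimal_cutoffs`.
#' @examples
#' scan <- optimize_cutoff(dplyr::filter(calb_set_s(), mutant != "WT"))
#' glance(scan)
#' @export
optimize_cutoff <- function(records, thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (!is.data.frame(records) || nrow(records) < 2) {
    abort("Need at least 2 records to scan cutoffs.")
  }
  values <- sort(unique(records$barrier))
  candidates <- sort(c(values, values[-length(values)] + diff(values) / 2))
  ef <- experimental_factor(records$activity, thresholds)
  scan <- tibble::tibble(
    cutoff = candidates,
    n_agree = vapply(candidates, function(cs) {
      sum(ef != 0L & computational_factor(records$barrier, cs) == ef)
    }, integer(1))
  )
  max_agreement <- max(scan$n_agree)
  structure(
    list(
      scan = scan,
      n_scored = sum(ef != 0L),
      max_agreement = max_agreement,
      optimal_cutoffs = scan$cutoff[scan$n_agree == max_agreement]
    ),
    class = "cutoff_scan"
  )
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(
    "Cutoff scan: max agreement %d/%d (%d%%) at cutoff(s) %s kcal/mol\n",
    x$max_agreement, x$n_scored, round(100 * x$max_agreement / x$n_scored),
    paste(format(x$optimal_cutoffs), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname optimize_cutoff
#' @param x A `cutoff_scan` object.
#' @param ... Unused.
#' @export
tidy.cutoff_scan <- function(x, ...) {
  x$scan
}

#' @rdname optimize_cutoff
#' @export
glance.cutoff_scan <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$scan),
    n_scored = x$n_scored,
    max_agreement = x$max_agreement,
    max_agreement_percent = round(100 * x$max_agreement / x$n_scored),
    n_optimal_cutoffs = length(x$optimal_cutoffs)
  )
}

#' Rank kept candidates by ascending barrier
#'
#' Prospective use of the screen: choose the N mutants with the lowest
#' barriers for experimental follow-up. Ties are broken by the mutant
#' identifier string, for reproducibility.
#'
#' @param analyses A data frame with columns `mutant` and `barrier`
#'   (typically the `kept` partition from [apply_filters()] or a loaded
#'   candidate table such as [calb_set_l_top20()]).
#' @param n Number of candidates to return (>= 1). If `n` exceeds the pool
#'   size the full pool is returned with a message.
#' @return A tibble with columns `rank`, `mutant`, `barrier`, sorted by
#'   ascending barrier.
#' @examples
#' rank_candidates(calb_set_l_top20(), n = 3)
#' @export
rank_candidates <- function(analyses, n) {
  if (!is.data.frame(analyses) ||
    !all(c("mutant", "barrier") %in% names(analyses))) {
    abort("`analyses` needs columns `mutant` and `barrier`.")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) {
    abort("`n` must be an integer >= 1.")
  }
  if (n > nrow(analyses)) {
    inform(sprintf(
      "Requested %d candidates but only %d available; returning all.",
      n, nrow(analyses)
    ))
    n <- nrow(analyses)
  }
  analyses |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$barrier, .data$mutant) |>
    dplyr::slice_head(n = n) |>
    dplyr::transmute(
      rank = dplyr::row_number(), .data$mutant, .data$barrier
    )
}

#' Summarize the composition of a mutant collection
#'
#' Reports how many mutants there are of each order and, for each mutated
#' position, how many mutants carry any substitution there.
#'
#' @param mutants Character vector of mutant identifiers.
#' @param positions Optional integer vector of positions to tabulate
#'   (e.g. the library positions); defaults to every position observed.
#' @return A list of class `mutant_composition` with tibbles `orders`
#'   (`order`, `n`) and `positions` (`position`, `n`); both all-zero-free
#'   except that requested `positions` absent from the collection report 0.
#' @examples
#' composition_summary(calb_set_l_top20()$mutant)
#' @export
composition_summary <- function(mutants, positions = NULL) {
  if (length(mutants) == 0) {
    out <- list(
      n_mutants = 0L,
      orders = tibble::tibble(order = integer(), n = integer()),
      positions = tibble::tibble(
        position = as.integer(positions %||% integer()),
        n = rep(0L, length(positions %||% integer()))
      )
    )
    return(structure(out, class = "mutant_composition"))
  }
  long <- mutation_table(mutants)
  orders <- tibble::tibble(mutant = unique(canonical_mutant(mutants))) |>
    dplyr::mutate(order = mutant_order(.data$mutant)) |>
    dplyr::count(.data$order, name = "n")
  pos_counts <- long |>
    dplyr::distinct(.data$mutant, .data$position) |>
    dplyr::count(.data$position, name = "n")
  if (!is.null(positions)) {
    pos_counts <- tibble::tibble(position = as.integer(positions)) |>
      dplyr::left_join(pos_counts, by = "position") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  structure(
    list(
      n_mutants = length(unique(canonical_mutant(mutants))),
      orders = orders,
      positions = pos_counts
    ),
    class = "mutant_composition"
  )
}

#' @export
print.mutant_composition <- function(x, ...) {
  cat(sprintf("Composition of %d mutant(s)\n", x$n_mutants))
  cat("  by order: ", paste(
    sprintf("%d-fold: %d", x$orders$order, x$orders$n),
    collapse = ", "
  ), "\n", sep = "")
  cat("  by position: ", paste(
    sprintf("%d: %d", x$positions$position, x$positions$n),
    collapse = ", "
  ), "\n", sep = "")
  invisible(x)
}
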