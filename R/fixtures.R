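#' Packaged benchmark tables for the CalB amidase engineering study
#'
#' The package ships exact transcriptions (one decimal as printed) of the
#' published benchmark data for introducing amidase activity into
#' *Candida antarctica* lipase B:
#'
#' * `calb_set_s()` — the 22-mutant benchmark set S with experimental
#'   fold-wild-type amidase activities, computed reaction barriers and the
#'   expression organism (`Ao` = *Aspergillus oryzae*,
#'   `Pp` = *Pichia pastoris*), plus the WT reference row (activity 1.0,
#'   barrier 7.5 kcal/mol); 23 rows in total.
#' * `calb_mutation_library()` — the six-position substitution library for
#'   the combinatorial set L (multiplicities 1, 1, 3, 2, 5, 1).
#' * `calb_exclusions()` — the two sterically forbidden pairs
#'   (A141N–I189Y and A141Q–I189Y).
#' * `calb_set_l_top20()` — the 20 set-L candidates with the lowest
#'   computed barriers.
#'
#' @return `calb_set_s()` and `calb_set_l_top20()` return tibbles with
#'   columns `mutant`, `activity` / `barrier` (and `organism` for set S);
#'   `calb_mutation_library()` a [mutation_library()];
#'   `calb_exclusions()` an [exclusion_pairs()] tibble.
#' @examples
#' calb_mutation_library()
#' @name calb_fixtures
NULL

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "mutscreen")
  if (path == "") {
    abort(sprintf("Packaged fixture not found: %s", file))
  }
  path
}

#' @rdname calb_fixtures
#' @export
calb_set_s <- function() {
  raw <- read_checked(
    fixture_path("calb_set_s.csv"),
    cols = c("mutant", "activity_fold_wt", "barrier_kcal_mol", "organism"),
    numeric_cols = c("activity_fold_wt", "barrier_kcal_mol")
  )
  tibble::tibble(
    mutant = raw$mutant,
    activity = raw$activity_fold_wt,
    barrier = raw$barrier_kcal_mol,
    organism = raw$organism
  )
}

#' @rdname calb_fixtures
#' @export
calb_mutation_library <- function() {
  read_mutation_library(fixture_path("calb_mutation_library.tsv"))
}

#' @rdname calb_fixtures
#' @export
calb_exclusions <- function() {
  read_exclusions(fixture_path("calb_exclusions.csv"))
}

#' @rdname calb_fixtures
#' @export
calb_set_l_top20 <- function() {
  raw <- read_checked(
    fixture_path("calb_set_l_top20.csv"),
    cols = c("mutant", "barrier_kcal_mol"),
    numeric_cols = "barrier_kcal_mol"
  )
  tibble::tibble(mutant = raw$mutant, barrier = raw$barrier_kcal_mol)
}

#' Load a packaged fixture by name
#'
#' Dispatch wrapper over the `calb_*()` accessors, convenient for scripted
#' pipelines: `"set_s"`, `"library"`, `"exclusions"` or `"set_l_top20"`.
#'
#' @param name Fixture name.
#' @return The corresponding typed table; see [calb_fixtures].
#' @export
load_fixture <- function(name = c("set_s", "library", "exclusions", "set_l_top20")) {
  name <- rlang::arg_match(name)
  switch(name,
    set_s = calb_set_s(),
    library = calb_mutation_library(),
    exclusions = calb_exclusions(),
    set_l_top20 = calb_set_l_top20()
  )
}

#' Read an experimental activity table
#'
#' Expects columns `mutant`, `activity_fold_wt`, `barrier_kcal_mol` and
#' optionally `organism`; the same schema as the packaged set-S fixture.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @return A tibble with columns `mutant`, `activity`, `barrier` (and
#'   `organism` when present).
#' @export
read_activity_table <- function(path) {
  raw <- read_checked(path,
    cols = c("mutant", "activity_fold_wt", "barrier_kcal_mol"),
    numeric_cols = c("activity_fold_wt", "barrier_kcal_mol")
  )
  out <- tibble::tibble(
    mutant = raw$mutant,
    activity = raw$activity_fold_wt,
    barrier = raw$barrier_kcal_mol
  )
  if ("organism" %in% names(raw)) {
    out$organism <- raw$organism
  }
  out
}
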