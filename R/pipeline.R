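#' Pipeline configuration
#'
#' Bundles every tunable of the screening pipeline with its default:
#' classification thresholds (1.2 / 0.8 fold-WT, cutoff 12.5 kcal/mol),
#' profile filters (19.0 kcal/mol barrier maximum, 2.0 kcal/mol peak
#' similarity window), the interpolation segment count (10), the
#' enumeration order limit (4), the candidate list length (20) and the
#' seed for any synthetic generation. Unknown keys are rejected.
#'
#' @param thresholds A [classification_thresholds()].
#' @param filters A [filter_config()].
#' @param n_segments Interpolation segments per profile.
#' @param max_order Highest combination order enumerated.
#' @param ranking_n Length of the ranked candidate list.
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = classification_thresholds(),
                            filters = filter_config(),
                            n_segments = 10L, max_order = 4L,
                            ranking_n = 20L, seed = 1L) {
  stopifnot(
    inherits(thresholds, "classification_thresholds"),
    inherits(filters, "filter_config")
  )
  structure(
    list(
      thresholds = thresholds, filters = filters,
      n_segments = as.integer(n_segments), max_order = as.integer(max_order),
      ranking_n = as.integer(ranking_n), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration file
#'
#' A declarative YAML file with up to four sections — `thresholds`
#' (`improve_min`, `degrade_max`, `barrier_cutoff`), `filters`
#' (`barrier_max`, `peak_similarity_window`) and top-level `n_segments`,
#' `max_order`, `ranking_n`, `seed`. Every key is optional and defaults as
#' in [pipeline_config()]; unknown keys raise an error naming them.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c("thresholds", "filters", "n_segments", "max_order", "ranking_n", "seed")
  check_keys <- function(x, known, where) {
    unknown <- setdiff(names(x), known)
    if (length(unknown) > 0) {
      abort(sprintf(
        "%s: unknown configuration key(s) in %s: %s",
        path, where, paste(unknown, collapse = ", ")
      ))
    }
  }
  check_keys(cfg, known_top, "top level")
  check_keys(
    cfg$thresholds, c("improve_min", "degrade_max", "barrier_cutoff"),
    "`thresholds`"
  )
  check_keys(
    cfg$filters, c("barrier_max", "peak_similarity_window"), "`filters`"
  )
  th <- do.call(classification_thresholds, cfg$thresholds %||% list())
  fl <- do.call(filter_config, cfg$filters %||% list())
  pipeline_config(
    thresholds = th, filters = fl,
    n_segments = cfg$n_segments %||% 10L,
    max_order = cfg$max_order %||% 4L,
    ranking_n = cfg$ranking_n %||% 20L,
    seed = cfg$seed %||% 1L
  )
}

#' Run the full screening pipeline
#'
#' Chains the pipeline stages: enumerate the combinatorial space under
#' exclusions; analyze and filter the supplied energy profiles; rank the
#' kept candidates; and, when an experimental activity table is supplied,
#' benchmark the barrier predictions and scan the cutoff. Stages whose
#' inputs are absent are skipped with a logged note — enumeration output
#' is produced even with no profiles. Stage counts are logged in a
#' diffable `stage: count` format (possible / excluded / irregular /
#' high-barrier / kept per order).
#'
#' @param library A [mutation_library()].
#' @param exclusions Optional [exclusion_pairs()] tibble.
#' @param profiles Optional profile table (`mutant`, `frame`, `energy`).
#' @param activities Optional activity table (`mutant`, `activity`,
#'   `barrier`), e.g. [calb_set_s()] without the WT row.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes
#'   `mutants.txt` (one canonical mutant per line),
#'   `enumeration_manifest.json`, `analyses.csv`, `ranking.csv` and
#'   `benchmark.json` for the stages that ran. Reports are byte-stable
#'   across reruns (no timestamps).
#' @param quiet Suppress stage logging (default `FALSE`).
#' @return A list of class `screening_run`: `enumeration` (tibble),
#'   `manifest` (per-order bookkeeping tibble), `analyses`, `partition`,
#'   `ranking`, `benchmark`, `cutoff_scan` (NULL where skipped), `config`.
#' @examples
#' run <- run_screening(
#'   calb_mutation_library(),
#'   exclusions = calb_exclusions(),
#'   quiet = TRUE
#' )
#' run$manifest
#' @export
run_screening <- function(library, exclusions = NULL, profiles = NULL,
                          activities = NULL, config = pipeline_config(),
                          out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  possible <- count_table(library, config$max_order)
  enumeration <- enumerate_mutants(library, config$max_order, exclusions)
  kept_orders <- dplyr::count(enumeration, .data$order, name = "enumerated")
  manifest <- possible |>
    dplyr::left_join(kept_orders, by = "order") |>
    dplyr::mutate(
      enumerated = dplyr::coalesce(.data$enumerated, 0L),
      excluded_pair = .data$count - .data$enumerated
    ) |>
    dplyr::rename(possible = "count")
  for (i in seq_len(nrow(manifest))) {
    say(
      "order %d: possible %d, excluded-pair %d, enumerated %d",
      manifest$order[[i]], manifest$possible[[i]],
      manifest$excluded_pair[[i]], manifest$enumerated[[i]]
    )
  }
  say(
    "total: possible %d, enumerated %d",
    sum(manifest$possible), sum(manifest$enumerated)
  )

  analyses <- NULL
  partition <- NULL
  ranking <- NULL
  if (!is.null(profiles) && nrow(profiles) > 0) {
    analyses <- analyze_profiles(profiles, config$filters)
    partition <- apply_filters(analyses)
    say(
      "profiles: analyzed %d, inconclusive %d, high-barrier %d, kept %d",
      nrow(analyses), nrow(partition$discarded_irregular),
      nrow(partition$discarded_high_barrier), nrow(partition$kept)
    )
    if (nrow(partition$kept) > 0) {
      ranking <- rank_candidates(partition$kept, config$ranking_n)
    }
  } else {
    say("profiles: none supplied; analysis and ranking stages skipped")
  }

  bench <- NULL
  scan <- NULL
  if (!is.null(activities) && nrow(activities) > 0) {
    bench <- benchmark(activities, config$thresholds)
    scan <- optimize_cutoff(activities, config$thresholds)
    say(
      "benchmark: %d/%d correct at cutoff %.1f; scan max %d",
      bench$n_agree, bench$n_scored, config$thresholds$barrier_cutoff,
      scan$max_agreement
    )
  } else {
    say("activities: none supplied; benchmark stage skipped")
  }

  run <- structure(
    list(
      enumeration = enumeration, manifest = manifest, analyses = analyses,
      partition = partition, ranking = ranking, benchmark = bench,
      cutoff_scan = scan, config = config
    ),
    class = "screening_run"
  )
  if (!is.null(out_dir)) {
    write_screening_run(run, out_dir)
  }
  run
}

#' Write the report bundle of a screening run
#'
#' @param run A `screening_run` from [run_screening()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_screening_run <- function(run, out_dir) {
  stopifnot(inherits(run, "screening_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(out_dir, "mutants.txt")
  writeLines(run$enumeration$mutant, p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "enumeration_manifest.json")
  jsonlite::write_json(
    list(
      per_order = run$manifest,
      total_possible = sum(run$manifest$possible),
      total_enumerated = sum(run$manifest$enumerated)
    ),
    p,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, p)
  if (!is.null(run$analyses)) {
    p <- file.path(out_dir, "analyses.csv")
    readr::write_csv(run$analyses, p)
    paths <- c(paths, p)
  }
  if (!is.null(run$ranking)) {
    p <- file.path(out_dir, "ranking.csv")
    readr::write_csv(run$ranking, p)
    paths <- c(paths, p)
  }
  if (!is.null(run$benchmark)) {
    p <- file.path(out_dir, "benchmark.json")
    jsonlite::write_json(
      list(
        summary = as.list(glance(run$benchmark)),
        subgroups = run$benchmark$subgroups,
        records = tidy(run$benchmark),
        cutoff_scan = tidy(run$cutoff_scan),
        optimal_cutoffs = run$cutoff_scan$optimal_cutoffs
      ),
      p,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}
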