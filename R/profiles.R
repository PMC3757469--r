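#' Filter configuration for screening energy profiles
#'
#' Two filters remove unusable candidates from a screening set. First,
#' profiles with multiple peaks of similar height along the reaction
#' coordinate are inconclusive and discarded ("irregular"); "similar" is
#' formalized as lying within `peak_similarity_window` kcal/mol of the
#' profile's global maximum. Second, among regular profiles, barriers
#' strictly greater than `barrier_max` are discarded as non-promising
#' (the default 19.0 kcal/mol is the largest barrier retained in the
#' benchmark set, so 19.0 itself is kept).
#'
#' @param barrier_max Discard threshold in kcal/mol (strict inequality);
#'   default 19.0.
#' @param peak_similarity_window Height window in kcal/mol below the global
#'   maximum within which interior peaks count as "similar"; default 2.0.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(barrier_max = 19.0, peak_similarity_window = 2.0) {
  if (!is.numeric(barrier_max) || barrier_max <= 0) {
    abort("`barrier_max` must be positive (kcal/mol).")
  }
  if (!is.numeric(peak_similarity_window) || peak_similarity_window < 0) {
    abort("`peak_similarity_window` must be >= 0 (kcal/mol).")
  }
  structure(
    list(
      barrier_max = as.numeric(barrier_max),
      peak_similarity_window = as.numeric(peak_similarity_window)
    ),
    class = "filter_config"
  )
}

# Validate a single profile: tibble/data.frame with frame + energy columns,
# >= 3 points, strictly increasing frames starting at 0, finite energies.
check_profile <- function(profile) {
  if (!is.data.frame(profile) || !all(c("frame", "energy") %in% names(profile))) {
    abort("A profile needs columns `frame` and `energy`.")
  }
  profile <- dplyr::arrange(tibble::as_tibble(profile), frame)
  if (nrow(profile) < 3) {
    abort("A profile needs at least 3 points.")
  }
  if (profile$frame[[1]] != 0) {
    abort("Frame 0 (the ES reference) is missing from the profile.")
  }
  if (anyDuplicated(profile$frame)) {
    abort("Duplicate frame indices in profile.")
  }
  if (!all(is.finite(profile$energy))) {
    abort("Profile energies must be finite.")
  }
  profile
}

#' Reaction barrier of an energy profile
#'
#' The barrier is the highest energy on the profile minus the energy of the
#' enzyme-substrate complex (frame 0). Ties for the maximum resolve to the
#' lowest frame index.
#'
#' @param profile A data frame with columns `frame` and `energy`
#'   (kcal/mol); frame 0 must be present.
#' @return The barrier height in kcal/mol (>= 0 unless every point lies
#'   below the ES reference). The argmax frame is available via
#'   [analyze_profiles()].
#' @examples
#' barrier_height(data.frame(frame = 0:4, energy = c(0, 5, 12.5, 9, 6)))
#' @export
barrier_height <- function(profile) {
  profile <- check_profile(profile)
  max(profile$energy) - profile$energy[[1]]
}

#' Interior local maxima of an energy profile
#'
#' An interior maximum is a frame strictly between the endpoints whose
#' energy exceeds both neighbours. A plateau of equal energies flanked by
#' lower values counts once, at its first frame.
#'
#' @inheritParams barrier_height
#' @return A tibble with columns `frame` and `energy`, one row per interior
#'   maximum, in frame order.
#' @examples
#' interior_maxima(data.frame(frame = 0:4, energy = c(0, 5, 2, 6, 1)))
#' @export
interior_maxima <- function(profile) {
  profile <- check_profile(profile)
  r <- rle(profile$energy)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  hits <- which(
    seq_len(k) > 1L & seq_len(k) < k &
      r$values > c(Inf, r$values)[seq_len(k)] &
      r$values > c(r$values, Inf)[seq_len(k) + 1L]
  )
  tibble::tibble(
    frame = profile$frame[starts[hits]],
    energy = r$values[hits]
  )
}

#' Is a profile's barrier shape regular?
#'
#' A profile is irregular — inconclusive for screening — when it shows two
#' or more interior peaks of similar height, i.e. at least two interior
#' maxima within `peak_similarity_window` kcal/mol of the global maximum
#' energy. This operationalizes the visual inspection step of the original
#' workflow; plotting the profile recovers the visual criterion.
#'
#' @inheritParams barrier_height
#' @param config A [filter_config()].
#' @return `TRUE` (regular) or `FALSE` (irregular).
#' @export
classify_regularity <- function(profile, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  profile <- check_profile(profile)
  peaks <- interior_maxima(profile)
  if (nrow(peaks) < 2) {
    return(TRUE)
  }
  top <- max(profile$energy)
  sum(peaks$energy >= top - config$peak_similarity_window) < 2
}

#' Analyze a table of energy profiles
#'
#' Computes, per mutant, the barrier height, the frame of the global
#' maximum (ties to the lowest frame), the number of interior maxima and
#' the regularity verdict, then assigns a filter disposition: irregular
#' profiles are discarded first, and of the regular ones those with barrier
#' strictly above `config$barrier_max` are discarded; the rest are kept.
#'
#' @param profiles A data frame with columns `mutant`, `frame`, `energy`
#'   (kcal/mol); one table may hold many mutants.
#' @param config A [filter_config()].
#' @return A tibble with one row per mutant: `mutant`, `barrier`,
#'   `peak_frame`, `n_interior_maxima`, `regular`, `disposition` (one of
#'   `"kept"`, `"discarded_irregular"`, `"discarded_high_barrier"`).
#' @examples
#' profs <- generate_screening_set(5, irregular_fraction = 0, seed = 1)$profiles
#' analyze_profiles(profs)
#' @export
analyze_profiles <- function(profiles, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (!is.data.frame(profiles) ||
    !all(c("mutant", "frame", "energy") %in% names(profiles))) {
    abort("`profiles` needs columns `mutant`, `frame`, `energy`.")
  }
  out <- profiles |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$mutant) |>
    dplyr::group_modify(function(df, key) {
      df <- check_profile(df)
      peaks <- interior_maxima(df)
      tibble::tibble(
        barrier = max(df$energy) - df$energy[[1]],
        peak_frame = df$frame[[which.max(df$energy)]],
        n_interior_maxima = nrow(peaks),
        regular = classify_regularity(df, config)
      )
    }) |>
    dplyr::ungroup()
  out$disposition <- dplyr::case_when(
    !out$regular ~ "discarded_irregular",
    out$barrier > config$barrier_max ~ "discarded_high_barrier",
    TRUE ~ "kept"
  )
  out
}

#' Partition analyzed profiles by filter disposition
#'
#' Convenience wrapper around [analyze_profiles()] output: splits the
#' analysis table into the three disposition classes. The partition is
#' exhaustive and disjoint, and irregularity takes precedence over the
#' barrier threshold (an irregular profile with a high barrier is counted
#' once, as irregular).
#'
#' @param profiles A profile table (see [analyze_profiles()]) or an
#'   already-analyzed tibble containing a `disposition` column.
#' @param config A [filter_config()].
#' @return A named list of tibbles: `kept`, `discarded_irregular`,
#'   `discarded_high_barrier`.
#' @export
apply_filters <- function(profiles, config = filter_config()) {
  analyses <- if (is.data.frame(profiles) && "disposition" %in% names(profiles)) {
    tibble::as_tibble(profiles)
  } else {
    analyze_profiles(profiles, config)
  }
  split_by <- function(d) analyses[analyses$disposition == d, ]
  list(
    kept = split_by("kept"),
    discarded_irregular = split_by("discarded_irregular"),
    discarded_high_barrier = split_by("discarded_high_barrier")
  )
}

#' Read energy profiles from a delimited file
#'
#' Expects columns `mutant`, `frame`, `energy_kcal_mol`; one file may hold
#' many mutants.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @return A tibble with columns `mutant`, `frame`, `energy`.
#' @export
read_profiles <- function(path) {
  raw <- read_checked(path,
    cols = c("mutant", "frame", "energy_kcal_mol"),
    numeric_cols = c("frame", "energy_kcal_mol")
  )
  tibble::tibble(
    mutant = raw$mutant,
    frame = as.integer(raw$frame),
    energy = raw$energy_kcal_mol
  )
}

#' Write energy profiles to a delimited file
#'
#' Writes the same schema [read_profiles()] consumes.
#'
#' @param profiles A tibble with columns `mutant`, `frame`, `energy`.
#' @param path Output path (`.csv` or `.tsv` chooses the delimiter).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- tibble::tibble(
    mutant = profiles$mutant,
    frame = profiles$frame,
    energy_kcal_mol = profiles$energy
  )
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
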