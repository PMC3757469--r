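#' Specification of a synthetic energy profile
#'
#' Defines a profile with known ground truth so barrier extraction and
#' filtering can be tested without an external energy program. The base
#' shape is a piecewise-linear bump through three anchors: the ES reference
#' (frame 0, `baseline`), the transition peak (`peak_frame`,
#' `baseline + true_barrier`) and the TI endpoint (last frame,
#' `baseline + ti_delta`). Secondary peaks — single frames raised to a
#' stated height below the global peak — make the profile multi-peaked;
#' per-frame Gaussian noise (including frame 0, so extraction must tolerate
#' a noisy reference) makes it stochastic. This is a statistical stand-in
#' for backend output, not a physical model.
#'
#' @param true_barrier Peak height above the ES reference, kcal/mol (>= 0).
#' @param peak_frame Frame of the main peak; strictly interior
#'   (`0 < peak_frame < n_segments`).
#' @param n_segments Number of interpolation segments (default 10; the
#'   profile has `n_segments + 1` frames).
#' @param baseline ES reference energy, kcal/mol (default 0).
#' @param ti_delta TI energy above the baseline, kcal/mol; default
#'   `true_barrier / 2` (must stay below `true_barrier`).
#' @param secondary_peaks Optional data frame with columns `frame` and
#'   `depth`: each listed interior frame is raised to
#'   `depth` kcal/mol below the global peak. Secondary frames may not touch
#'   the main peak or the endpoints, and the raised value must exceed both
#'   neighbouring base values so a genuine local maximum results.
#' @param noise_sd Per-frame Gaussian noise standard deviation, kcal/mol
#'   (default 0).
#' @param seed Integer seed; generation is always seeded.
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(true_barrier, peak_frame, n_segments = 10L,
                         baseline = 0, ti_delta = true_barrier / 2,
                         secondary_peaks = NULL, noise_sd = 0, seed = 1L) {
  n_segments <- as.integer(n_segments)
  peak_frame <- as.integer(peak_frame)
  if (!is.numeric(true_barrier) || true_barrier < 0) {
    abort("`true_barrier` must be >= 0 (kcal/mol).")
  }
  if (is.na(peak_frame) || peak_frame <= 0 || peak_frame >= n_segments) {
    abort("`peak_frame` must satisfy 0 < peak_frame < n_segments.")
  }
  if (!is.numeric(ti_delta) || ti_delta >= true_barrier && true_barrier > 0) {
    abort("`ti_delta` must be below `true_barrier`.")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.")
  }
  if (!is.null(secondary_peaks)) {
    secondary_peaks <- tibble::as_tibble(secondary_peaks)
    stopifnot(all(c("frame", "depth") %in% names(secondary_peaks)))
    sf <- as.integer(secondary_peaks$frame)
    if (any(sf <= 0) || any(sf >= n_segments) || any(abs(sf - peak_frame) <= 1)) {
      abort("Secondary peaks must be interior and not adjacent to `peak_frame`.")
    }
    if (anyDuplicated(sf) || any(secondary_peaks$depth < 0)) {
      abort("Secondary peak frames must be unique with depth >= 0.")
    }
  }
  structure(
    list(
      true_barrier = as.numeric(true_barrier), peak_frame = peak_frame,
      n_segments = n_segments, baseline = as.numeric(baseline),
      ti_delta = as.numeric(ti_delta), secondary_peaks = secondary_peaks,
      noise_sd = as.numeric(noise_sd), seed = as.integer(seed)
    ),
    class = "profile_spec"
  )
}

#' Generate one synthetic energy profile
#'
#' Deterministic given the spec (identical seed, identical profile). At
#' `noise_sd = 0` the construction guarantees
#' `barrier_height()` recovers `true_barrier` exactly and the global
#' maximum sits at `peak_frame`.
#'
#' @param spec A [profile_spec()].
#' @param mutant Identifier attached to the profile rows (default
#'   `"synthetic"`).
#' @return A tibble with columns `mutant`, `frame`, `energy`.
#' @examples
#' prof <- generate_profile(profile_spec(true_barrier = 12.5, peak_frame = 5))
#' barrier_height(prof)
#' @export
generate_profile <- function(spec, mutant = "synthetic") {
  stopifnot(inherits(spec, "profile_spec"))
  frames <- 0:spec$n_segments
  peak_e <- spec$baseline + spec$true_barrier
  energy <- approx(
    x = c(0, spec$peak_frame, spec$n_segments),
    y = c(spec$baseline, peak_e, spec$baseline + spec$ti_delta),
    xout = frames
  )$y
  if (!is.null(spec$secondary_peaks)) {
    for (j in seq_len(nrow(spec$secondary_peaks))) {
      f <- as.integer(spec$secondary_peaks$frame[[j]])
      val <- peak_e - spec$secondary_peaks$depth[[j]]
      nb <- energy[c(f, f + 2)] # neighbours of frame f at indices f, f+2
      if (any(val <= nb)) {
        abort(sprintf(
          "Secondary peak at frame %d (%.2f kcal/mol) does not exceed its neighbours.",
          f, val
        ))
      }
      energy[[f + 1]] <- val
    }
  }
  if (spec$noise_sd > 0) {
    energy <- with_local_seed(
      spec$seed,
      energy + rnorm(length(energy), mean = 0, sd = spec$noise_sd)
    )
  }
  tibble::tibble(mutant = mutant, frame = frames, energy = energy)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a labelled synthetic screening set
#'
#' Draws `n` profiles with known truth. Each profile's barrier is drawn
#' from a Normal distribution (truncated to stay positive), its peak frame
#' is drawn from the interior frames, and a fraction of profiles receive a
#' secondary peak within the regularity window so they are irregular by
#' construction; the rest are single-peaked. The defaults mirror the
#' barrier range observed in a combinatorial amidase screen of a lipase
#' scaffold: most barriers between roughly 6 and 20 kcal/mol, with a
#' modest share of inconclusive multi-peaked profiles.
#'
#' @param n Number of profiles (>= 1).
#' @param irregular_fraction Expected share of irregular profiles in
#'   `[0, 1]`; default 0.15.
#' @param barrier_mean,barrier_sd Normal parameters of the true barrier in
#'   kcal/mol; defaults 13 and 3.5.
#' @param n_segments Frames per profile minus one (default 10).
#' @param noise_sd Per-frame noise, kcal/mol (default 0).
#' @param window Regularity window used to place secondary peaks, kcal/mol;
#'   keep equal to the analysis window for exact label recovery
#'   (default 2.0).
#' @param seed Integer seed (mandatory; there is no unseeded path).
#' @return A list of class `labeled_profile_set`: `profiles` (tibble
#'   `mutant`, `frame`, `energy`) and `truth` (tibble `mutant`,
#'   `true_barrier`, `peak_frame`, `regular`).
#' @examples
#' set <- generate_screening_set(10, irregular_fraction = 0.2, seed = 7)
#' dplyr::count(set$truth, regular)
#' @export
generate_screening_set <- function(n, irregular_fraction = 0.15,
                                   barrier_mean = 13, barrier_sd = 3.5,
                                   n_segments = 10L, noise_sd = 0,
                                   window = 2.0, seed) {
  stopifnot(n >= 1, irregular_fraction >= 0, irregular_fraction <= 1)
  if (missing(seed)) {
    abort("`seed` is required: generation is always seeded.")
  }
  n_segments <- as.integer(n_segments)
  if (n_segments < 5) {
    abort("`n_segments` must be >= 5 to place distinct primary and secondary peaks.")
  }
  draws <- with_local_seed(seed, {
    b <- pmax(rnorm(n, barrier_mean, barrier_sd), 1.0)
    # primary peak in the left interior leaves room for a secondary two
    # frames to its right
    peak <- (2:(n_segments - 3L))[sample.int(n_segments - 4L, n, replace = TRUE)]
    # descent of the base curve per frame right of the peak; a secondary
    # peak must stay shallower than this to be a genuine local maximum,
    # and within `window` of the top to earn the irregular label
    drop <- (b / 2) / (n_segments - peak)
    tibble::tibble(
      mutant = sprintf("synthetic_%04d", seq_len(n)),
      true_barrier = b,
      peak_frame = peak,
      irregular = stats::runif(n) < irregular_fraction,
      depth = stats::runif(n, 0.05, 0.95) * pmin(window, drop),
      profile_seed = sample.int(.Machine$integer.max, n)
    )
  })
  profiles <- purrr::pmap_dfr(draws, function(mutant, true_barrier, peak_frame,
                                              irregular, depth, profile_seed) {
    sec <- if (irregular) tibble::tibble(frame = peak_frame + 2L, depth = depth)
    spec <- profile_spec(
      true_barrier = true_barrier, peak_frame = peak_frame,
      n_segments = n_segments, secondary_peaks = sec,
      noise_sd = noise_sd, seed = profile_seed
    )
    generate_profile(spec, mutant = mutant)
  })
  truth <- tibble::tibble(
    mutant = draws$mutant,
    true_barrier = draws$true_barrier,
    peak_frame = draws$peak_frame,
    regular = !draws$irregular
  )
  structure(list(profiles = profiles, truth = truth),
    class = "labeled_profile_set"
  )
}

#' Write a labelled set as profile file plus truth-table sidecar
#'
#' @param set A `labeled_profile_set` from [generate_screening_set()].
#' @param profile_path,truth_path Output file paths (delimited text).
#' @return Invisibly, a list of both paths.
#' @export
write_labeled_set <- function(set, profile_path, truth_path) {
  stopifnot(inherits(set, "labeled_profile_set"))
  write_profiles(set$profiles, profile_path)
  delim <- if (grepl("\\.tsv$", truth_path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(set$truth, truth_path, delim = delim)
  invisible(list(profiles = profile_path, truth = truth_path))
}
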