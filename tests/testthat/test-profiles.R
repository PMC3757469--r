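profile_of <- function(energies) {
  data.frame(frame = seq_along(energies) - 1L, energy = energies)
}

test_that("barrier height is max energy minus the ES reference", {
  expect_equal(barrier_height(profile_of(c(0, 5, 12.5, 9, 6))), 12.5)
  expect_equal(barrier_height(profile_of(rep(3, 5))), 0)
  # maximum at the ES point itself
  expect_equal(barrier_height(profile_of(c(10, 4, 2))), 0)
  # invariance under adding a constant
  e <- c(0, 3, 8, 5, 2)
  expect_equal(
    barrier_height(profile_of(e)),
    barrier_height(profile_of(e + 123.4))
  )
  # validation
  expect_error(barrier_height(profile_of(c(1, 2))), "at least 3")
  expect_error(
    barrier_height(data.frame(frame = 1:4, energy = 1:4)),
    "Frame 0"
  )
  expect_error(barrier_height(profile_of(c(0, Inf, 1))), "finite")
})

test_that("interior maxima follow the strict-neighbour rule with plateau handling", {
  expect_equal(nrow(interior_maxima(profile_of(c(0, 1, 2, 3)))), 0)
  m <- interior_maxima(profile_of(c(0, 5, 2, 6, 1)))
  expect_equal(m$frame, c(1, 3))
  expect_equal(m$energy, c(5, 6))
  # plateau counts once, at its first frame
  p <- interior_maxima(profile_of(c(0, 4, 4, 0)))
  expect_equal(p$frame, 1)
  # plateau touching the boundary is not interior
  expect_equal(nrow(interior_maxima(profile_of(c(4, 4, 0)))), 0)
})

test_that("regularity formalizes 'multiple peaks of similar height'", {
  cfg <- filter_config(peak_similarity_window = 2.0)
  single <- generate_profile(profile_spec(true_barrier = 12, peak_frame = 5))
  expect_true(classify_regularity(single, cfg))
  # two interior peaks of exactly equal height
  expect_false(classify_regularity(profile_of(c(0, 7, 3, 7, 1)), cfg))
  # second peak deeper than the window
  expect_true(classify_regularity(profile_of(c(0, 10, 2, 3, 1)), cfg))
  # just inside the window
  expect_false(classify_regularity(profile_of(c(0, 10, 2, 8.5, 1)), cfg))
})

test_that("narrowing the similarity window never creates more irregular profiles", {
  set <- generate_screening_set(60,
    irregular_fraction = 0.4, noise_sd = 0.3, seed = 5
  )
  windows <- c(4, 3, 2, 1, 0.5, 0)
  n_irregular <- vapply(windows, function(w) {
    an <- analyze_profiles(set$profiles, filter_config(peak_similarity_window = w))
    sum(!an$regular)
  }, numeric(1))
  expect_true(all(diff(n_irregular) <= 0))
})

test_that("filters partition exhaustively with irregularity taking precedence", {
  cfg <- filter_config(barrier_max = 19.0)
  profiles <- dplyr::bind_rows(
    # kept: regular, exactly at the threshold (19.0 itself is retained)
    dplyr::mutate(profile_of(c(0, 19.0, 5)), mutant = "at_threshold"),
    # discarded: regular but strictly above the threshold
    dplyr::mutate(profile_of(c(0, 19.1, 5)), mutant = "too_high"),
    # irregular with a high barrier: counted once, as irregular
    dplyr::mutate(profile_of(c(0, 25, 3, 25, 1)), mutant = "double_peak")
  )
  part <- apply_filters(profiles, cfg)
  expect_equal(part$kept$mutant, "at_threshold")
  expect_equal(part$discarded_high_barrier$mutant, "too_high")
  expect_equal(part$discarded_irregular$mutant, "double_peak")
  expect_equal(
    sum(vapply(part, nrow, integer(1))),
    length(unique(profiles$mutant))
  )
})

test_that("analyze_profiles reports argmax frame with ties to the lowest frame", {
  prof <- dplyr::mutate(profile_of(c(0, 9, 3, 9, 1)), mutant = "tied")
  an <- analyze_profiles(prof)
  expect_equal(an$peak_frame, 1)
  expect_equal(an$barrier, 9)
  expect_equal(an$n_interior_maxima, 2)
})

test_that("profile files round-trip through the delimited format", {
  set <- generate_screening_set(4, irregular_fraction = 0.5, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(set$profiles, path)
  back <- read_profiles(path)
  expect_equal(back, set$profiles)
})
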