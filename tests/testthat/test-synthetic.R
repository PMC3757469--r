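test_that("noise-free generation recovers barrier and peak exactly", {
  spec <- profile_spec(true_barrier = 12.5, peak_frame = 5, noise_sd = 0)
  prof <- generate_profile(spec)
  expect_equal(nrow(prof), 11)
  expect_equal(barrier_height(prof), 12.5)
  expect_equal(prof$frame[[which.max(prof$energy)]], 5)
  expect_equal(prof$energy[[1]], 0)
  # TI endpoint sits below the peak by construction
  expect_lt(prof$energy[[11]], max(prof$energy))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- profile_spec(true_barrier = 10, peak_frame = 4, noise_sd = 1.5, seed = 77)
  expect_identical(generate_profile(spec), generate_profile(spec))
  other <- profile_spec(true_barrier = 10, peak_frame = 4, noise_sd = 1.5, seed = 78)
  expect_false(identical(generate_profile(spec), generate_profile(other)))

  s1 <- generate_screening_set(20, irregular_fraction = 0.3, noise_sd = 0.5, seed = 3)
  s2 <- generate_screening_set(20, irregular_fraction = 0.3, noise_sd = 0.5, seed = 3)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$truth, s2$truth)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_screening_set(5, seed = 9))
  expect_identical(runif(1), before)
})

test_that("secondary peaks within the window flip the regularity verdict", {
  sec <- data.frame(frame = 7, depth = 0.5)
  spec <- profile_spec(
    true_barrier = 12, peak_frame = 3,
    secondary_peaks = sec, noise_sd = 0
  )
  prof <- generate_profile(spec)
  expect_false(classify_regularity(prof, filter_config(peak_similarity_window = 2)))
  # same shape, window smaller than the depth: regular again
  expect_true(classify_regularity(prof, filter_config(peak_similarity_window = 0.2)))
  # the main barrier is unchanged by the secondary peak
  expect_equal(barrier_height(prof), 12)
})

test_that("invalid specs are rejected", {
  expect_error(profile_spec(12, peak_frame = 0), "peak_frame")
  expect_error(profile_spec(12, peak_frame = 10), "peak_frame")
  expect_error(profile_spec(-1, peak_frame = 5), "true_barrier")
  expect_error(
    profile_spec(12, 5, secondary_peaks = data.frame(frame = 6, depth = 1)),
    "adjacent"
  )
  expect_error(
    generate_profile(
      profile_spec(12, 2,
        # too deep: would sink below the descending base curve
        secondary_peaks = data.frame(frame = 8, depth = 11)
      )
    ),
    "does not exceed"
  )
  expect_error(generate_screening_set(10, irregular_fraction = 0.1), "seed")
})

test_that("screening sets carry recoverable labels and honest fractions", {
  set <- generate_screening_set(400, irregular_fraction = 0.25, seed = 21)
  expect_equal(nrow(set$truth), 400)
  share <- mean(!set$truth$regular)
  # within binomial sampling error of the requested fraction
  expect_lt(abs(share - 0.25), 4 * sqrt(0.25 * 0.75 / 400))

  an <- analyze_profiles(set$profiles)
  m <- dplyr::inner_join(an, set$truth, by = "mutant", suffix = c("", ".true"))
  expect_equal(m$regular, m$regular.true)
  expect_equal(m$barrier, m$true_barrier)
})

test_that("labelled sets round-trip through profile and truth files", {
  set <- generate_screening_set(6, irregular_fraction = 0.5, seed = 8)
  pf <- withr::local_tempfile(fileext = ".csv")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_labeled_set(set, pf, tf)
  expect_equal(read_profiles(pf), set$profiles)
  truth <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(truth$mutant, set$truth$mutant)
  expect_equal(truth$regular, set$truth$regular)
})

test_that("mean barrier error under noise stays within a few noise SDs", {
  sd <- 0.5
  set <- generate_screening_set(300, irregular_fraction = 0, noise_sd = sd, seed = 14)
  an <- analyze_profiles(set$profiles)
  m <- dplyr::inner_join(an, set$truth, by = "mutant", suffix = c("", ".true"))
  expect_lt(mean(abs(m$barrier - m$true_barrier)), 3 * sd)
})
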