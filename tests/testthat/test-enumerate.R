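test_that("count_by_order reproduces the library census", {
  lib <- calb_mutation_library()
  expect_equal(lib$multiplicity, c(1L, 1L, 3L, 2L, 5L, 1L))
  expect_equal(count_by_order(lib, 1:4), c(13L, 64L, 154L, 193L))
  expect_equal(sum(count_by_order(lib, 1:4)), 424L)

  # one position cannot host a double mutant
  one_pos <- mutation_library(10, "A", "C,D,E")
  expect_equal(count_by_order(one_pos, 2), 0L)

  # g = (2, 3): brute-force count of pairs
  two_pos <- mutation_library(c(1, 2), c("A", "G"), c("C,D", "F,H,K"))
  expect_equal(count_by_order(two_pos, 2), nrow(brute_enumerate(two_pos, 2)) -
    nrow(brute_enumerate(two_pos, 1)))
  expect_equal(count_by_order(two_pos, 2), 6L)

  # order above the position count is zero, not an error
  expect_equal(count_by_order(two_pos, 5), 0L)
  expect_error(count_by_order(two_pos, 0), ">= 1")
})

test_that("total combination count matches the product closed form", {
  for (seed in 1:5) {
    lib <- random_library(seed)
    n_pos <- nrow(lib)
    expect_equal(
      sum(count_by_order(lib, seq_len(n_pos))),
      prod(1 + lib$multiplicity) - 1
    )
  }
})

test_that("enumeration agrees with the closed-form counts and brute force", {
  for (seed in 11:20) {
    lib <- random_library(seed)
    enum <- enumerate_mutants(lib, max_order = nrow(lib))
    counts <- dplyr::count(enum, order)
    expect_equal(
      counts$n,
      count_by_order(lib, counts$order),
      info = paste("seed", seed)
    )
    oracle <- brute_enumerate(lib, nrow(lib))
    expect_equal(enum$mutant, oracle$mutant, info = paste("seed", seed))
    expect_false(any(duplicated(enum$mutant)))
  }
})

test_that("exclusions discard exactly the mutants containing a forbidden pair", {
  lib <- calb_mutation_library()
  exc <- calb_exclusions()
  enum_all <- enumerate_mutants(lib, 4)
  enum_exc <- enumerate_mutants(lib, 4, exc)
  expect_equal(nrow(enum_all), 424)
  expect_equal(nrow(enum_exc), 386)

  # inclusion-exclusion: removed set is the union over forbidden pairs
  has_pair <- vapply(strsplit(enum_all$mutant, "-", fixed = TRUE), function(tk) {
    any(exc$mutation_a %in% tk & exc$mutation_b %in% tk)
  }, logical(1))
  expect_setequal(enum_exc$mutant, enum_all$mutant[!has_pair])

  # per-order removals: 0 single, 2 double, 12 triple, 24 four-fold
  removed <- dplyr::count(enum_all[has_pair, ], order)
  expect_equal(removed$order, 2:4)
  expect_equal(removed$n, c(2L, 12L, 24L))

  # exclusion semantics also hold on random small libraries
  for (seed in 31:35) {
    rlib <- random_library(seed)
    rexc <- random_exclusion(rlib)
    got <- enumerate_mutants(rlib, nrow(rlib), rexc)
    oracle <- brute_enumerate(rlib, nrow(rlib), rexc)
    expect_equal(got$mutant, oracle$mutant, info = paste("seed", seed))
  }
})

test_that("single-position library enumerates only its singles", {
  lib <- mutation_library(7, "G", "A,S")
  enum <- enumerate_mutants(lib, max_order = 4)
  expect_equal(sort(enum$mutant), c("G7A", "G7S"))
  expect_equal(enum$order, c(1L, 1L))
})

test_that("count_containing_pair matches the published removals and brute force", {
  lib <- calb_mutation_library()
  pair_n <- c("A141N", "I189Y")
  pair_q <- c("A141Q", "I189Y")
  for (o in 2:4) {
    both <- count_containing_pair(lib, pair_n, o) +
      count_containing_pair(lib, pair_q, o)
    expect_equal(both, c(`2` = 2L, `3` = 12L, `4` = 24L)[[as.character(o)]])
  }
  expect_equal(count_containing_pair(lib, pair_n, 1), 0L)

  # brute-force cross-check for a pair of singletons
  enum <- enumerate_mutants(lib, 4)
  by_force <- sum(vapply(
    strsplit(enum$mutant[enum$order == 2], "-", fixed = TRUE),
    function(tk) all(c("G39A", "L278A") %in% tk), logical(1)
  ))
  expect_equal(count_containing_pair(lib, c("G39A", "L278A"), 2), by_force)
  expect_equal(count_containing_pair(lib, c("G39A", "L278A"), 2), 1L)

  expect_error(count_containing_pair(lib, c("G39A", "G41S"), 2), "not present")
  expect_error(count_containing_pair(lib, c("W104F", "W104Q"), 2), "distinct")
})
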