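test_that("experimental and computational factors apply the boundary rules", {
  expect_equal(experimental_factor(c(11.2, 0.8, 1.0, 1.2, 0.81)), c(1L, -1L, 0L, 1L, 0L))
  expect_error(experimental_factor(-0.1), ">= 0")
  expect_equal(computational_factor(c(12.5, 7.3, 18.9), 12.5), c(-1L, 1L, -1L))
  # monotone step functions
  acts <- seq(0, 3, by = 0.05)
  expect_true(all(diff(experimental_factor(acts)) >= 0))
  bars <- seq(5, 20, by = 0.1)
  expect_true(all(diff(computational_factor(bars, 12.5)) <= 0))
})

test_that("the set-S benchmark reproduces the published agreement", {
  records <- set_s_records()
  expect_equal(nrow(records), 22)
  bench <- benchmark(records)
  g <- glance(bench)
  expect_equal(g$n_agree, 15L)
  expect_equal(g$n_scored, 22L)
  expect_equal(g$agreement_percent, 68)
  expect_equal(g$high_activity_n, 6L)
  expect_equal(g$high_activity_correct, 4L)
  expect_equal(g$low_activity_n, 8L)
  expect_equal(g$low_activity_correct, 7L)
  # agreement equals the per-record brute-force count, in any record order
  expect_equal(g$n_agree, brute_agreement(records$activity, records$barrier, 12.5))
  shuffled <- records[sample(nrow(records)), ]
  expect_equal(benchmark(shuffled)$n_agree, 15L)
})

test_that("tidy() exposes per-mutant factors matching the published table", {
  td <- tidy(benchmark(set_s_records()))
  expect_equal(
    td$computational_factor[td$mutant == "A132N"], -1L
  )
  expect_equal(
    td$experimental_factor[td$mutant == "G39A-T103G"], -1L
  )
  row <- td[td$mutant == "G39A-T103G-L278A", ]
  expect_equal(row$experimental_factor, 1L)
  expect_equal(row$computational_factor, 1L)
  expect_true(row$agree)
})

test_that("neutral-band records are excluded from agreement but reported", {
  records <- data.frame(
    mutant = c("A1C", "C2A", "D3A"),
    activity = c(2.0, 1.0, 0.5),
    barrier = c(10, 10, 15)
  )
  expect_message(bench <- benchmark(records), "neutral")
  expect_equal(bench$n_neutral, 1L)
  expect_equal(bench$n_scored, 2L)
  expect_equal(bench$n_agree, 2L)
  expect_equal(bench$agreement_rate, 1)
})

test_that("cutoff scan finds the published optimum and beats any grid cutoff", {
  records <- set_s_records()
  scan <- optimize_cutoff(records)
  expect_equal(scan$max_agreement, 15L)
  expect_true(12.5 %in% scan$optimal_cutoffs)
  # scan optimality against a fine brute-force grid
  grid <- seq(min(records$barrier) - 1, max(records$barrier) + 1, by = 0.01)
  grid_best <- max(vapply(
    grid, function(cs) brute_agreement(records$activity, records$barrier, cs),
    integer(1)
  ))
  expect_equal(scan$max_agreement, grid_best)
})

test_that("cutoff scan handles separable and contradictory records", {
  separable <- data.frame(
    mutant = c("A1C", "C2A", "D3A", "E4A"),
    activity = c(3, 2, 0.5, 0.1),
    barrier = c(8, 9, 14, 16)
  )
  expect_equal(optimize_cutoff(separable)$max_agreement, 4L)
  contradictory <- data.frame(
    mutant = c("A1C", "C2A"),
    activity = c(3, 0.1),
    barrier = c(10, 10)
  )
  expect_equal(optimize_cutoff(contradictory)$max_agreement, 1L)
  expect_error(optimize_cutoff(contradictory[1, ]), "at least 2")
})

test_that("candidate ranking is sorted with deterministic tie-breaks", {
  top <- calb_set_l_top20()
  r3 <- rank_candidates(top, 3)
  expect_equal(r3$mutant[[1]], "G39A-T103G-I189Y")
  expect_equal(r3$barrier[[1]], 5.7)
  full <- rank_candidates(top, 20)
  expect_true(!is.unsorted(full$barrier))
  # the returned barriers are exactly the N smallest of the input multiset
  expect_equal(
    rank_candidates(top, 7)$barrier,
    sort(top$barrier)[1:7]
  )
  # ties broken by canonical mutant string
  tied <- full[full$barrier == 10.4, ]
  expect_equal(tied$mutant, sort(tied$mutant))
  expect_message(all_of_them <- rank_candidates(top, 50), "returning all")
  expect_equal(nrow(all_of_them), 20)
})

test_that("composition summaries match the published set-L breakdown", {
  lib <- calb_mutation_library()
  cs <- composition_summary(calb_set_l_top20()$mutant, positions = lib$position)
  expect_equal(cs$orders$order, c(2L, 3L, 4L))
  expect_equal(cs$orders$n, c(3L, 7L, 10L))
  expect_equal(cs$positions$n[cs$positions$position == 141], 13L)
  expect_equal(cs$positions$n[cs$positions$position == 189], 16L)
  expect_equal(cs$positions$n[cs$positions$position == 39], 19L)

  empty <- composition_summary(character(), positions = lib$position)
  expect_equal(empty$n_mutants, 0L)
  expect_equal(empty$positions$n, rep(0L, 6))
})
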