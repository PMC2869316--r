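test_that("mean length is the densitometric centre of mass", {
  expect_equal(mean_length(lane_profile(10, 1)), 10)
  expect_equal(mean_length(lane_profile(c(10, 5), c(1, 1))), 7.5)
})

test_that("mean length is invariant to global OD scaling", {
  pop <- sim_fragments(1000, seed = 4)
  lane <- render_lane(pop, seed = 4)
  for (c_ in c(0.01, 3, 1e4)) {
    scaled <- lane_profile(lane$size_kb, lane$od * c_)
    expect_equal(mean_length(scaled), mean_length(lane))
  }
})

test_that("mean length errors when no density remains", {
  lane <- lane_profile(c(10, 5), c(1, 0))
  expect_error(mean_length(lane, window = c(1, 2)))
  expect_error(mean_length(lane, baseline = 10))
})

test_that("lesions per fragment follow ML(mock)/ML(fpg) - 1", {
  lane <- render_lane(sim_fragments(500, seed = 1), seed = 1)
  est <- estimate_lesions(lane, lane)
  expect_equal(est$lesions_per_fragment, 0)
  expect_false(est$flag_negative)

  grid <- c(20, 10)
  mock <- lane_profile(grid, c(1, 0), treatment = "mock")
  fpg <- lane_profile(grid, c(0, 1), treatment = "fpg")
  est2 <- estimate_lesions(mock, fpg)
  expect_equal(est2$ml_mock, 20)
  expect_equal(est2$ml_fpg, 10)
  expect_equal(est2$lesions_per_fragment, 1)
})

test_that("densitometry-path estimate matches the fragment bookkeeping oracle", {
  # oracle: mass-weighted mean lengths computed directly on the uncut and
  # cut fragment populations, no densitometry involved
  p <- sim_lane_pair(n = 10000, rate = 0.05, efficiency = 1,
                     blur_sigma = 0, noise_sd = 0, seed = 1)
  est <- estimate_lesions(p$mock, p$fpg)
  oracle <- population_mean_length(p$pop_mock) /
    population_mean_length(p$pop_fpg) - 1
  expect_lt(abs(est$lesions_per_fragment - oracle) / oracle, 0.15)
})

test_that("negative estimates are reported raw and flagged", {
  grid <- c(20, 10)
  mock <- lane_profile(grid, c(0.4, 0.6), treatment = "mock")
  fpg <- lane_profile(grid, c(0.6, 0.4), treatment = "fpg")
  est <- estimate_lesions(mock, fpg)
  expect_lt(est$lesions_per_fragment, 0)
  expect_true(est$flag_negative)
})

test_that("mismatched lane grids are refused beyond 5%", {
  mock <- lane_profile(c(20, 10), c(1, 1))
  fpg_far <- lane_profile(c(30, 15), c(1, 1))
  expect_error(estimate_lesions(mock, fpg_far))
  # small digitization offsets are interpolated onto the mock grid
  fpg_near <- lane_profile(c(20.4, 10.2), c(1, 1))
  est <- estimate_lesions(mock, fpg_near)
  expect_equal(est$ml_fpg, 15)
})

test_that("fold change normalizes to the control", {
  mk <- function(lesions) {
    structure(list(ml_mock = 20, ml_fpg = 20 / (1 + lesions),
                   lesions_per_fragment = lesions,
                   flag_negative = lesions < 0),
              class = "lesion_estimate")
  }
  expect_equal(fold_change(mk(0.5), mk(0.5)), 1)
  expect_equal(fold_change(mk(1.0), mk(0.5)), 2)
  expect_error(fold_change(mk(0.5), mk(0)))
})

test_that("lesion density per kb divides by the undigested mean length", {
  est <- structure(list(ml_mock = 20, ml_fpg = 10,
                        lesions_per_fragment = 1, flag_negative = FALSE),
                   class = "lesion_estimate")
  expect_equal(lesions_per_kb(est), 0.05)
  est0 <- structure(list(ml_mock = 20, ml_fpg = 20,
                         lesions_per_fragment = 0, flag_negative = FALSE),
                    class = "lesion_estimate")
  expect_equal(lesions_per_kb(est0), 0)
})

test_that("estimates increase with the simulated lesion rate", {
  means <- vapply(c(0.01, 0.03, 0.05), function(r) {
    mean(vapply(1:5, function(s) {
      p <- sim_lane_pair(n = 4000, rate = r, seed = 1000 * s + round(1e4 * r))
      estimate_lesions(p$mock, p$fpg)$lesions_per_fragment
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
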