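test_that("chain yield is the product of step yields", {
  expect_equal(round_half_up(chain_yield(c(0.89, 0.9, 0.85, 0.91, 0.97,
                                           0.89)), 3), 0.535)
  expect_equal(round_half_up(chain_yield(c(0.79, 0.94, 0.72, 0.98, 0.93,
                                           0.99)), 3), 0.482)
  expect_equal(round_half_up(chain_yield(c(0.95, 0.87)), 3), 0.827)
  expect_identical(chain_yield(c(1, 1, 1)), 1)
  expect_identical(chain_yield(numeric(0)), 1)
  expect_equal(chain_yield(c(0.262144), rounding_policy("paper2dp")), 0.26)
  expect_error(chain_yield(c(0.9, 1.2)), "\\(0, 1\\]")
  expect_error(chain_yield(c(0.9, 0)), "\\(0, 1\\]")
})

test_that("weighted branch mean matches the worked convergences", {
  expect_equal(weighted_yield_mean(c(0.82, 0.65), c(1, 1)), 0.735)
  expect_equal(round_half_up(
    weighted_yield_mean(c(0.535, 0.482, 0.827), c(6, 6, 2)), 3), 0.554)
  expect_equal(weighted_yield_mean(rep(0.7, 3), c(1, 9, 2)), 0.7)
  expect_error(weighted_yield_mean(c(0.5), c(1, 2)), "equal length")
  expect_error(weighted_yield_mean(numeric(0), numeric(0)), "equal length")
  expect_error(weighted_yield_mean(c(0.5, 0.6), c(1, -1)), "positive")
})

test_that("case-study route evaluates to the published intermediates", {
  res <- overall_yield(case_study_route())
  expect_identical(res$step_count, 8L)
  expect_equal(round_half_up(100 * res$overall_yield, 1), 22.5)
  expect_equal(res$convergence_means$mean[1], 0.735)
  expect_equal(round_half_up(res$convergence_means$mean[2], 2), 0.41)
  expect_equal(round_half_up(res$modification_factors$factor[1], 3), 0.896)
  expect_equal(round_half_up(res$modification_factors$factor[2], 3), 0.539)
  expect_equal(res$efficiency, 100 * res$overall_yield / 8)
  expect_equal(round_half_up(backbone_yield(case_study_route()), 3), 0.466)
})

test_that("modification-factor method agrees with the direct method", {
  cs <- case_study_route()
  expect_equal(overall_yield_via_mf(cs), overall_yield(cs)$overall_yield,
               tolerance = 1e-12)
  expect_equal(round_half_up(100 * overall_yield_via_mf(cs), 1), 22.5)
  # printed-value cross-check of the factors themselves
  expect_equal(round_half_up(modification_factor(0.735, 0.82), 3), 0.896)
  expect_equal(round_half_up(modification_factor(0.41, 0.76), 3), 0.539)
  # a single-branch convergence contributes a factor of exactly 1
  r <- synth_route(convergence(synth_branch(synth_step("a", 0.7))),
                   synth_step("b", 0.9))
  expect_equal(overall_yield(r)$modification_factors$factor, 1)
  expect_error(modification_factor(0.5, 0), "\\(0, 1\\]")
})

test_that("evaluation of a linear route reduces to the chain product", {
  ys <- c(0.9, 0.85, 0.77, 0.93)
  r <- linear_route(ys)
  res <- overall_yield(r)
  expect_identical(res$overall_yield, chain_yield(ys))
  expect_identical(backbone_yield(r), chain_yield(ys))
  expect_identical(fictive_linear_yield(r), chain_yield(ys))
  expect_identical(overall_yield_via_mf(r), chain_yield(ys))
  expect_identical(nrow(res$convergence_means), 0L)
})

test_that("direct evaluation matches the brute-force oracle on random routes", {
  for (seed in 1:100) {
    r <- generate_random_route(seed, max_depth = 4)
    expect_equal(overall_yield(r)$overall_yield, oracle_yield(r),
                 tolerance = 1e-12)
  }
})

test_that("explicit branch weights override the step-count default", {
  r_default <- synth_route(
    convergence(synth_branch(synth_step("a", 0.9)),
                synth_branch(synth_step("b1", 0.5),
                             synth_step("b2", 0.5))),
    name = "w")
  r_explicit <- synth_route(
    convergence(synth_branch(synth_step("a", 0.9), weight = 1),
                synth_branch(synth_step("b1", 0.5), synth_step("b2", 0.5),
                             weight = 2)),
    name = "w")
  expect_equal(overall_yield(r_default)$overall_yield, (0.9 + 0.25 * 2) / 3)
  expect_equal(overall_yield(r_default)$overall_yield,
               overall_yield(r_explicit)$overall_yield)
  r_override <- synth_route(
    convergence(synth_branch(synth_step("a", 0.9), weight = 5),
                synth_branch(synth_step("b1", 0.5), synth_step("b2", 0.5))))
  expect_equal(overall_yield(r_override)$overall_yield,
               (0.9 * 5 + 0.25 * 2) / 7)
})

test_that("synthesis efficiency is yield per step on the percent scale", {
  expect_equal(synthesis_efficiency(0.9, 1), 90)
  expect_equal(signif(synthesis_efficiency(0.0075, 20), 2), 0.038)
  expect_equal(round_half_up(synthesis_efficiency(0.499, 17), 1), 2.9)
  expect_error(synthesis_efficiency(0.9, 0), "n_steps")
  expect_error(synthesis_efficiency(1.5, 2), "\\(0, 1\\]")
})

test_that("the step-count override feeds the efficiency denominator", {
  et <- et743_route()
  res <- overall_yield(et, n_steps = 17)
  expect_identical(res$step_count, 17L)
  expect_identical(res$tree_step_count, 15L)
  expect_equal(round_half_up(res$efficiency, 1), 2.9)
  expect_equal(res$overall_yield, overall_yield(et)$overall_yield)
})

test_that("fictive sequential yield never beats the branched yield", {
  et <- et743_route()
  expect_equal(round_half_up(fictive_linear_yield(et), 3), 0.192)
  for (seed in 1:100) {
    r <- generate_random_route(seed, max_depth = 4)
    fict <- fictive_linear_yield(r)
    direct <- overall_yield(r)$overall_yield
    expect_lte(fict, direct + 1e-12)
    if (!has_multi_branch_convergence(r)) {
      expect_equal(fict, direct, tolerance = 1e-12)
    }
  }
})

test_that("ratios compare yields and efficiencies", {
  expect_equal(efficiency_ratio(90, 0.75), 120)
  expect_equal(efficiency_ratio(3.2, 3.2), 1)
  expect_equal(round(efficiency_ratio(90, 0.038)), 2368)
  expect_error(efficiency_ratio(1, 0), "denominator")
})

test_that("cost estimate scales with steps and inversely with yield", {
  expect_equal(cost_estimate(1, 1, cost_params(1, 1, 0)), 1)
  expect_equal(round_half_up(cost_estimate(8, 0.225, cost_params(1, 1, 0)),
                             2), 35.56)
  base <- cost_estimate(5, 0.5, cost_params(c1 = 2, c2 = 1, C = 10))
  doubled <- cost_estimate(5, 0.5, cost_params(c1 = 4, c2 = 1, C = 10))
  expect_equal(doubled - 10, 2 * (base - 10))
  expect_error(cost_params(c2 = 0), "c2")
  expect_error(cost_estimate(5, 0, cost_params()), "overall_yield")
})

test_that("paper-display rounding policy rounds branch chain yields", {
  # heptapeptide + tripeptide fragments at a uniform 0.8:
  # full precision keeps 0.262144 and 0.64; the display policy rounds the
  # chains to 0.26 and 0.64 before the weighted mean
  r <- fragmentation_route(fragmentation_plan(rep(0.8, 8), 6, 0.8))
  full <- overall_yield(r)$overall_yield
  disp <- overall_yield(r, rounding_policy("paper2dp"))$overall_yield
  expect_equal(round_half_up(full, 3), 0.285)
  expect_equal(round_half_up(disp, 3), 0.284)
  expect_equal(disp, ((0.26 * 6 + 0.64 * 2) / 8) * 0.8)
})

test_that("invalid routes are rejected with a classed error", {
  bad <- linear_route(c(0.9, 1.5))
  expect_error(overall_yield(bad), class = "syntheff_validation_error")
  expect_error(fictive_linear_yield(bad),
               class = "syntheff_validation_error")
  expect_error(backbone_yield(bad), class = "syntheff_validation_error")
})
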