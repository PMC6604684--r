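test_that("the three decapeptide assembly strategies reproduce", {
  seq10 <- fragmentation_plan(rep(0.8, 9))
  expect_equal(round_half_up(evaluate_fragmentation(seq10), 2), 0.13)

  penta <- fragmentation_plan(rep(0.8, 8), cut_points = 4,
                              linking_yield = 0.8)
  expect_equal(round_half_up(evaluate_fragmentation(penta), 2), 0.33)

  hepta_tri <- fragmentation_plan(rep(0.8, 8), cut_points = 6,
                                  linking_yield = 0.8)
  expect_equal(round_half_up(
    evaluate_fragmentation(hepta_tri, rounding_policy("paper2dp")), 3),
    0.284)
})

test_that("fragmentation plans validate their inputs", {
  expect_error(fragmentation_plan(rep(0.8, 4), cut_points = 4,
                                  linking_yield = 0.8), "cut_points")
  expect_error(fragmentation_plan(rep(0.8, 4), cut_points = c(2, 2),
                                  linking_yield = 0.8), "cut_points")
  expect_error(fragmentation_plan(rep(0.8, 4), cut_points = 2), "linking")
  expect_error(fragmentation_plan(c(0.8, 1.1)), "\\(0, 1\\]")
  # fragment route structure: branches weighted by their step counts
  r <- fragmentation_route(fragmentation_plan(rep(0.8, 8), 6, 0.8))
  expect_identical(step_count(r), 9L)
  expect_equal(default_weights(r$elements[[1]]), c(6, 2))
})

test_that("exhaustive fragmentation ranks the symmetric split first", {
  top <- enumerate_fragmentations(rep(0.8, 8), linking_yield = 0.8,
                                  max_fragments = 2)
  expect_identical(top$cut_points[1], "4")
  expect_equal(round_half_up(top$overall_yield[1], 2), 0.33)
  # the no-cut plan is present; with the link mandated its value is the
  # plain chain yield times the linking yield
  nocut <- top[top$cut_points == "", ]
  expect_identical(nrow(nocut), 1L)
  expect_equal(nocut$overall_yield, prod(rep(0.8, 8)) * 0.8)
  # ranking is complete and sorted
  expect_identical(nrow(top), 8L)
  expect_true(all(diff(top$overall_yield) <= 0))
})

test_that("single-fragment enumeration returns only the linear case", {
  out <- enumerate_fragmentations(c(0.9, 0.8, 0.7), linking_yield = 0.95,
                                  max_fragments = 1)
  expect_identical(nrow(out), 1L)
  expect_equal(out$overall_yield, 0.9 * 0.8 * 0.7 * 0.95)
  expect_error(enumerate_fragmentations(c(0.9), 0.9), "at least two")
  expect_error(
    enumerate_fragmentations(rep(0.9, 30), 0.9, max_fragments = 15,
                             max_plans = 100),
    "cap")
})

test_that("efficiency grid matches its closed form and published cells", {
  g <- efficiency_grid()
  expect_identical(nrow(g), 50L)
  # Eff * n == y_oa at full precision for every cell
  expect_equal(g$eff_pct * g$n, g$y_oa_pct, tolerance = 1e-12)
  cell <- function(yav, n) g[g$y_av == yav & g$n == n, ]
  expect_equal(cell(0.9, 2)$y_oa_pct, 81)
  expect_identical(cell(0.9, 2)$y_oa_display, "81")
  expect_identical(cell(0.9, 2)$eff_display, "40")
  expect_identical(cell(0.95, 10)$y_oa_display, "60")
  expect_equal(as.numeric(cell(0.95, 10)$eff_display), 6)
  expect_equal(as.numeric(cell(0.6, 6)$eff_display), 0.78)
  # n = 1: efficiency equals overall yield equals the average yield
  one <- g[g$n == 1, ]
  expect_equal(one$eff_pct, one$y_oa_pct)
  expect_equal(one$y_oa_pct, 100 * one$y_av)
  # efficiency strictly decreases with n for every average yield
  for (yav in unique(g$y_av)) {
    expect_true(all(diff(g$eff_pct[g$y_av == yav][order(g$n[g$y_av ==
      yav])]) < 0))
  }
  expect_error(efficiency_grid(c(0.9, 1.2)), "\\(0, 1\\]")
  expect_error(efficiency_grid(0.9, 0), "max_steps")
})

test_that("route comparison orders by efficiency and reports ratios", {
  et <- et743_route()
  et_seq <- linear_route(leaf_yields(et), name = "et743-sequential")
  cmp <- compare_routes(list(et, et_seq))
  expect_identical(cmp$summary$name[1], "et743-ugi-4cr")
  r <- cmp$yield_ratio["et743-ugi-4cr", "et743-sequential"]
  expect_equal(round_half_up(r, 1), 2.6)
  # ratios are quotients of the reported full-precision quantities
  expect_equal(r, cmp$summary$overall_yield[1] / cmp$summary$overall_yield[2])
  expect_equal(diag(cmp$efficiency_ratio), rep(1, 2), ignore_attr = TRUE)

  same <- compare_routes(list(et, et))
  expect_true(all(abs(same$yield_ratio - 1) < 1e-12))
  expect_true(all(abs(same$efficiency_ratio - 1) < 1e-12))
  expect_error(compare_routes(list(et)), "at least two")
})

test_that("one-pot MCR vs long linear synthesis comparison", {
  mcr <- linear_route(0.9, name = "mannich-3cr")
  linear20 <- linear_route(0.0075, name = "willstaetter")
  cmp <- compare_routes(list(mcr, linear20), n_steps = c(1, 20))
  expect_equal(cmp$yield_ratio["mannich-3cr", "willstaetter"], 120)
  eff_lin <- cmp$summary$efficiency_pct[cmp$summary$name == "willstaetter"]
  expect_equal(eff_lin, 0.0375)
  # two-stage display rounding: efficiency to 2 significant figures first
  expect_equal(round(90 / signif(eff_lin, 2)), 2368)
  # and the unrounded ratio
  expect_equal(cmp$efficiency_ratio["mannich-3cr", "willstaetter"], 2400)
})
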