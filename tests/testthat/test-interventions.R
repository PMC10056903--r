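test_that("mitigation scales the targeted wild stages only", {
  dfe <- disease_free_equilibrium(baseline)
  expect_identical(apply_mitigation(dfe, mitigation_spec()), dfe)
  m <- apply_mitigation(dfe, mitigation_spec(larvae = 0.6, adults = 0.6))
  expect_equal(m[["Lu"]], 0.4 * dfe[["Lu"]])
  expect_equal(m[["Fu"]], 0.4 * dfe[["Fu"]])
  expect_equal(m[["Mu"]], 0.4 * dfe[["Mu"]])
  expect_equal(m[["Eu"]], dfe[["Eu"]]) # eggs are not targeted
  full <- apply_mitigation(dfe, mitigation_spec(1, 1))
  expect_equal(full[["Lu"]], 0)
  expect_equal(full[["Fu"]] + full[["Mu"]], 0)
  expect_equal(full[["Eu"]], dfe[["Eu"]])
})

test_that("release plans expand into equal evenly spaced batches", {
  plan <- release_plan(2, n_batches = 5, window = 60, start_day = 0)
  imp <- release_impulses(plan, Fu0_ref = 1000)
  expect_equal(imp$time, c(0, 12, 24, 36, 48))
  expect_equal(imp$Fw, rep(2 * 1000 / 5, 5))
  expect_equal(imp$Mw, imp$Fw) # equal numbers of both sexes
  expect_error(release_plan(-1), "release_factor")
  expect_error(release_plan(1, n_batches = 2.5), "round")
})

test_that("establishment verdicts bracket the no-mitigation threshold", {
  # releases far from the threshold resolve decisively
  expect_true(establishes(baseline, plan = release_plan(5)))
  expect_false(establishes(baseline, plan = release_plan(0.1)))
  # the flip sits between factors 1.11 and 1.15
  expect_false(establishes(baseline, plan = release_plan(1.11)))
  expect_true(establishes(baseline, plan = release_plan(1.15)))
  # a zero release stays at the disease-free state
  traj <- run_release(baseline, plan = release_plan(0), t_end = 500, dt = 5)
  expect_lt(female_infection_fraction(final_state(traj)), 1e-9)
})

test_that("establishment outcome is robust to tolerance tightening", {
  for (f in c(1.0, 1.3)) {
    coarse <- run_release(baseline, plan = release_plan(f), t_end = 3000,
                          dt = 15)
    tight <- run_release(baseline, plan = release_plan(f), t_end = 3000,
                         dt = 15, rtol = 1e-9, atol = 1e-7)
    expect_equal(
      female_infection_fraction(final_state(coarse)) > 0.5,
      female_infection_fraction(final_state(tight)) > 0.5
    )
  }
})

test_that("threshold release factor agrees with a coarse brute-force scan", {
  thr <- threshold_release_factor(baseline)
  # independent oracle: step the factor in 0.01 increments over a bracket
  grid <- seq(1.08, 1.18, by = 0.01)
  verdicts <- vapply(grid, function(f) {
    establishes(baseline, plan = release_plan(f))
  }, logical(1))
  expect_true(any(verdicts) && !all(verdicts))
  flip <- grid[which(verdicts)[1]]
  expect_lt(abs(thr - flip), 0.011)
  # published value to two decimals at the bisection resolution
  expect_lt(abs(thr - 1.13), 0.015)
})

test_that("mitigation lowers the release threshold monotonically", {
  thr0 <- threshold_release_factor(baseline, resolution = 0.01)
  thr_larv <- threshold_release_factor(
    baseline, mitigation_spec(larvae = 0.4), resolution = 0.01)
  thr_both <- threshold_release_factor(
    baseline, mitigation_spec(larvae = 0.6, adults = 0.4), resolution = 0.01)
  expect_gt(thr0, thr_larv)
  expect_gt(thr_larv, thr_both)
})

test_that("time-limited thresholds exceed the unlimited one", {
  unlimited <- threshold_release_factor(baseline, resolution = 0.01)
  limited60 <- threshold_release_factor(baseline, time_limit = 60,
                                        resolution = 0.05)
  limited90 <- threshold_release_factor(baseline, time_limit = 90,
                                        resolution = 0.05)
  expect_gt(limited90, unlimited)
  expect_gt(limited60, limited90)
  # published two-month value
  expect_lt(abs(limited60 - 9.9), 0.25)
})

test_that("time to 90% infection: published single-release scenarios", {
  # single release, size 2, no mitigation
  t_plain <- time_to_fraction(
    run_release(baseline, plan = release_plan(2), t_end = 300), 0.9)
  expect_lt(abs(t_plain - 143), 5)
  # same release after 60% mitigation of larvae and adults
  t_mit <- time_to_fraction(
    run_release(baseline, mitigation_spec(0.6, 0.6), release_plan(2),
                t_end = 300), 0.9)
  expect_lt(abs(t_mit - 85), 5)
  # mitigation accelerates establishment at equal release size
  expect_lt(t_mit, t_plain)
  # five batches with mitigation land near the published 109 days
  t_batch <- time_to_fraction(
    run_release(baseline, mitigation_spec(0.6, 0.6),
                release_plan(2, n_batches = 5, window = 60), t_end = 400),
    0.9)
  expect_lt(abs(t_batch - 109), 5)
})

test_that("time_to_fraction conventions", {
  cie <- complete_infection_equilibrium(baseline)
  traj <- simulate_invasion(baseline, cie, t_end = 50, dt = 1)
  expect_equal(time_to_fraction(traj, 0.9), 0)
  dying <- run_release(baseline, plan = release_plan(0.5), t_end = 400)
  expect_true(is.na(time_to_fraction(dying, 0.9)))
  # the adult metric lags the female metric (males are never released in
  # excess and dilute the infected share)
  traj2 <- run_release(baseline, plan = release_plan(2), t_end = 300)
  expect_gt(time_to_fraction(traj2, 0.9, metric = "adult"),
            time_to_fraction(traj2, 0.9, metric = "female") - 20)
})

test_that("batch spacing trade-off: optima with and without mitigation", {
  counts <- 1:5
  # without mitigation the habitat is saturated: a large release gains
  # from ~two-week spacing (the surface is nearly flat beyond 5 batches)
  plain <- batch_grid(baseline, sizes = 5, batch_counts = counts,
                      t_end = 800)
  best_plain <- plain$n_batches[which.min(plain$days_to_90)]
  expect_true(best_plain %in% c(4, 5))
  # after strong mitigation the habitat gap favours releasing everything
  # at once (size 2, the regime of the published release figures)
  mit <- batch_grid(baseline, mitigation_spec(0.6, 0.6), sizes = 2,
                    batch_counts = counts, t_end = 800)
  expect_equal(mit$n_batches[which.min(mit$days_to_90)], 1)
  # larger releases are never slower at a fixed batch count
  two_sizes <- batch_grid(baseline, sizes = c(2, 5), batch_counts = c(1, 5),
                          t_end = 800)
  wide <- tidyr::pivot_wider(two_sizes, names_from = "size",
                             values_from = "days_to_90")
  expect_true(all(wide[["5"]] <= wide[["2"]]))
})
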