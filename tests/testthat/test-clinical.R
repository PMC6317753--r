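test_that("QIDS rectifies negative mood, scales and clips", {
  traj <- data.frame(m = c(3, 0, -2, -40))
  expect_equal(qids_series(traj), c(0, 0, 2, 27))
  expect_equal(qids_series(traj, scale = 2), c(0, 0, 4, 27))
  expect_equal(qids_series(traj, clip_max = Inf), c(0, 0, 2, 40))
  expect_error(qids_series(traj, scale = -1))
})

test_that("QIDS is zero exactly when mood is non-negative", {
  traj <- simulate_mood(slow_params(1.5), constant_reality(0, 120),
                        init = c(0, -1))
  q <- qids_series(traj)
  expect_true(all(q >= 0))
  expect_identical(q > 0, traj$m < 0)
})

test_that("intermittent QIDS spikes appear under random reality", {
  r <- random_reality(2, 1, seed = 12, horizon = 150)
  traj <- simulate_mood(slow_params(1.5), r, init = c(0, 0),
                        opts = solver_options(grid_dt = 0.1))
  q <- qids_series(traj)
  runs <- rle(q > 0)
  # several separate scoring episodes with zero-score stretches between
  expect_gt(sum(runs$values), 3L)
  expect_gt(sum(!runs$values), 3L)
})

test_that("intervention constructors validate their arguments", {
  expect_error(antidepressant_mood_shift(9.2, p = 1.2), "p in")
  expect_error(antidepressant_mood_shift(9.2, p = 0), "p in")
  expect_error(lithium_reduction(27.1, fraction = 1.5))
  sched <- intervention_schedule(antidepressant_mood_shift(9.2, 0.3),
                                 lithium_reduction(30, 0.2))
  expect_s3_class(sched, "intervention_schedule")
  expect_equal(sched$time, c(9.2, 30))
  p <- slow_params(1.5)
  expect_error(
    simulate_mood(p, constant_reality(0, 10), init = c(0, -1),
                  interventions = intervention_schedule(
                    antidepressant_mood_shift(15, 0.3))),
    "inside")
})

test_that("a near-unit dose fraction leaves the trajectory almost unchanged", {
  p <- slow_params(1.5)
  base <- simulate_mood(p, constant_reality(0, 60), init = c(0, -1),
                        opts = solver_options(grid_dt = 0.1))
  treated <- simulate_mood(p, constant_reality(0, 60), init = c(0, -1),
                           opts = solver_options(grid_dt = 0.1),
                           interventions = intervention_schedule(
                             antidepressant_mood_shift(9.2, 0.999)))
  expect_lt(max(abs(base$m - treated$m)), 0.05 * max(abs(base$m)))
})

test_that("re-setting the sensitivity to its current value changes nothing", {
  p <- slow_params(1.5)
  base <- simulate_mood(p, constant_reality(0, 60), init = c(0, -1),
                        opts = solver_options(grid_dt = 0.1))
  same <- simulate_mood(p, constant_reality(0, 60), init = c(0, -1),
                        opts = solver_options(grid_dt = 0.1),
                        interventions = intervention_schedule(
                          antidepressant_sensitivity(20, 1.5 * 0.74)))
  expect_equal(base$m, same$m, tolerance = 1e-6)
})

test_that("a mood shift during a depressive episode advances the next mania", {
  p <- slow_params(1.5)
  run <- function(sched = NULL)
    simulate_mood(p, constant_reality(0, 80), init = c(0, -1),
                  opts = solver_options(grid_dt = 0.05),
                  interventions = sched)
  untreated <- run()
  strong <- run(intervention_schedule(antidepressant_mood_shift(9.2, 0.1)))
  mild <- run(intervention_schedule(antidepressant_mood_shift(9.2, 0.7)))
  t_un <- first_mood_peak(untreated, after = 9.2, min_height = 1)$time
  t_mild <- first_mood_peak(mild, after = 9.2, min_height = 1)$time
  t_strong <- first_mood_peak(strong, after = 9.2, min_height = 1)$time
  expect_lt(t_strong, t_mild)
  expect_lt(t_strong, t_un)
})

test_that("a mood shift outside a depressive episode warns", {
  p <- slow_params(1.5)
  # by t = 15 the first manic phase is under way (m > 0)
  expect_warning(
    simulate_mood(p, constant_reality(0, 40), init = c(0, -1),
                  opts = solver_options(grid_dt = 0.1),
                  interventions = intervention_schedule(
                    antidepressant_mood_shift(16, 0.5))),
    "depressive")
})

test_that("a symmetric sensitivity reduction shrinks the cycle", {
  p <- slow_params(1.5, 1.0)
  base <- simulate_mood(p, constant_reality(0, 120), init = c(0, -1),
                        opts = solver_options(grid_dt = 0.05))
  treated <- simulate_mood(p, constant_reality(0, 120), init = c(0, -1),
                           opts = solver_options(grid_dt = 0.05),
                           interventions = intervention_schedule(
                             lithium_reduction(27.1, 0.2)))
  pre <- treated[treated$time < 27.1, ]
  post <- treated[treated$time > 80, ]
  expect_lt(max(abs(post$m)), max(abs(pre$m)))
  expect_lt(max(qids_series(post)), max(qids_series(pre)))
  # no mania induced: the post-treatment maximum never exceeds the
  # untreated cycle maximum
  expect_lt(max(treated$m[treated$time > 27.1]), max(base$m))
})
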