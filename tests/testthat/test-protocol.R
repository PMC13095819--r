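test_that("competence-test schedule is balanced at every scale", {
  sch <- schedule_competence_test(seed = 1)
  expect_equal(nrow(sch$cues), 162)
  expect_equal(as.vector(table(sch$cues$label)), rep(54L, 3))
  expect_true(all(table(sch$cues$series, sch$cues$label) == 6))
  expect_equal(sch$baselines$duration, c(60, 60))
  one <- schedule_competence_test(n_series = 1, seed = 5)
  expect_equal(nrow(one$cues), 18)
  expect_equal(as.vector(table(one$cues$label)), rep(6L, 3))
})

test_that("different seeds permute cue order but never the per-series counts", {
  a <- schedule_competence_test(seed = 1)
  b <- schedule_competence_test(seed = 2)
  expect_false(identical(a$cues$label, b$cues$label))
  for (s in 1:9) {
    expect_equal(sort(a$cues$label[a$cues$series == s]),
                 sort(b$cues$label[b$cues$series == s]))
  }
  expect_identical(schedule_competence_test(seed = 1)$cues, a$cues)
})

test_that("dwell evaluation follows the hand-simulated rule", {
  # constant correct state: completes at the required hold
  ex1 <- exercise("left_hand", 3, 5)
  r1 <- evaluate_exercise(constant_stream("left_hand", 5), ex1)
  expect_true(r1$success)
  expect_equal(r1$completion_time, 3, tolerance = 0.0625 + 1e-9)
  # constant wrong state: failure, no completion time
  r2 <- evaluate_exercise(constant_stream("relax", 5), ex1)
  expect_false(r2$success)
  expect_true(is.na(r2$completion_time))
  # the three-segment example: perfect 6/3/3 script completes at 12 s
  ex3 <- exercise(c("right_hand", "relax", "left_hand"), c(6, 3, 3), 15)
  st3 <- scripted_stream(c("right_hand", "relax", "left_hand"), c(6, 3, 3))
  r3 <- evaluate_exercise(st3, ex3)
  expect_true(r3$success)
  expect_equal(r3$completion_time, 12, tolerance = 0.0625 + 1e-9)
  expect_equal(r3$achieved_holds, c(6, 3, 3), tolerance = 0.13)
})

test_that("cumulative dwell tolerates flicker; consecutive mode resets", {
  ex <- exercise("left_hand", 2, 8)
  # alternating decisions: half the dwell rate, cumulative still succeeds
  flicker <- scripted_stream(rep(c("left_hand", "relax"), 32),
                             rep(0.125, 64))
  rc <- evaluate_exercise(flicker, ex)
  expect_true(rc$success)
  expect_equal(rc$completion_time, 4, tolerance = 0.13)
  rk <- evaluate_exercise(flicker, ex, rule = "consecutive")
  expect_false(rk$success)
})

test_that("improving a decision stream never hurts the outcome", {
  ex <- exercise(c("right_hand", "relax"), c(3, 3), 10)
  noisy <- scripted_stream(c("right_hand", "relax", "right_hand", "relax"),
                           c(2, 1, 2, 5))
  better <- noisy
  # replace wrong-phase decisions with the currently required state
  better$decisions$label[better$decisions$time <= 5] <- "right_hand"
  better$decisions$label[better$decisions$time > 5] <- "relax"
  r_noisy <- evaluate_exercise(noisy, ex)
  r_better <- evaluate_exercise(better, ex)
  expect_gte(as.integer(r_better$success), as.integer(r_noisy$success))
  if (r_noisy$success && r_better$success) {
    expect_lte(r_better$completion_time, r_noisy$completion_time)
  }
})

test_that("difficulty score follows the state-count x tightness formula", {
  expect_equal(difficulty_score(exercise("relax", 3, 3)), 1)
  expect_equal(difficulty_score(
    exercise(c("right_hand", "relax", "left_hand"), c(6, 3, 3), 24)), 1.5)
  # invariant under relabeling and permutation of equal-hold segments
  expect_equal(difficulty_score(exercise(c("a", "b"), c(3, 3), 9)),
               difficulty_score(exercise(c("b", "a"), c(3, 3), 9)))
  # adding a state at a fixed hold/allotted ratio strictly increases it
  d3 <- difficulty_score(exercise(c("a", "b", "c"), c(2, 2, 2), 12))
  d4 <- difficulty_score(exercise(c("a", "b", "c", "d"), c(2, 2, 2, 2), 16))
  expect_gt(d4, d3)
})

test_that("session success rate is successes over attempts", {
  res <- list(list(success = TRUE), list(success = TRUE),
              list(success = TRUE), list(success = FALSE))
  expect_equal(session_success_rate(res), 0.75)
  expect_equal(session_success_rate(res[1:3]), 1)
  expect_error(session_success_rate(list()), "zero attempts")
})

test_that("the demo ramp raises difficulty monotonically", {
  d <- vapply(1:10, function(t) difficulty_score(ramp_exercise(t)), numeric(1))
  expect_true(all(diff(d) >= 0))
  expect_gt(d[10], d[1])
})

test_that("a short simulated course keeps success high under the ramp", {
  tc <- simulate_training_course(n_sessions = 3, exercises_per_session = 2,
                                 config = synth_eeg_config(erd_depth = 0.5,
                                                           n_series = 2),
                                 seed = 6)
  expect_gte(median(tc$sessions$success_rate), 0.70)
  expect_equal(nrow(tc$sessions), 3)
})
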