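# Exposure scenarios: window/event construction and forcing evaluation.

test_that("scenario 1: constant forcing over 336 h, no events", {
  s <- make_scenario(1, 0.35)
  expect_equal(s$duration, 336)
  expect_equal(nrow(s$events), 0)
  expect_equal(nrow(s$windows), 1)
  expect_identical(forcing_at(s, c(0, 100, 335.9)), rep(0.35, 3))
})

test_that("scenario 2: continuous stomach delivery, no forcing", {
  s <- make_scenario(2, 10)
  expect_equal(s$background_rate, 10)
  expect_equal(nrow(s$events), 0)
  expect_identical(forcing_at(s, 100), 0)
})

test_that("scenario 3: ten 6-h windows on working days", {
  s <- make_scenario(3, 0.35)
  expect_equal(nrow(s$windows), 10)
  expect_equal(s$windows$end - s$windows$start, rep(6, 10))
  # inside the first window
  expect_equal(forcing_at(s, 10), 0.35)
  # weekend gap: day 6 (t in [120, 144)) carries no exposure
  expect_identical(forcing_at(s, 130), 0)
  # right-continuity at a window edge
  expect_equal(forcing_at(s, s$windows$start[1]), 0.35)
  expect_identical(forcing_at(s, s$windows$end[1]), 0)
  # total exposure time: 10 windows x 6 h
  expect_equal(sum(s$windows$end - s$windows$start), 60)
})

test_that("scenario 4: 84 boluses, 6/day at 4-h spacing, all inside the
           window", {
  s <- make_scenario(4, 50)
  expect_equal(nrow(s$events), 84)
  expect_true(all(s$events$time >= 0 & s$events$time <= 336))
  expect_identical(unique(s$events$state), "amt_stomach_lumen")
  expect_equal(sum(s$events$increment), 84 * 50)
  per_day <- table(floor(s$events$time / 24))
  expect_identical(as.vector(per_day), rep(6L, 14))
  expect_equal(unique(diff(s$events$time[1:6])), 4)
})

test_that("construction is deterministic and validated", {
  expect_identical(make_scenario(3, 0.1), make_scenario(3, 0.1))
  expect_error(make_scenario(5, 1), "unknown scenario")
  expect_error(make_scenario(1, -1), "dose_level")
  expect_error(forcing_at(make_scenario(1, 1), -2), "t must be")
})

test_that("events export as CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(make_scenario(4, 50), f)
  ev <- utils::read.csv(f)
  expect_equal(nrow(ev), 84)
  expect_named(ev, c("time", "target_state", "increment"))
})
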