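# Timing harness: record structure, Welch comparisons, experiment
# registry.  These tests exercise the machinery at small batch sizes;
# the directional orderings at the full protocol live in the acceptance
# suite.

test_that("time_batch records the repetition protocol", {
  pop <- sample_population(population_spec(2, seed = 1))
  sch <- scenario_for(1)
  factory <- function(s) build_standalone("dcm", chem_dcm, s)
  rec <- time_batch(function() run_batch(factory, pop, sch, n_points = 20),
                    n_reps = 3, experiment = 1, variant = "standalone",
                    batch_size = 2, scenario = 1, chemical = "dcm")
  expect_s3_class(rec, "timing_record")
  expect_length(rec$batch_cpu, 3)
  expect_length(rec$solve_cpu, 3)
  expect_true(all(rec$batch_cpu >= 0))
  # solve-only span is contained in the batch span for every rep
  expect_true(all(rec$solve_cpu <= rec$batch_cpu + 0.05))
  expect_error(time_batch(function() NULL, n_reps = 1), "n_reps")
})

test_that("an empty batch still yields a valid (near-zero) record", {
  pop <- sample_population(population_spec(0, seed = 1))
  factory <- function(s) build_standalone("dcm", chem_dcm, s)
  expect_warning(
    rec <- time_batch(function() run_batch(factory, pop, scenario_for(1)),
                      n_reps = 2),
    "timer resolution")
  expect_lt(mean(rec$batch_cpu), 0.05)
})

test_that("Welch comparison flags separated samples and not identical
           ones", {
  mk <- function(times, label) structure(
    list(experiment = 1, variant = label, n_reps = length(times),
         batch_cpu = times, solve_cpu = times, batch_size = 10,
         scenario = 1, chemical = "dcm"), class = "timing_record")
  a <- mk(c(1, 1.01, 0.99, 1.02, 0.98), "a")
  self <- compare_timings(a, a)
  expect_false(self$significant)
  expect_equal(self$mean_diff, 0)
  b <- mk(c(2, 2.01, 1.99, 2.02, 1.98), "b")
  ab <- compare_timings(a, b)
  expect_true(ab$significant)
  expect_lt(ab$p_value, 0.05)
  expect_equal(ab$mean_diff, -1, tolerance = 0.01)
  # degenerate equal-constant records compare as indistinguishable
  c1 <- mk(rep(1, 4), "c1")
  expect_false(compare_timings(c1, c1)$significant)
  # mismatched conditions refuse to compare
  d <- mk(1:5, "d"); d$batch_size <- 99
  expect_error(compare_timings(a, d), "different experimental conditions")
})

test_that("the Welch null false-positive rate is near 5 percent", {
  set.seed(31)
  mk <- function(times) structure(
    list(experiment = 1, variant = "v", n_reps = length(times),
         batch_cpu = times, solve_cpu = times, batch_size = 10,
         scenario = 1, chemical = "dcm"), class = "timing_record")
  hits <- 0; n_trials <- 400
  for (i in seq_len(n_trials)) {
    a <- mk(stats::rnorm(10, 1, 0.05))
    b <- mk(stats::rnorm(10, 1, 0.05))
    if (compare_timings(a, b)$significant) hits <- hits + 1
  }
  # binomial(400, 0.05): 3 sd band around 20
  expect_gt(hits, 20 - 3 * sqrt(400 * 0.05 * 0.95))
  expect_lt(hits, 20 + 3 * sqrt(400 * 0.05 * 0.95))
})

test_that("the experiment registry builds the stated variants", {
  v6 <- .experiment_variants(6, "dcm")
  expect_named(v6, c("full", "pruned"))
  expect_equal(nrow(state_roster(v6$full$config)), 53)
  expect_equal(nrow(state_roster(v6$pruned$config, pruned = TRUE)), 34)
  v5 <- .experiment_variants(5, "cf")
  expect_length(v5, 3)                 # the three body-weight modes
  v3 <- .experiment_variants(3, "dcm")
  expect_equal(vapply(v3, function(v) v$n_points, numeric(1)),
               c(points_50 = 50, points_100 = 100, points_500 = 500))
  v8 <- .experiment_variants(8, "dcm")
  expect_named(v8, c("no_lung_ge_ss", "lung_ge_ss", "lung_ge_state"))
  expect_error(.experiment_variants(9, "dcm"), "unknown experiment")
})

test_that("run_experiment produces the stable table schema", {
  tab <- run_experiment(1, chemicals = "dcm", scenarios = 1,
                        batch_size = 2, n_reps = 2, seed = 1,
                        n_points = 20)
  expect_named(tab, c("experiment", "chemical", "scenario", "variant",
                      "mean_s", "sd_s", "n"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$mean_s >= 0))
  cmp <- attr(tab, "comparisons")
  expect_length(cmp, 1)
  expect_s3_class(cmp[[1]], "timing_comparison")
})
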