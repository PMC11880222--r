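# Virtual-population sampling: determinism, invariants, distribution
# calibration.

test_that("sampling is deterministic and subset-stable", {
  spec <- population_spec(50, seed = 11)
  p1 <- sample_population(spec)
  p2 <- sample_population(spec)
  expect_identical(p1, p2)
  expect_length(p1, 50)
  # subject i does not depend on n
  p3 <- sample_population(population_spec(10, seed = 11))
  expect_identical(p1[[7]], p3[[7]])
  # different seed, different sample
  p4 <- sample_population(population_spec(10, seed = 12))
  expect_false(identical(p3[[1]], p4[[1]]))
})

test_that("every subject satisfies the physiology invariants", {
  pop <- sample_population(population_spec(200, seed = 3))
  ffk <- paste0("flow_fraction_",
                c("fat", "liver", "kidney", "richly", "slowly", "skin",
                  "stomach", "intestine", "lung"))
  vfk <- grep("^volume_fraction_", names(phys_ref), value = TRUE)
  for (s in pop) {
    expect_s3_class(s, "physiology_params")
    expect_gt(s[["body_weight"]], 0)
    expect_lte(sum(s[vfk]), 1)
    expect_lt(abs(sum(s[ffk]) - 1), 1e-12)
  }
})

test_that("zero spread reproduces the reference subject", {
  keys <- physiology_param_names()
  spec <- population_spec(5, seed = 1,
                          cv = stats::setNames(rep(0, length(keys)), keys))
  pop <- sample_population(spec)
  for (s in pop) {
    ff <- paste0("flow_fraction_",
                 c("fat", "liver", "kidney", "richly", "slowly", "skin",
                   "stomach", "intestine", "lung"))
    expect_equal(unclass(s)[setdiff(keys, ff)],
                 unclass(phys_ref)[setdiff(keys, ff)])
    # flow fractions renormalized to an exact unit sum
    expect_equal(sum(s[ff]), 1)
  }
})

test_that("subsetting keeps the leading records in order", {
  pop <- sample_population(population_spec(30, seed = 2))
  sub <- subset_population(pop, 10)
  expect_length(sub, 10)
  expect_identical(sub[[10]], pop[[10]])
  expect_identical(subset_population(pop, 30), pop)
  expect_length(subset_population(pop, 0), 0)
  expect_error(subset_population(pop, 31), "exceeds")
})

test_that("truncated-distribution means match their closed forms", {
  n <- 4000
  pop <- sample_population(population_spec(n, seed = 5))
  bw <- vapply(pop, function(s) s[["body_weight"]], numeric(1))
  # truncated lognormal (median 70, CV 0.2, +/- 3 SD on the log scale):
  # E = 70 * E[exp(sd*z) | |z|<=3]
  sdlog <- sqrt(log(1 + 0.2^2))
  trunc_factor <- exp(sdlog^2 / 2) *
    (stats::pnorm(3 - sdlog) - stats::pnorm(-3 - sdlog)) /
    (stats::pnorm(3) - stats::pnorm(-3))
  expect_lt(abs(mean(bw) - 70 * trunc_factor), 3 * stats::sd(bw) / sqrt(n))
  # symmetric truncated normal keeps its location (volume fraction)
  vfat <- vapply(pop, function(s) s[["volume_fraction_fat"]], numeric(1))
  expect_lt(abs(mean(vfat) - as.numeric(phys_ref["volume_fraction_fat"])),
            3 * stats::sd(vfat) / sqrt(n))
})

test_that("populations export as one row per subject", {
  pop <- sample_population(population_spec(8, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, f)
  tab <- utils::read.csv(f)
  expect_equal(nrow(tab), 8)
  expect_true("body_weight" %in% names(tab))
})

test_that("specification is validated", {
  expect_error(population_spec(10, cv = c(nonsense = 0.2)), "unknown cv")
  expect_error(population_spec(10, cv = c(body_weight = -1)), "CVs")
  expect_error(population_spec(10, family = c(body_weight = "uniform")),
               "family")
  expect_error(population_spec(-1), "n >= 0")
})
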