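# Simulation driver: grids, events, convergence, batch execution.

test_that("zero-dose scenarios stay at the origin", {
  eng <- build_engine(template_config("dcm"), chem_dcm, phys_ref)
  for (k in c(1, 4)) {
    res <- simulate_model(eng, make_scenario(k, 0), 25)
    expect_identical(max(abs(res$states)), 0)
  }
})

test_that("the output grid matches the request exactly", {
  eng <- build_standalone("dcm", chem_dcm, phys_ref)
  for (np in c(50, 100, 500)) {
    res <- simulate_model(eng, scenario_for(1), np)
    expect_length(res$time, np)
    expect_equal(res$time, seq(0, 336, length.out = np))
    expect_equal(dim(res$states), c(np, 21L))
  }
  expect_error(simulate_model(eng, scenario_for(1), 1), "n_points")
})

test_that("bolus events jump the state and the intake accumulator by
           exactly the administered mass", {
  eng <- build_engine(template_config("dcm"), chem_dcm, phys_ref)
  sch <- make_scenario(4, 50)
  # a grid point lands exactly on the first bolus (t = 2 h)
  res <- simulate_model(eng, sch, n_points = 169)   # spacing 2 h
  i_pre <- which(res$time == 0)
  i_on <- which(res$time == 2)
  expect_equal(unname(res$states[i_pre, "in_oral"]), 0)
  # recording at the bolus instant is post-event (right-continuous)
  expect_equal(unname(res$states[i_on, "in_oral"]), 50)
  # total administered mass is accounted exactly at the end
  expect_identical(unname(res$states[169, "in_oral"]), 84 * 50)
})

test_that("halving tolerances leaves terminal concentrations within
           0.01 percent", {
  for (build in list(
    function() build_engine(template_config("dcm"), chem_dcm, phys_ref),
    function() build_standalone("cf", chem_cf, phys_ref))) {
    eng <- build()
    for (k in c(1, 3)) {
      a <- simulate_model(eng, scenario_for(k), 50, solver_settings(1e-6, 1e-6))
      b <- simulate_model(eng, scenario_for(k), 50, solver_settings(1e-8, 1e-8))
      ta <- a$outputs[50, "conc_venous"]; tb <- b$outputs[50, "conc_venous"]
      expect_lt(abs(ta - tb) / max(abs(tb), 1e-12), 1e-4)
    }
  }
})

test_that("stiff and explicit methods agree within tolerance bounds", {
  eng <- build_engine(template_config("cf"), chem_cf, phys_ref)
  a <- simulate_model(eng, scenario_for(2), 50,
                      solver_settings(1e-8, 1e-8, method = "rosenbrock"))
  b <- simulate_model(eng, scenario_for(2), 50,
                      solver_settings(1e-8, 1e-8, method = "dp5"))
  expect_lt(max(abs(a$states - b$states)) / max(abs(b$states)), 1e-6)
  # the stiff method must actually be taking large steps
  expect_lt(a$diagnostics$n_steps, b$diagnostics$n_steps / 5)
})

test_that("batches preserve order, determinism and the per-subject
           contract", {
  pop <- sample_population(population_spec(3, seed = 9))
  sch <- scenario_for(1)
  factory <- function(s) build_engine(template_config("dcm"), chem_dcm, s)
  batch <- run_batch(factory, pop, sch, n_points = 20)
  expect_length(batch, 3)
  expect_gt(attr(batch, "solve_cpu"), 0)
  # identical subjects give identical results
  twice <- run_batch(factory, pop[c(1, 1)], sch, n_points = 20)
  expect_identical(twice[[1]]$states, twice[[2]]$states)
  # order-preserving: each batch element equals its solo simulation
  solo <- simulate_model(factory(pop[[2]]), sch, 20)
  expect_identical(batch[[2]]$states, solo$states)
  # single-subject batch
  expect_length(run_batch(factory, pop[1], sch, n_points = 20), 1)
})

test_that("a batch over subjects keeps mass balance below 1e-8", {
  pop <- sample_population(population_spec(25, seed = 21))
  factory <- function(s) build_engine(template_config("dcm"), chem_dcm, s)
  batch <- run_batch(factory, pop, scenario_for(1), n_points = 30)
  mb <- vapply(batch, function(r) r$diagnostics$mass_balance_rel,
               numeric(1))
  expect_lt(max(mb), 1e-8)
})

test_that("results export as wide CSV", {
  eng <- build_standalone("cf", chem_cf, phys_ref)
  res <- simulate_model(eng, scenario_for(2), 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_result(res, f)
  tab <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(tab), 12)
  expect_equal(ncol(tab), 1 + 19 + 26)
})
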