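# Stand-alone DCM/CF models: rosters, output maps, and equivalence with
# the template implementations.

test_that("stand-alone rosters and output maps have the stated sizes", {
  expect_equal(nrow(standalone_roster("dcm")), 21)
  expect_equal(nrow(standalone_roster("cf")), 19)
  expect_equal(nrow(standalone_output_map("dcm")), 22)
  expect_equal(nrow(standalone_output_map("cf")), 26)
  dcm <- build_standalone("dcm", chem_dcm, phys_ref)
  cf <- build_standalone("cf", chem_cf, phys_ref)
  expect_equal(nrow(dcm$roster), 21)
  expect_equal(nrow(cf$roster), 19)
  expect_equal(dcm$n_outputs, 22)
  expect_equal(cf$n_outputs, 26)
  expect_error(build_standalone("benzene", chem_dcm, phys_ref))
})

test_that("max_discrepancy behaves as a metric on shared outputs", {
  eng <- build_standalone("dcm", chem_dcm, phys_ref)
  a <- simulate_model(eng, scenario_for(1), 20)
  expect_identical(max_discrepancy(a, a), 0)
  b <- a
  b$outputs[, "conc_liver"] <- b$outputs[, "conc_liver"] + 0.5
  expect_equal(max_discrepancy(a, b), 0.5)
  expect_error(max_discrepancy(a, b, "no_such_output"), "not present")
  short <- simulate_model(eng, scenario_for(1), 19)
  expect_error(max_discrepancy(a, short), "grids")
})

test_that("template and stand-alone DCM agree to 1e-6 (scenario 1)", {
  tmpl <- build_engine(template_config("dcm"), chem_dcm, phys_ref)
  sa <- build_standalone("dcm", chem_dcm, phys_ref)
  a <- simulate_model(tmpl, scenario_for(1), 100, settings_tight)
  b <- simulate_model(sa, scenario_for(1), 100, settings_tight)
  shared <- intersect(colnames(a$outputs), colnames(b$outputs))
  expect_gt(length(shared), 15)        # the comparison has real content
  expect_lt(max_discrepancy(a, b), 1e-6)
  # sanity: the trajectories are not trivially zero
  expect_gt(max(a$outputs[, "conc_venous"]), 0.01)
})

test_that("stand-alone models satisfy the mass-balance invariant", {
  for (nm in c("dcm", "cf")) {
    eng <- build_standalone(nm, chemical_fixture(nm), phys_ref)
    for (k in c(1, 4)) {
      res <- simulate_model(eng, scenario_for(k), 50)
      expect_lt(res$diagnostics$mass_balance_rel, 1e-8)
    }
  }
})

test_that("stand-alone and template kinetics respond to parameters
           identically (spot check via a perturbed record)", {
  x <- unclass(chem_dcm)
  x["vmax_c_liver1"] <- 2.5; x["partition_fat"] <- 20
  chem2 <- chemical_params(x)
  tmpl <- build_engine(template_config("dcm"), chem2, phys_ref)
  sa <- build_standalone("dcm", chem2, phys_ref)
  a <- simulate_model(tmpl, scenario_for(3), 60, settings_tight)
  b <- simulate_model(sa, scenario_for(3), 60, settings_tight)
  expect_lt(max_discrepancy(a, b), 1e-6)
})
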