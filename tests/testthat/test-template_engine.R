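# The template superstructure: roster/output/conditional structure,
# elementary algebraic pieces, the derivative contract, and integration
# against a closed-form linear-system oracle.

test_that("the full roster has 53 states in the stated groups", {
  r <- state_roster()
  expect_equal(nrow(r), 53)
  expect_equal(as.vector(table(r$group)[c("compartment_amount",
                                          "cumulative_metabolism",
                                          "cumulative_intake_elimination",
                                          "auc")]),
               c(17L, 9L, 13L, 14L))
  expect_false(anyDuplicated(r$name) > 0)
})

test_that("output maps have 105 and 76 entries", {
  expect_equal(nrow(output_map()), 105)
  expect_equal(nrow(output_map(reduced = TRUE)), 76)
  expect_false(anyDuplicated(output_map()$name) > 0)
  # reduced map is an ordered subset of the full map
  expect_identical(output_map(TRUE)$name,
                   intersect(output_map()$name, output_map(TRUE)$name))
})

test_that("there are 32 conditional sites, 4 + 28", {
  cs <- conditional_sites()
  expect_equal(nrow(cs), 32)
  expect_equal(sum(cs$section == "INITIALIZE"), 4)
  expect_equal(sum(cs$section == "DYNAMICS"), 28)
  expect_false(anyDuplicated(cs$id) > 0)
})

test_that("pruning removes exactly the structurally inert states", {
  expect_equal(nrow(prune_states(template_config("full"))), 53)
  dcm <- prune_states(template_config("dcm"))
  expect_equal(nrow(dcm), 34)            # 19 of 53 removed
  cf <- prune_states(template_config("cf"))
  expect_equal(nrow(cf), 33)             # 20 of 53 removed
  # retained states keep full-roster order
  expect_identical(dcm$name, intersect(state_roster()$name, dcm$name))
  # intake/elimination accumulators are never pruned
  expect_true(all(state_roster()$name[
    state_roster()$group == "cumulative_intake_elimination"] %in% dcm$name))
})

test_that("configuration invariants are enforced", {
  expect_error(template_config("cf", gas_exchange_mode = "GE_STATE"),
               "lung_present")
  expect_error(template_config("full",
    routes = c("inhalation_open", "inhalation_closed")), "excludes")
  expect_error(template_config("cf", active_pathways = "sat_lung"),
               "inactive compartments")
  expect_error(template_config("dcm", active_compartments = "nowhere"),
               "unknown compartments")
  expect_error(template_config("full", blood_mode = "MAYBE"), "blood_mode")
})

test_that("arterial steady-state equilibrium matches direct arithmetic", {
  expect_equal(arterial_ss(0, 0, 5, 4, 10), 0)
  expect_equal(arterial_ss(1, 0.2, 5, 4, 10), 5.8 / 5.4)
  # infinite-partition limit: everything inhaled is retained
  expect_equal(arterial_ss(1, 0.2, 5, 4, 1e12),
               (5 * 1 + 4 * 0.2) / 5, tolerance = 1e-9)
  expect_error(arterial_ss(1, 0.2, 5, 4, 0), "partition")
})

test_that("venous steady-state mixing matches direct arithmetic", {
  expect_equal(venous_ss(cbind(c(3, 2), c(1, 0.5)), 5), 0.8)
  expect_equal(venous_ss(cbind(c(3, 2), c(0, 0)), 5, iv_rate = 5), 1)
  # mixing identity: equal concentrations pass through unchanged
  expect_equal(venous_ss(cbind(c(1, 2, 2), rep(0.7, 3)), 5), 0.7)
  expect_error(venous_ss(cbind(c(3, 1), c(1, 1)), 5), "sum")
})

test_that("saturable kinetics: bounds, half-saturation, arithmetic", {
  expect_equal(saturable_rate(10, 0.5, 0), 0)
  expect_equal(saturable_rate(10, 0.5, 0.5), 5)      # c = km
  expect_equal(saturable_rate(10, 0.5, 1.5), 7.5)
  cs <- seq(0, 50, by = 0.5)
  r <- saturable_rate(10, 0.5, cs)
  expect_true(all(diff(r) > 0))                      # monotone
  expect_true(all(r < 10))                           # bounded by vmax
  expect_error(saturable_rate(10, 0, 1), "km")
  expect_error(saturable_rate(10, 0.5, -1), "concentration")
})

test_that("conditional modes agree for finite operands", {
  expect_equal(evaluate_conditional(TRUE, 3.2, -1, "BRANCH"), 3.2)
  expect_equal(evaluate_conditional(TRUE, 3.2, -1, "SWITCH"), 3.2)
  expect_equal(evaluate_conditional(FALSE, 3.2, -1, "BRANCH"), -1)
  expect_equal(evaluate_conditional(FALSE, 3.2, -1, "SWITCH"), -1)
  set.seed(7)
  for (i in 1:1000) {
    a <- stats::rcauchy(1); b <- stats::rcauchy(1)
    p <- stats::runif(1) < 0.5
    expect_identical(evaluate_conditional(p, a, b, "SWITCH"),
                     evaluate_conditional(p, a, b, "BRANCH"))
  }
  expect_error(evaluate_conditional(TRUE, 1, 2, site = "no_such_site"),
               "unknown conditional site")
})

test_that("derivative contract: equilibria and hand-computed balances", {
  eng <- build_engine(template_config("dcm"), chem_dcm, phys_ref)
  n <- nrow(eng$roster)
  # origin with zero exposure is an equilibrium
  expect_identical(unname(engine_rhs(eng, 0, numeric(n))), numeric(n))
  # flow-limited equilibrium: tissue in equilibrium with arterial blood
  s <- scale_physiology(renormalize_flows(phys_ref, eng$config),
                        chem_dcm, 70)
  y <- numeric(n); names(y) <- eng$roster$name
  c_art <- 0.8
  y["amt_arterial"] <- c_art * s$volumes[["arterial"]]
  p_fat <- as.numeric(chem_dcm["partition_fat"])
  y["amt_fat"] <- c_art * p_fat * s$volumes[["fat"]]   # Cv_fat = c_art
  dy <- engine_rhs(eng, 0, y)
  expect_equal(unname(dy["amt_fat"]), 0)
  # hand-computed flow-limited balance for an out-of-equilibrium state
  y["amt_fat"] <- 2.0
  cv_fat <- 2.0 / s$volumes[["fat"]] / p_fat
  expect_equal(unname(engine_rhs(eng, 0, y)["amt_fat"]),
               s$flows[["fat"]] * (c_art - cv_fat))
  # venous balance: returns minus outflow (independent hand evaluation)
  y2 <- numeric(n); names(y2) <- eng$roster$name
  y2["amt_venous"] <- 1.3; y2["amt_liver"] <- 0.9
  cv_liv <- 0.9 / s$volumes[["liver"]] /
    as.numeric(chem_dcm["partition_liver"])
  c_ven <- 1.3 / s$volumes[["venous"]]
  c_pv <- arterial_ss(c_ven, 0, s$cardiac_output, s$alveolar_ventilation,
                      as.numeric(chem_dcm["blood_air_partition"]))
  vret <- s$flows[["liver"]] * cv_liv
  expect_equal(unname(engine_rhs(eng, 0, y2)["amt_venous"]),
               vret - s$cardiac_output * c_ven)
  expect_equal(unname(engine_rhs(eng, 0, y2)["amt_arterial"]),
               s$cardiac_output * c_pv)
  expect_error(engine_rhs(eng, 0, rep(NaN, n)), "integration-abort")
})

test_that("integration matches the matrix-exponential oracle on a
           linear configuration", {
  skip_if_not_installed("Matrix")
  # no saturable pathways -> the system is linear: y' = A y + b
  eng <- build_engine(template_config("dcm"), chem_linear, phys_ref)
  n <- nrow(eng$roster)
  cinh <- 0.35
  b <- unname(engine_rhs(eng, 0, numeric(n), c_inhaled = cinh))
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ej <- numeric(n); ej[j] <- 1
    A[, j] <- unname(engine_rhs(eng, 0, ej, c_inhaled = cinh)) - b
  }
  # y(t) = int_0^t exp(A s) b ds for y(0) = 0, via the augmented
  # matrix [[A, b], [0, 0]] (A itself is singular: accumulator states
  # never feed back)
  t_end <- 24
  M <- rbind(cbind(A, b), 0)
  y_oracle <- as.matrix(Matrix::expm(M * t_end))[seq_len(n), n + 1]
  sch <- make_scenario(1, cinh)
  for (method in c("rosenbrock", "dp5")) {
    res <- simulate_model(eng, sch, n_points = 15,
                          solver_settings(1e-10, 1e-12, method = method))
    idx <- which(abs(res$time - t_end) < 1e-9)
    expect_equal(unname(res$states[idx, ]), y_oracle, tolerance = 1e-7)
  }
})

test_that("body-weight resolution modes behave as specified", {
  tab <- data.frame(time = c(0, 100), bw = c(70, 80))
  r <- resolve_bw(50, tab, "INPUT_TABLE", phys_ref, chem_dcm)
  expect_equal(r$bw, 75)
  # clamped outside the table
  expect_equal(resolve_bw(500, tab, "INPUT_TABLE", phys_ref, chem_dcm)$bw, 80)
  expect_equal(resolve_bw(-5, tab, "INPUT_TABLE", phys_ref, chem_dcm)$bw, 70)
  # constant table: all three modes agree exactly
  ctab <- data.frame(time = c(0, 100), bw = c(72, 72))
  vals <- lapply(c("INPUT_TABLE", "FIXED_DYNAMIC", "FIXED_INIT"),
                 function(m) resolve_bw(30, ctab, m, phys_ref, chem_dcm))
  expect_equal(vals[[1]]$scaled$cardiac_output,
               vals[[2]]$scaled$cardiac_output)
  expect_identical(vals[[2]]$scaled, vals[[3]]$scaled)
  # FIXED_INIT computes the scaled set exactly once per simulation
  eng <- build_engine(template_config("dcm", bw_mode = "FIXED_INIT"),
                      chem_dcm, phys_ref)
  res <- simulate_model(eng, make_scenario(1, 0.35), 10)
  expect_equal(res$diagnostics$n_scale_calls, 1)
  # dynamic modes rescale at every derivative evaluation
  engd <- build_engine(template_config("dcm", bw_mode = "FIXED_DYNAMIC"),
                       chem_dcm, phys_ref)
  resd <- simulate_model(engd, make_scenario(1, 0.35), 10)
  expect_gt(resd$diagnostics$n_scale_calls, resd$diagnostics$n_steps)
})

test_that("compute_outputs: zero state gives zero concentrations and
           lengths match the maps", {
  eng <- build_engine(template_config("full"), chem_dcm, phys_ref)
  out <- compute_outputs(eng, 0, numeric(53))
  expect_length(out, 105)
  conc <- out[startsWith(names(out), "conc_")]
  expect_identical(unname(conc), rep(0, 17))
  engr <- build_engine(template_config("full", reduced_outputs = TRUE),
                       chem_dcm, phys_ref)
  expect_length(compute_outputs(engr, 0, numeric(53)), 76)
  # inactive compartments report zero concentration, keeping tables
  # rectangular
  engd <- build_engine(template_config("dcm"), chem_dcm, phys_ref)
  y <- numeric(nrow(engd$roster))
  y[engd$roster$name == "amt_liver"] <- 3
  out <- compute_outputs(engd, 1, y)
  expect_identical(unname(out[c("conc_kidney", "conc_skin",
                                "conc_chamber")]), rep(0, 3))
  expect_gt(out[["conc_liver"]], 0)
})
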