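# Shared fixtures: parameter records and short scenarios.  Everything is
# built in code; no binary artifacts.

chem_dcm <- chemical_fixture("dcm")
chem_cf  <- chemical_fixture("cf")
phys_ref <- physiology_fixture()

# dose levels used throughout: mg/L air for inhalation, mg/h or mg for oral
dose_for <- function(kind) if (kind %in% c(2, 4)) 50 else 0.35

scenario_for <- function(kind) make_scenario(kind, dose_for(kind))

# tight-tolerance settings used by the equivalence checks
settings_tight <- solver_settings(rtol = 1e-10, atol = 1e-10)

# a linear chemical record (no saturable pathways): closed-form solvable
chem_linear <- local({
  x <- unclass(chem_dcm)
  x[paste0("vmax_c_", c("liver1", "liver2", "lung", "kidney"))] <- 0
  chemical_params(x)
})
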