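## Template superstructure configuration: which compartments, pathways,
## routes and representation options are switched on.  The configuration
## fully determines the state roster (53 states when nothing is pruned)
## and the output map (105 quantities, or 76 in the reduced map).

.COMPARTMENT_VOCAB <- c("lung_tissue", "gas_exchange", "fat", "liver",
                        "kidney", "richly", "slowly", "skin", "stomach",
                        "intestine", "stomach_lumen", "intestine_lumen",
                        "chamber", "dermal_vehicle", "depot")
.ROUTE_VOCAB <- c("inhalation_open", "inhalation_closed", "oral",
                  "dermal", "iv")

## Tissue compartment in which each metabolic pathway is sited.
.PATHWAY_SITE <- c(sat_liver1 = "liver", sat_liver2 = "liver",
                   sat_lung = "lung_tissue", sat_kidney = "kidney",
                   fo_liver = "liver", fo_lung = "lung_tissue",
                   fo_kidney = "kidney", fo_stomach = "stomach",
                   fo_intestine = "intestine")

## Amount-state name for each compartment (canonical order; indices are
## shared with the compiled core).
.AMOUNT_STATES <- c("amt_arterial", "amt_venous", "amt_lung",
                    "amt_gas_exchange", "amt_fat", "amt_liver",
                    "amt_kidney", "amt_richly", "amt_slowly", "amt_skin",
                    "amt_stomach", "amt_intestine", "amt_stomach_lumen",
                    "amt_intestine_lumen", "amt_chamber",
                    "amt_dermal_vehicle", "amt_depot")
.METAB_STATES <- paste0("met_", .PATHWAYS)
.ROUTE_STATES <- c("in_inhaled", "in_oral", "in_dermal", "in_iv",
                   "in_depot", "out_exhaled", "out_urine", "out_feces",
                   "out_chamber_loss", "abs_stomach", "abs_intestine",
                   "abs_dermal", "met_total")
.AUC_STATES <- c("auc_arterial", "auc_venous", "auc_lung",
                 "auc_gas_exchange", "auc_fat", "auc_liver", "auc_kidney",
                 "auc_richly", "auc_slowly", "auc_skin", "auc_stomach",
                 "auc_intestine", "auc_stomach_lumen", "auc_dermal_vehicle")

#' Configure the PBPK model template superstructure
#'
#' A `template_config` selects which compartments, metabolic pathways and
#' exposure routes of the superstructure are active and which
#' representation options are used.  The three presets reproduce the two
#' chemical-specific mappings shipped with the package and the fully
#' active superstructure:
#'
#' * `"full"`: every compartment, pathway and route switched on, blood
#'   and gas-exchange region represented by state variables (nothing can
#'   be pruned; 53 states).
#' * `"dcm"`: dichloromethane mapping -- lung, fat, liver, richly and
#'   slowly perfused tissues, gas exchange by steady-state approximation,
#'   saturable + first-order metabolism in liver and lung, inhalation and
#'   oral (stomach only) routes.
#' * `"cf"`: chloroform mapping -- fat, liver, kidney, richly, slowly;
#'   no lung compartment; saturable metabolism in liver and kidney;
#'   two-segment gastrointestinal lumen with fecal elimination.
#'
#' @param model preset: `"full"`, `"dcm"` or `"cf"`.
#' @param active_compartments,active_pathways,routes character subsets of
#'   the superstructure vocabulary (override the preset).
#' @param blood_mode `"STATE_VARS"` (amounts in arterial/venous blood are
#'   state variables) or `"SS_APPROX"` (algebraic steady-state
#'   approximation).
#' @param gas_exchange_mode `"GE_SS"` (steady-state pulmonary-vein
#'   concentration) or `"GE_STATE"` (gas-exchange amount is a state
#'   variable; requires `lung_present`).
#' @param lung_present explicit lung tissue compartment present?
#' @param bw_mode `"INPUT_TABLE"` (body weight interpolated from a
#'   time table, dependents recomputed every derivative call),
#'   `"FIXED_DYNAMIC"` (constant BW, dependents still recomputed every
#'   call) or `"FIXED_INIT"` (dependents computed once per simulation).
#' @param conditional_mode `"BRANCH"` (if/else, the ternary-operator
#'   analogue) or `"SWITCH"` (multiplicative 0/1 switches).
#' @param prune drop structurally inert states from the integrated
#'   system?
#' @param reduced_outputs use the reduced 76-entry output map instead of
#'   the full 105-entry map?
#' @return object of class `template_config`.
#' @export
template_config <- function(model = c("full", "dcm", "cf"),
                            active_compartments = NULL,
                            active_pathways = NULL,
                            routes = NULL,
                            blood_mode = NULL,
                            gas_exchange_mode = NULL,
                            lung_present = NULL,
                            bw_mode = "FIXED_INIT",
                            conditional_mode = "BRANCH",
                            prune = FALSE,
                            reduced_outputs = FALSE) {
  model <- match.arg(model)
  preset <- switch(model,
    full = list(
      active_compartments = .COMPARTMENT_VOCAB,
      active_pathways = .PATHWAYS,
      routes = c("inhalation_open", "oral", "dermal", "iv"),
      blood_mode = "STATE_VARS", gas_exchange_mode = "GE_STATE",
      lung_present = TRUE),
    dcm = list(
      active_compartments = c("lung_tissue", "gas_exchange", "fat",
                              "liver", "richly", "slowly",
                              "stomach_lumen"),
      active_pathways = c("sat_liver1", "fo_liver", "sat_lung", "fo_lung"),
      routes = c("inhalation_open", "oral"),
      blood_mode = "STATE_VARS", gas_exchange_mode = "GE_SS",
      lung_present = TRUE),
    cf = list(
      active_compartments = c("gas_exchange", "fat", "liver", "kidney",
                              "richly", "slowly", "stomach_lumen",
                              "intestine_lumen"),
      active_pathways = c("sat_liver1", "sat_kidney"),
      routes = c("inhalation_open", "oral"),
      blood_mode = "STATE_VARS", gas_exchange_mode = "GE_SS",
      lung_present = FALSE))
  cfg <- structure(list(
    model = model,
    active_compartments = active_compartments %||% preset$active_compartments,
    active_pathways = active_pathways %||% preset$active_pathways,
    routes = routes %||% preset$routes,
    blood_mode = blood_mode %||% preset$blood_mode,
    gas_exchange_mode = gas_exchange_mode %||% preset$gas_exchange_mode,
    lung_present = lung_present %||% preset$lung_present,
    bw_mode = bw_mode,
    conditional_mode = conditional_mode,
    prune = prune,
    reduced_outputs = reduced_outputs
  ), class = "template_config")
  validate_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname template_config
#' @param config object to validate.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "template_config"))
  bad <- setdiff(config$active_compartments, .COMPARTMENT_VOCAB)
  if (length(bad))
    stop("unknown compartments: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(config$active_pathways, .PATHWAYS)
  if (length(bad))
    stop("unknown pathways: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(config$routes, .ROUTE_VOCAB)
  if (length(bad))
    stop("unknown routes: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!config$blood_mode %in% c("STATE_VARS", "SS_APPROX"))
    stop("blood_mode must be STATE_VARS or SS_APPROX", call. = FALSE)
  if (!config$gas_exchange_mode %in% c("GE_SS", "GE_STATE"))
    stop("gas_exchange_mode must be GE_SS or GE_STATE", call. = FALSE)
  if (!config$bw_mode %in% c("INPUT_TABLE", "FIXED_DYNAMIC", "FIXED_INIT"))
    stop("bw_mode must be INPUT_TABLE, FIXED_DYNAMIC or FIXED_INIT",
         call. = FALSE)
  if (!config$conditional_mode %in% c("BRANCH", "SWITCH"))
    stop("conditional_mode must be BRANCH or SWITCH", call. = FALSE)
  if (config$gas_exchange_mode == "GE_STATE" && !isTRUE(config$lung_present))
    stop("GE_STATE requires lung_present = TRUE", call. = FALSE)
  if (all(c("inhalation_open", "inhalation_closed") %in% config$routes))
    stop("inhalation_closed excludes inhalation_open", call. = FALSE)
  if (isTRUE(config$lung_present) &&
      !"lung_tissue" %in% config$active_compartments)
    stop("lung_present = TRUE requires the lung_tissue compartment",
         call. = FALSE)
  if (!isTRUE(config$lung_present) &&
      "lung_tissue" %in% config$active_compartments)
    stop("lung_tissue compartment active but lung_present = FALSE",
         call. = FALSE)
  site <- .PATHWAY_SITE[config$active_pathways]
  off  <- config$active_pathways[!site %in% config$active_compartments]
  if (length(off))
    stop("pathways sited in inactive compartments: ",
         paste(off, collapse = ", "), call. = FALSE)
  if (length(.perfused_from_config(config)) == 0L)
    stop("configuration has no active perfused compartments", call. = FALSE)
  config
}

#' The template state roster
#'
#' The full superstructure integrates 53 state variables: 17 compartment
#' amounts (mg), 9 cumulative-metabolism accumulators (mg), 13 cumulative
#' intake/elimination accumulators (mg) and 14 AUC accumulators
#' (mg*h/L).  With `pruned = TRUE` (or `config$prune`) the structurally
#' inert states for the given configuration are dropped, keeping the
#' full-roster order.
#'
#' @param config a [template_config()]; `NULL` means the full roster.
#' @param pruned drop structurally inert states?
#' @return data.frame with columns `name`, `group`, `units`.
#' @export
state_roster <- function(config = NULL, pruned = FALSE) {
  full <- data.frame(
    name = c(.AMOUNT_STATES, .METAB_STATES, .ROUTE_STATES, .AUC_STATES),
    group = c(rep("compartment_amount", length(.AMOUNT_STATES)),
              rep("cumulative_metabolism", length(.METAB_STATES)),
              rep("cumulative_intake_elimination", length(.ROUTE_STATES)),
              rep("auc", length(.AUC_STATES))),
    units = c(rep("mg", 17L + 9L + 13L), rep("mg*h/L", 14L)),
    stringsAsFactors = FALSE)
  if (is.null(config) || !(pruned || isTRUE(config$prune))) return(full)
  keep <- !full$name %in% .pruned_state_names(config)
  out <- full[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## States that are structurally inert under a configuration and are
## eliminated by the reduced ("pruned") template implementation:
## amounts and AUCs owned by deactivated compartments, amounts replaced
## by a steady-state algebraic representation, and metabolism
## accumulators of inactive pathways.  The 13 intake/elimination
## accumulators are never pruned: exposure routes are properties of the
## simulated scenario, not of the model structure.
.pruned_state_names <- function(config) {
  ac <- config$active_compartments
  comp_amount <- stats::setNames(.AMOUNT_STATES, c(
    "arterial", "venous", "lung_tissue", "gas_exchange", "fat", "liver",
    "kidney", "richly", "slowly", "skin", "stomach", "intestine",
    "stomach_lumen", "intestine_lumen", "chamber", "dermal_vehicle",
    "depot"))
  dropped <- character(0)
  inactive <- setdiff(names(comp_amount), c("arterial", "venous"))
  inactive <- inactive[!inactive %in% ac]
  dropped <- c(dropped, unname(comp_amount[inactive]))
  if (config$blood_mode == "SS_APPROX")
    dropped <- c(dropped, "amt_arterial", "amt_venous")
  if (config$gas_exchange_mode == "GE_SS")
    dropped <- c(dropped, "amt_gas_exchange")
  auc_owner <- c(auc_lung = "lung_tissue", auc_gas_exchange = "gas_exchange",
                 auc_fat = "fat", auc_liver = "liver", auc_kidney = "kidney",
                 auc_richly = "richly", auc_slowly = "slowly",
                 auc_skin = "skin", auc_stomach = "stomach",
                 auc_intestine = "intestine",
                 auc_stomach_lumen = "stomach_lumen",
                 auc_dermal_vehicle = "dermal_vehicle")
  dropped <- c(dropped, names(auc_owner)[!auc_owner %in% ac])
  dropped <- c(dropped,
               paste0("met_", setdiff(.PATHWAYS, config$active_pathways)))
  unique(dropped)
}

#' Structural pruning of inert states
#'
#' Returns the reduced state roster for a configuration: the states kept
#' by the "no zero states" template implementation, in full-roster
#' order.  For the shipped mappings this removes 19 of 53 states (DCM)
#' and 20 of 53 (CF).
#'
#' @param config a [template_config()].
#' @return data.frame as [state_roster()].
#' @export
prune_states <- function(config) {
  validate_config(config)
  state_roster(config, pruned = TRUE)
}

#' The template output map
#'
#' 105 named algebraic quantities computed alongside the integrated
#' states: compartment concentrations (17), venous-equilibrated tissue
#' concentrations (10), blood composites (3), air-phase concentrations
#' (3), per-pathway metabolism rates (9), per-route intake rates (5),
#' mass-balance diagnostics (4), per-kg tissue amounts (17), cumulative
#' dose fractions (10), time-weighted-average concentrations (14) and
#' scaled-parameter echoes (13).  The reduced map (76 entries) drops the
#' echoes, dose fractions, air-phase concentrations and blood composites.
#'
#' @param reduced return the 76-entry reduced map?
#' @return data.frame with columns `name`, `group`, `units`.
#' @export
output_map <- function(reduced = FALSE) {
  comp <- sub("^amt_", "", .AMOUNT_STATES)
  grp <- function(names, group, units)
    data.frame(name = names, group = group, units = units,
               stringsAsFactors = FALSE)
  full <- rbind(
    grp(paste0("conc_", comp), "compartment_concentration", "mg/L"),
    grp(c(paste0("cv_", c("fat", "liver", "kidney", "richly", "slowly",
                          "skin", "stomach", "intestine", "lung")),
          "c_pulmonary_vein"), "venous_equilibrated", "mg/L"),
    grp(c("c_arterial_blood", "c_mixed_venous", "c_blood_avg"),
        "blood_composite", "mg/L"),
    grp(c("c_inhaled_air", "c_exhaled_air", "c_chamber_air"),
        "air_phase", "mg/L"),
    grp(paste0("rate_met_", .PATHWAYS), "metabolism_rate", "mg/h"),
    grp(paste0("rate_in_", c("inhalation", "oral", "dermal", "iv",
                             "depot")), "intake_rate", "mg/h"),
    grp(c("mb_total_input", "mb_in_body", "mb_eliminated", "mb_error"),
        "mass_balance", "mg"),
    grp(paste0("perkg_", comp), "per_kg_amount", "mg/kg"),
    grp(c("frac_exhaled", "frac_metabolized", "frac_urine", "frac_feces",
          "frac_absorbed_stomach", "frac_absorbed_intestine",
          "frac_absorbed_dermal", "frac_met_liver", "frac_met_lung",
          "frac_met_kidney"), "dose_fraction", "unitless"),
    grp(paste0("twa_", sub("^auc_", "", .AUC_STATES)),
        "time_weighted_average", "mg/L"),
    grp(c("echo_bw", "echo_cardiac_output", "echo_alveolar_ventilation",
          paste0("echo_volume_", c("arterial", "venous", "lung", "fat",
                                   "liver", "kidney", "richly", "slowly",
                                   "skin")), "echo_urinary_clearance"),
        "parameter_echo", c("kg", rep("L/h", 2), rep("L", 9), "L/h")))
  if (!reduced) return(full)
  drop <- c("parameter_echo", "dose_fraction", "air_phase",
            "blood_composite")
  out <- full[!full$group %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Registry of the 32 conditional sites
#'
#' The template evaluates 32 two-way conditionals: 4 in the INITIALIZE
#' section (evaluated once per simulation) selecting the body-weight
#' source, blood representation, lung/gas-exchange representation and
#' parameter placement; and 28 in the DYNAMICS section (evaluated at
#' every step of the integration algorithm) switching the chamber mode,
#' exposure-route terms, the 9 metabolic pathways, the 10 tissue
#' compartments, body-weight interpolation and the two steady-state
#' selections.  Each site can be realized either as a branch
#' (if/else; the ternary-operator style) or as a multiplicative 0/1
#' switch -- see [evaluate_conditional()].
#'
#' @return data.frame with columns `id`, `section`, `predicate`.
#' @export
conditional_sites <- function() {
  init <- c(init_bw_source = "bw_mode == INPUT_TABLE",
            init_blood_mode = "blood_mode == SS_APPROX",
            init_lung_ge_mode = "gas_exchange_mode == GE_STATE",
            init_param_placement = "bw_mode == FIXED_INIT")
  dyn <- c(dyn_chamber_closed = "inhalation_closed in routes",
           dyn_inhalation_active = "inhalation route active",
           dyn_absorption_stomach = "oral absorption from stomach lumen",
           dyn_absorption_intestine = "oral absorption from intestine lumen",
           dyn_dermal_active = "dermal route active",
           dyn_iv_active = "iv route active",
           stats::setNames(paste0("pathway ", .PATHWAYS, " active"),
                           paste0("dyn_pathway_", .PATHWAYS)),
           stats::setNames(paste0("compartment ",
                                  c("lung_tissue", "gas_exchange", "fat",
                                    "liver", "kidney", "richly", "slowly",
                                    "skin", "stomach", "intestine"),
                                  " active"),
                           paste0("dyn_compartment_",
                                  c("lung", "gas_exchange", "fat", "liver",
                                    "kidney", "richly", "slowly", "skin",
                                    "stomach", "intestine"))),
           dyn_bw_interpolate = "bw interpolated from input table",
           dyn_blood_ss = "blood steady-state selected",
           dyn_ge_ss = "gas-exchange steady-state selected")
  data.frame(id = c(names(init), names(dyn)),
             section = c(rep("INITIALIZE", length(init)),
                         rep("DYNAMICS", length(dyn))),
             predicate = c(unname(init), unname(dyn)),
             stringsAsFactors = FALSE)
}

#' Evaluate a two-way conditional in branch or switch style
#'
#' `BRANCH` uses an if/else (the compiled core's ternary operator);
#' `SWITCH` computes `s*a + (1-s)*b` with `s` in \{0, 1\}.  For finite
#' operands the two styles return identical floating-point values, which
#' is the equivalence the conditional-implementation timing experiment
#' relies on.
#'
#' @param predicate_value logical scalar.
#' @param a,b the two candidate values (finite numerics).
#' @param mode `"BRANCH"` or `"SWITCH"`.
#' @param site optional site id from [conditional_sites()] (checked).
#' @return `a` if `predicate_value` else `b`.
#' @export
evaluate_conditional <- function(predicate_value, a, b,
                                 mode = c("BRANCH", "SWITCH"),
                                 site = NULL) {
  mode <- match.arg(mode)
  if (!is.null(site) && !site %in% conditional_sites()$id)
    stop("unknown conditional site: ", site, call. = FALSE)
  stopifnot(is.logical(predicate_value), length(predicate_value) == 1L)
  if (mode == "BRANCH") {
    if (predicate_value) a else b
  } else {
    s <- as.numeric(predicate_value)
    s * a + (1 - s) * b
  }
}

#' Export a roster or output map as CSV
#'
#' @param x data.frame from [state_roster()] or [output_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.template_config <- function(x, ...) {
  cat("<template_config> preset:", x$model, "\n",
      " compartments:", length(x$active_compartments),
      "| pathways:", length(x$active_pathways),
      "| routes:", paste(x$routes, collapse = ","), "\n",
      " blood:", x$blood_mode, "| gas exchange:", x$gas_exchange_mode,
      "| lung:", x$lung_present, "\n",
      " bw:", x$bw_mode, "| conditionals:", x$conditional_mode,
      "| prune:", x$prune,
      "| outputs:", if (x$reduced_outputs) 76 else 105, "\n")
  invisible(x)
}
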