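## Engine construction: translate a template configuration (or a
## stand-alone model name) plus parameter records into the flat
## structure consumed by the compiled core.

#' Build a template-implemented PBPK engine
#'
#' Assembles the configurable superstructure for a given configuration
#' and parameter set: renormalizes perfusion fractions over the active
#' compartments, freezes the body-weight input, resolves the (possibly
#' pruned) state roster and output map, and returns an engine exposing
#' the integrated system to [simulate_model()], [engine_rhs()] and
#' [compute_outputs()].
#'
#' @param config a [template_config()].
#' @param chem a [chemical_params()] record.
#' @param phys a [physiology_params()] record.
#' @param bw_input body-weight input: `NULL` (use the record's reference
#'   body weight), a single value (kg), or a data.frame with columns
#'   `time` (h, strictly increasing) and `bw` (kg) interpolated
#'   piecewise-linearly and clamped outside its range (only meaningful
#'   with `bw_mode = "INPUT_TABLE"`).
#' @return object of class `pbpk_engine`.
#' @export
build_engine <- function(config, chem, phys, bw_input = NULL) {
  validate_config(config)
  stopifnot(inherits(chem, "chemical_params"),
            inherits(phys, "physiology_params"))
  phys <- renormalize_flows(phys, config)

  bw_tab <- .resolve_bw_input(bw_input, phys, config$bw_mode)
  ac <- config$active_compartments
  comp_active <- as.integer(c("fat", "liver", "kidney", "richly", "slowly",
                              "skin", "stomach", "intestine") %in% ac)
  comp_active <- c(comp_active,
                   as.integer(isTRUE(config$lung_present) &&
                              "lung_tissue" %in% ac))

  routes <- config$routes
  if ("oral" %in% routes && !"stomach_lumen" %in% ac)
    stop("oral route requires the stomach_lumen compartment", call. = FALSE)
  if (chem[["stomach_to_intestine_rate"]] > 0 && !"intestine_lumen" %in% ac)
    stop("stomach_to_intestine_rate > 0 but intestine_lumen is inactive",
         call. = FALSE)
  if ("inhalation_closed" %in% routes && !"chamber" %in% ac)
    stop("closed-chamber inhalation requires the chamber compartment",
         call. = FALSE)
  vf <- as.numeric(phys[paste0("volume_fraction_",
                               c("arterial", "venous", .TISSUES))])
  act_v <- c(1L, 1L, comp_active)
  if (any(act_v == 1L & vf <= 0))
    stop("active compartments must have positive volume fractions",
         call. = FALSE)

  roster <- state_roster(config, pruned = isTRUE(config$prune))
  full_names <- state_roster()$name
  loc2full <- match(roster$name, full_names) - 1L
  omap <- output_map(reduced = isTRUE(config$reduced_outputs))

  eng <- list(
    type = 0L,
    kind = "template",
    switch_mode = as.integer(config$conditional_mode == "SWITCH"),
    blood_ss = as.integer(config$blood_mode == "SS_APPROX"),
    ge_ss = as.integer(config$gas_exchange_mode == "GE_SS"),
    lung_present = as.integer(isTRUE(config$lung_present)),
    bw_mode = match(config$bw_mode,
                    c("INPUT_TABLE", "FIXED_DYNAMIC", "FIXED_INIT")) - 1L,
    closed_chamber = as.integer("inhalation_closed" %in% routes),
    inh_route = as.integer("inhalation_open" %in% routes),
    oral_route = as.integer("oral" %in% routes),
    dermal_route = as.integer("dermal" %in% routes),
    iv_route = as.integer("iv" %in% routes),
    comp_active = comp_active,
    ge_active = as.integer("gas_exchange" %in% ac),
    stl_active = as.integer("stomach_lumen" %in% ac),
    inl_active = as.integer("intestine_lumen" %in% ac),
    ch_active = as.integer("chamber" %in% ac),
    dv_active = as.integer("dermal_vehicle" %in% ac),
    dep_active = as.integer("depot" %in% ac),
    path_active = as.integer(.PATHWAYS %in% config$active_pathways),
    vf = vf,
    ff = as.numeric(phys[paste0("flow_fraction_", .TISSUES)]),
    qc_c = as.numeric(phys["cardiac_output_c"]),
    qalv_c = as.numeric(phys["alveolar_ventilation_c"]),
    ska_c = as.numeric(phys["skin_area_c"]),
    pba = as.numeric(chem["blood_air_partition"]),
    P = as.numeric(chem[paste0("partition_", .TISSUES)]),
    vmax_c = as.numeric(chem[paste0("vmax_c_", .SAT_PATHWAYS)]),
    km = as.numeric(chem[paste0("km_", .SAT_PATHWAYS)]),
    kf = as.numeric(chem[paste0("kf_", .FO_PATHWAYS)]),
    ka_st = as.numeric(chem["oral_absorption_rate_stomach"]),
    ka_in = as.numeric(chem["oral_absorption_rate_intestine"]),
    k_sti = as.numeric(chem["stomach_to_intestine_rate"]),
    k_fec = as.numeric(chem["fecal_transit_rate"]),
    perm = as.numeric(chem["dermal_permeability"]),
    clu_c = as.numeric(chem["urinary_clearance_c"]),
    bw_t = bw_tab$time,
    bw_v = bw_tab$bw,
    loc2full = loc2full,
    reduced = as.integer(isTRUE(config$reduced_outputs)),
    n_outputs = nrow(omap),
    roster = roster,
    outputs = omap,
    config = config
  )
  class(eng) <- "pbpk_engine"
  eng
}

.resolve_bw_input <- function(bw_input, phys, bw_mode) {
  if (is.null(bw_input))
    return(list(time = 0, bw = as.numeric(phys["body_weight"])))
  if (is.numeric(bw_input) && length(bw_input) == 1L) {
    if (bw_input <= 0) stop("body weight must be > 0", call. = FALSE)
    return(list(time = 0, bw = as.numeric(bw_input)))
  }
  if (is.data.frame(bw_input)) {
    stopifnot(all(c("time", "bw") %in% names(bw_input)))
    tt <- as.numeric(bw_input$time)
    bb <- as.numeric(bw_input$bw)
    if (any(diff(tt) <= 0))
      stop("bw table times must be strictly increasing", call. = FALSE)
    if (any(bb <= 0)) stop("bw must be > 0 everywhere", call. = FALSE)
    if (bw_mode != "INPUT_TABLE" && length(unique(bb)) > 1L)
      stop("a time-varying bw table requires bw_mode = INPUT_TABLE",
           call. = FALSE)
    return(list(time = tt, bw = bb))
  }
  stop("bw_input must be NULL, a single value, or a data.frame(time, bw)",
       call. = FALSE)
}

#' Build a stand-alone DCM or CF model
#'
#' Dedicated minimal implementations of the two chemical-specific
#' models, coded independently of the template: the DCM model has 21
#' state variables and 22 output variables (arterial/venous blood, lung,
#' fat, liver, richly and slowly perfused tissues, stomach lumen;
#' saturable + first-order metabolism in liver and lung); the CF model
#' has 19 states and 26 outputs (no lung compartment; saturable
#' metabolism in liver and kidney; two-segment gastrointestinal lumen).
#' Body weight is a constant parameter with all dependent quantities
#' computed once at initialization.
#'
#' @param name `"dcm"` or `"cf"`.
#' @param chem,phys parameter records (use the shipped fixtures for the
#'   published parameterizations).
#' @param bw body weight (kg); defaults to the record's reference value.
#' @return object of class `pbpk_engine`.
#' @export
build_standalone <- function(name = c("dcm", "cf"), chem, phys, bw = NULL) {
  name <- match.arg(name)
  stopifnot(inherits(chem, "chemical_params"),
            inherits(phys, "physiology_params"))
  bw <- if (is.null(bw)) as.numeric(phys["body_weight"]) else as.numeric(bw)
  if (bw <= 0) stop("bw must be > 0", call. = FALSE)
  cfg <- template_config(name)         # shares the structural mapping
  phys <- renormalize_flows(phys, cfg)
  S <- scale_physiology(phys, chem, bw)
  V <- S$volumes; Q <- S$flows
  sa <- c(V[["arterial"]], V[["venous"]], V[["lung"]], V[["fat"]],
          V[["liver"]], V[["kidney"]], V[["richly"]], V[["slowly"]],
          Q[["fat"]], Q[["liver"]], Q[["kidney"]], Q[["richly"]],
          Q[["slowly"]], Q[["lung"]],
          S$cardiac_output, S$alveolar_ventilation,
          as.numeric(chem["blood_air_partition"]),
          as.numeric(chem[paste0("partition_",
                                 c("fat", "liver", "kidney", "richly",
                                   "slowly", "lung"))]),
          S$vmax[["liver1"]], S$km[["liver1"]], S$kf[["liver"]],
          S$vmax[["lung"]], S$km[["lung"]], S$kf[["lung"]],
          S$vmax[["kidney"]], S$km[["kidney"]],
          as.numeric(chem["oral_absorption_rate_stomach"]),
          as.numeric(chem["oral_absorption_rate_intestine"]),
          as.numeric(chem["stomach_to_intestine_rate"]),
          as.numeric(chem["fecal_transit_rate"]))
  roster <- standalone_roster(name)
  omap <- standalone_output_map(name)
  eng <- list(
    type = if (name == "dcm") 1L else 2L,
    kind = paste0("standalone_", name),
    switch_mode = 0L, blood_ss = 0L, ge_ss = 1L,
    lung_present = as.integer(name == "dcm"),
    bw_mode = 2L, closed_chamber = 0L,
    inh_route = 1L, oral_route = 1L, dermal_route = 0L, iv_route = 0L,
    comp_active = integer(9), ge_active = 1L, stl_active = 1L,
    inl_active = as.integer(name == "cf"), ch_active = 0L,
    dv_active = 0L, dep_active = 0L, path_active = integer(9),
    vf = numeric(11), ff = numeric(9), qc_c = 0, qalv_c = 0, ska_c = 0,
    pba = as.numeric(chem["blood_air_partition"]),
    P = numeric(9), vmax_c = numeric(4), km = rep(1, 4), kf = numeric(5),
    ka_st = 0, ka_in = 0, k_sti = 0, k_fec = 0, perm = 0, clu_c = 0,
    bw_t = 0, bw_v = bw,
    loc2full = seq_len(nrow(roster)) - 1L,
    reduced = 0L,
    n_outputs = nrow(omap),
    sa_pars = as.numeric(sa),
    roster = roster,
    outputs = omap,
    config = cfg
  )
  class(eng) <- "pbpk_engine"
  eng
}

#' State rosters and output maps of the stand-alone models
#'
#' @param name `"dcm"` or `"cf"`.
#' @return data.frame with columns `name`, `group`, `units`.
#' @export
standalone_roster <- function(name = c("dcm", "cf")) {
  name <- match.arg(name)
  if (name == "dcm") {
    nm <- c("amt_arterial", "amt_venous", "amt_lung", "amt_fat",
            "amt_liver", "amt_richly", "amt_slowly", "amt_stomach_lumen",
            "met_sat_liver1", "met_fo_liver", "met_sat_lung",
            "met_fo_lung", "out_exhaled", "abs_stomach",
            paste0("auc_", c("arterial", "venous", "lung", "fat",
                             "liver", "richly", "slowly")))
    grp <- c(rep("compartment_amount", 8), rep("cumulative_metabolism", 4),
             rep("cumulative_intake_elimination", 2), rep("auc", 7))
  } else {
    nm <- c("amt_arterial", "amt_venous", "amt_fat", "amt_liver",
            "amt_kidney", "amt_richly", "amt_slowly", "amt_stomach_lumen",
            "amt_intestine_lumen", "met_sat_liver1", "met_sat_kidney",
            "out_exhaled", "abs_gi",
            paste0("auc_", c("venous", "fat", "liver", "kidney",
                             "richly", "slowly")))
    grp <- c(rep("compartment_amount", 9), rep("cumulative_metabolism", 2),
             rep("cumulative_intake_elimination", 2), rep("auc", 6))
  }
  data.frame(name = nm, group = grp,
             units = ifelse(grp == "auc", "mg*h/L", "mg"),
             stringsAsFactors = FALSE)
}

#' @rdname standalone_roster
#' @export
standalone_output_map <- function(name = c("dcm", "cf")) {
  name <- match.arg(name)
  grp <- function(names, group, units)
    data.frame(name = names, group = group, units = units,
               stringsAsFactors = FALSE)
  if (name == "dcm") {
    rbind(
      grp(paste0("conc_", c("arterial", "venous", "lung", "fat", "liver",
                            "richly", "slowly", "stomach_lumen")),
          "compartment_concentration", "mg/L"),
      grp(c("rate_met_sat_liver1", "rate_met_fo_liver",
            "rate_met_sat_lung", "rate_met_fo_lung"),
          "metabolism_rate", "mg/h"),
      grp(c("c_inhaled_air", "c_exhaled_air"), "air_phase", "mg/L"),
      grp(paste0("twa_", c("arterial", "venous", "lung", "fat", "liver",
                           "richly", "slowly")),
          "time_weighted_average", "mg/L"),
      grp("mb_error", "mass_balance", "mg"))
  } else {
    rbind(
      grp(paste0("conc_", c("arterial", "venous", "fat", "liver",
                            "kidney", "richly", "slowly", "stomach_lumen",
                            "intestine_lumen")),
          "compartment_concentration", "mg/L"),
      grp(paste0("cv_", c("fat", "liver", "kidney", "richly", "slowly")),
          "venous_equilibrated", "mg/L"),
      grp(c("rate_met_sat_liver1", "rate_met_sat_kidney"),
          "metabolism_rate", "mg/h"),
      grp(c("c_inhaled_air", "c_exhaled_air"), "air_phase", "mg/L"),
      grp(paste0("twa_", c("venous", "fat", "liver", "kidney", "richly",
                           "slowly")), "time_weighted_average", "mg/L"),
      grp("rate_in_oral", "intake_rate", "mg/h"),
      grp("mb_error", "mass_balance", "mg"))
  }
}

#' Evaluate the engine derivative at a point
#'
#' Exposes the compiled right-hand side for direct inspection: given a
#' time and a state vector (in the engine's roster order), returns the
#' derivative vector.  Exposure forcing is supplied as constants.
#'
#' @param engine a `pbpk_engine`.
#' @param t time (h).
#' @param state numeric vector matching the engine roster.
#' @param c_inhaled inhaled air concentration (mg/L).
#' @param oral_rate stomach-lumen delivery rate (mg/h).
#' @param iv_rate venous infusion rate (mg/h).
#' @return named derivative vector.
#' @export
engine_rhs <- function(engine, t, state, c_inhaled = 0, oral_rate = 0,
                       iv_rate = 0) {
  stopifnot(inherits(engine, "pbpk_engine"))
  if (any(!is.finite(state)))
    stop("integration-abort: non-finite state", call. = FALSE)
  dy <- .cpp_rhs_point(engine, t, as.numeric(state), c_inhaled, oral_rate,
                       iv_rate)
  stats::setNames(dy, engine$roster$name)
}

#' Evaluate the engine output map at a point
#'
#' @inheritParams engine_rhs
#' @return named output vector (105 or 76 entries for template engines;
#'   22 or 26 for the stand-alone models).
#' @export
compute_outputs <- function(engine, t, state, c_inhaled = 0, oral_rate = 0,
                            iv_rate = 0) {
  stopifnot(inherits(engine, "pbpk_engine"))
  out <- .cpp_outputs_point(engine, t, as.numeric(state), c_inhaled,
                            oral_rate, iv_rate)
  stats::setNames(out, engine$outputs$name)
}

#' Steady-state gas-exchange (pulmonary vein) concentration
#'
#' The classic algebraic equilibrium of the gas-exchange region:
#' `(Qc*Cven + Qalv*Cinh) / (Qc + Qalv/Pba)`.  The corresponding
#' exhaled-air concentration is the returned value divided by `Pba`.
#'
#' @param c_ven mixed venous blood concentration (mg/L).
#' @param c_inh inhaled air concentration (mg/L).
#' @param cardiac_output,alveolar_ventilation flows (L/h).
#' @param blood_air_partition blood:air partition coefficient (> 0).
#' @return pulmonary venous (arterial-side) concentration, mg/L.
#' @export
arterial_ss <- function(c_ven, c_inh, cardiac_output,
                        alveolar_ventilation, blood_air_partition) {
  if (blood_air_partition <= 0)
    stop("blood_air_partition must be > 0", call. = FALSE)
  (cardiac_output * c_ven + alveolar_ventilation * c_inh) /
    (cardiac_output + alveolar_ventilation / blood_air_partition)
}

#' Steady-state mixed venous concentration
#'
#' Flow-weighted mixing of tissue venous returns plus any direct venous
#' infusion: `sum(Q_i * Cv_i) / Qc + iv_rate / Qc`.
#'
#' @param venous_returns two-column matrix or data.frame of
#'   (flow L/h, concentration mg/L) pairs.
#' @param cardiac_output total cardiac output (L/h); the flows must sum
#'   to it (relative mismatch above 1e-9 is an error).
#' @param iv_rate venous infusion rate (mg/h).
#' @return mixed venous concentration, mg/L.
#' @export
venous_ss <- function(venous_returns, cardiac_output, iv_rate = 0) {
  vr <- as.matrix(venous_returns)
  stopifnot(ncol(vr) == 2, cardiac_output > 0)
  qs <- sum(vr[, 1])
  if (abs(qs - cardiac_output) > 1e-9 * max(abs(cardiac_output), 1))
    stop("venous return flows sum to ", qs, ", not cardiac output ",
         cardiac_output, call. = FALSE)
  sum(vr[, 1] * vr[, 2]) / cardiac_output + iv_rate / cardiac_output
}

#' Michaelis-Menten (saturable) metabolic rate
#'
#' `vmax * c / (km + c)`: monotone nondecreasing in `c`, bounded by
#' `vmax`, half-maximal at `c = km`.
#'
#' @param vmax capacity (mg/h).
#' @param km half-saturation concentration (mg/L, > 0).
#' @param c substrate concentration (mg/L, >= 0).
#' @return rate, mg/h.
#' @export
saturable_rate <- function(vmax, km, c) {
  if (any(km <= 0)) stop("km must be > 0", call. = FALSE)
  if (any(c < 0)) stop("concentration must be >= 0", call. = FALSE)
  vmax * c / (km + c)
}

#' Resolve body weight and scaled parameters at a time point
#'
#' Mirrors the three body-weight handling modes of the template:
#' `INPUT_TABLE` interpolates bw(t) piecewise-linearly (clamped at the
#' table ends) and rescales the 28 dependent quantities;
#' `FIXED_DYNAMIC` uses the constant bw but still rescales on every
#' call; `FIXED_INIT` computes the dependents once and caches them on
#' the input object.  For a constant-valued table all three modes agree
#' exactly.
#'
#' @param t time (h).
#' @param bw_input a data.frame(time, bw), or a single bw value.
#' @param mode `"INPUT_TABLE"`, `"FIXED_DYNAMIC"` or `"FIXED_INIT"`.
#' @param phys,chem parameter records.
#' @return list with `bw` and `scaled` (a [scale_physiology()] result).
#' @export
resolve_bw <- function(t, bw_input, mode, phys, chem) {
  stopifnot(mode %in% c("INPUT_TABLE", "FIXED_DYNAMIC", "FIXED_INIT"))
  tab <- .resolve_bw_input(bw_input, phys, mode)
  bw <- if (mode == "INPUT_TABLE" && length(tab$time) > 1L) {
    stats::approx(tab$time, tab$bw, xout = t, rule = 2)$y
  } else tab$bw[1]
  list(bw = bw, scaled = scale_physiology(phys, chem, bw))
}

#' @export
print.pbpk_engine <- function(x, ...) {
  cat("<pbpk_engine>", x$kind, "|", nrow(x$roster), "states |",
      x$n_outputs, "outputs\n")
  invisible(x)
}
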