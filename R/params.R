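## Parameter records, CSV input tables, and body-weight scaling.
##
## Two input tables parameterize every model built by this package:
##   chemical.csv   -- chemical- and species-specific parameters
##   physiology.csv -- anatomical/physiological parameters
## Both use the header `name,value,units` (decimal point, UTF-8).

.chem_keys <- function() {
  c("blood_air_partition",
    paste0("partition_", .PARTITION_TISSUES),
    paste0("vmax_c_", .SAT_PATHWAYS),
    paste0("km_", .SAT_PATHWAYS),
    paste0("kf_", .FO_PATHWAYS),
    "oral_absorption_rate_stomach", "oral_absorption_rate_intestine",
    "stomach_to_intestine_rate", "fecal_transit_rate",
    "dermal_permeability", "urinary_clearance_c")
}

.phys_keys <- function() {
  c("body_weight",
    paste0("volume_fraction_", .VOLUME_COMPARTMENTS),
    paste0("flow_fraction_", .PERFUSED),
    "cardiac_output_c", "alveolar_ventilation_c", "skin_area_c")
}

#' Construct a validated chemical parameter record
#'
#' Holds chemical- and species-specific constants: the blood:air partition
#' coefficient, tissue:blood partition coefficients for the nine perfused
#' tissues, saturable (Michaelis-Menten) pathway constants `vmax_c`
#' (mg/h/kg^0.75) and `km` (mg/L) for the four saturable pathways
#' (liver1, liver2, lung, kidney), first-order metabolic rate constants
#' `kf` (/h, applied to the tissue amount) for liver, lung, kidney,
#' stomach and intestine, gastrointestinal transfer rates (/h), dermal
#' permeability (cm/h) and an allometric urinary clearance coefficient
#' (L/h/kg^0.75).  Pathways a given model does not use are set to zero;
#' partition coefficients must stay positive because the full template
#' evaluates every tissue equation (with zero flow) even for deactivated
#' compartments.
#'
#' @param values named numeric vector covering every key in
#'   `chemical_param_names()`.
#' @return object of class `chemical_params` (a named numeric vector).
#' @export
chemical_params <- function(values) {
  x <- .validate_keyed(values, .chem_keys(), "chemical")
  parts <- x[c("blood_air_partition", paste0("partition_", .PARTITION_TISSUES))]
  if (any(parts <= 0))
    stop("partition coefficients must be > 0: ",
         paste(names(parts)[parts <= 0], collapse = ", "), call. = FALSE)
  rates <- x[setdiff(names(x), names(parts))]
  if (any(rates < 0))
    stop("rate constants must be >= 0: ",
         paste(names(rates)[rates < 0], collapse = ", "), call. = FALSE)
  for (p in .SAT_PATHWAYS) {
    if (x[paste0("vmax_c_", p)] > 0 && x[paste0("km_", p)] <= 0)
      stop("km_", p, " must be > 0 because vmax_c_", p, " > 0", call. = FALSE)
  }
  structure(x, class = "chemical_params")
}

#' Construct a validated physiology parameter record
#'
#' Reference body weight (kg), fractional compartment volumes (L/kg; 11
#' entries including arterial and venous blood), fractional blood flows
#' (dimensionless fractions of cardiac output; 9 perfused compartments),
#' and allometric coefficients for cardiac output and alveolar
#' ventilation (L/h/kg^0.75) and skin surface area (cm^2/kg^0.667).
#'
#' @param values named numeric vector covering every key in
#'   `physiology_param_names()`.
#' @return object of class `physiology_params`.
#' @export
physiology_params <- function(values) {
  x <- .validate_keyed(values, .phys_keys(), "physiology")
  if (x["body_weight"] <= 0) stop("body_weight must be > 0", call. = FALSE)
  vf <- x[paste0("volume_fraction_", .VOLUME_COMPARTMENTS)]
  if (any(vf < 0)) stop("volume fractions must be >= 0", call. = FALSE)
  if (sum(vf) > 1)
    stop("volume fractions sum to ", signif(sum(vf), 6), " > 1", call. = FALSE)
  ff <- x[paste0("flow_fraction_", .PERFUSED)]
  if (any(ff < 0)) stop("flow fractions must be >= 0", call. = FALSE)
  if (x["cardiac_output_c"] <= 0 || x["alveolar_ventilation_c"] <= 0)
    stop("cardiac_output_c and alveolar_ventilation_c must be > 0",
         call. = FALSE)
  structure(x, class = "physiology_params")
}

.validate_keyed <- function(values, keys, what) {
  if (is.null(names(values)) || any(names(values) == ""))
    stop("all ", what, " parameters must be named", call. = FALSE)
  unknown <- setdiff(names(values), keys)
  if (length(unknown))
    stop("unknown ", what, " parameter keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(keys, names(values))
  if (length(missing))
    stop("missing required ", what, " parameter keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- as.numeric(values[keys])
  names(x) <- keys
  if (any(!is.finite(x)))
    stop("non-finite ", what, " parameter values: ",
         paste(keys[!is.finite(x)], collapse = ", "), call. = FALSE)
  x
}

#' @rdname chemical_params
#' @export
chemical_param_names <- function() .chem_keys()

#' @rdname physiology_params
#' @export
physiology_param_names <- function() .phys_keys()

#' Read a parameter table from CSV
#'
#' The on-disk contract is a CSV with header `name,value,units`.  Unknown
#' keys are hard errors (silent misconfiguration is worse than friction
#' during QA review), as are missing required keys.
#'
#' @param path path to a CSV file.
#' @param schema one of `"chemical"`, `"physiology"`, `"exposure"`.
#' @return a `chemical_params`, `physiology_params`, or (for
#'   `"exposure"`) a named numeric vector of exposure keys.
#' @export
read_params <- function(path, schema = c("chemical", "physiology", "exposure")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(tab)))
    stop("parameter table must have columns name,value,units", call. = FALSE)
  vals <- stats::setNames(as.numeric(tab$value), tab$name)
  switch(schema,
         chemical = chemical_params(vals),
         physiology = physiology_params(vals),
         exposure = .validate_exposure_record(vals))
}

.EXPOSURE_KEYS <- c("scenario_kind", "dose_level", "duration_weeks")

.validate_exposure_record <- function(vals) {
  x <- .validate_keyed(vals, .EXPOSURE_KEYS, "exposure")
  if (!x["scenario_kind"] %in% 1:4)
    stop("scenario_kind must be 1, 2, 3 or 4", call. = FALSE)
  if (x["dose_level"] < 0) stop("dose_level must be >= 0", call. = FALSE)
  x
}

#' Write a parameter record back to CSV
#'
#' Inverse of [read_params()]: `read_params(write_params(x, f), schema)`
#' returns a record identical to `x`.
#'
#' @param x a parameter record (named numeric vector).
#' @param path output CSV path.
#' @param units optional character vector of unit strings (stored, not
#'   interpreted).
#' @return `path`, invisibly.
#' @export
write_params <- function(x, path, units = NULL) {
  if (is.null(units)) units <- rep("", length(x))
  utils::write.csv(data.frame(name = names(x), value = as.numeric(x),
                              units = units),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load one of the shipped fixture parameter sets
#'
#' `chemical_fixture()` returns the dichloromethane ("dcm") or chloroform
#' ("cf") chemical record; `physiology_fixture()` the reference human
#' physiology.  These fixtures emulate the published model
#' parameterizations: DCM metabolizes through saturable and first-order
#' pathways in liver and lung, CF through saturable pathways in liver and
#' kidney with a two-segment gastrointestinal lumen.
#'
#' @param chemical `"dcm"` or `"cf"`.
#' @return parameter record.
#' @export
chemical_fixture <- function(chemical = c("dcm", "cf")) {
  chemical <- match.arg(chemical)
  read_params(system.file("extdata", paste0(chemical, "_chemical.csv"),
                          package = "pbpktemplate", mustWork = TRUE),
              "chemical")
}

#' @rdname chemical_fixture
#' @export
physiology_fixture <- function() {
  read_params(system.file("extdata", "human_physiology.csv",
                          package = "pbpktemplate", mustWork = TRUE),
              "physiology")
}

#' Names of the 28 body-weight-dependent quantities
#'
#' The template derives exactly 28 scalar quantities from body weight:
#' 11 compartment volumes (proportional to BW), 9 perfused-compartment
#' blood flows plus cardiac output and alveolar ventilation (BW^0.75),
#' 4 saturable-pathway capacities (BW^0.75), urinary clearance (BW^0.75)
#' and skin surface area (BW^0.667).
#'
#' @return character vector of length 28.
#' @export
bw_dependent_names <- function() {
  c(paste0("volume_", .VOLUME_COMPARTMENTS),
    paste0("flow_", .PERFUSED),
    "cardiac_output", "alveolar_ventilation",
    paste0("vmax_", .SAT_PATHWAYS),
    "urinary_clearance", "skin_area")
}

#' Scale physiology and metabolic capacity to a body weight
#'
#' Applies the standard allometric conventions: volumes scale linearly
#' with body weight; flows, ventilation, metabolic capacities (vmax) and
#' urinary clearance scale with BW^0.75; skin area with BW^0.667.
#' First-order metabolic rate constants are per-hour rates applied to
#' compartment amounts and do not rescale, which keeps the
#' body-weight-dependent roster at exactly 28 quantities.
#'
#' @param phys a `physiology_params` record.
#' @param chem a `chemical_params` record.
#' @param bw body weight in kg (> 0).
#' @return object of class `scaled_params`: a list with elements
#'   `volumes` (L), `flows` (L/h), `cardiac_output`,
#'   `alveolar_ventilation` (L/h), `vmax` (mg/h), `km` (mg/L),
#'   `kf` (/h), `urinary_clearance` (L/h), `skin_area` (cm^2), `bw`,
#'   and `bw_dependent` (the 28 names).
#' @export
scale_physiology <- function(phys, chem, bw) {
  if (!is.numeric(bw) || length(bw) != 1L || !is.finite(bw) || bw <= 0)
    stop("bw must be a single finite value > 0", call. = FALSE)
  b75 <- bw^0.75
  volumes <- stats::setNames(
    as.numeric(phys[paste0("volume_fraction_", .VOLUME_COMPARTMENTS)]) * bw,
    .VOLUME_COMPARTMENTS)
  qc <- as.numeric(phys["cardiac_output_c"]) * b75
  flows <- stats::setNames(
    as.numeric(phys[paste0("flow_fraction_", .PERFUSED)]) * qc, .PERFUSED)
  structure(list(
    volumes = volumes,
    flows = flows,
    cardiac_output = qc,
    alveolar_ventilation = as.numeric(phys["alveolar_ventilation_c"]) * b75,
    vmax = stats::setNames(
      as.numeric(chem[paste0("vmax_c_", .SAT_PATHWAYS)]) * b75, .SAT_PATHWAYS),
    km = stats::setNames(as.numeric(chem[paste0("km_", .SAT_PATHWAYS)]),
                         .SAT_PATHWAYS),
    kf = stats::setNames(as.numeric(chem[paste0("kf_", .FO_PATHWAYS)]),
                         .FO_PATHWAYS),
    urinary_clearance = as.numeric(chem["urinary_clearance_c"]) * b75,
    skin_area = as.numeric(phys["skin_area_c"]) * bw^0.667,
    bw = bw,
    bw_dependent = bw_dependent_names()
  ), class = "scaled_params")
}

#' Renormalize perfusion fractions to the active compartments
#'
#' Deactivated compartments get zero blood flow; the remaining active
#' perfused fractions are rescaled to sum to exactly 1 so that total
#' tissue perfusion always equals cardiac output.  Idempotent.
#'
#' @param phys a `physiology_params` record.
#' @param config a [template_config()] object.
#' @return a `physiology_params` record with adjusted flow fractions.
#' @export
renormalize_flows <- function(phys, config) {
  active <- intersect(.PERFUSED, .perfused_from_config(config))
  if (length(active) == 0L)
    stop("no active perfused compartments in configuration", call. = FALSE)
  ff <- as.numeric(phys[paste0("flow_fraction_", .PERFUSED)])
  names(ff) <- .PERFUSED
  ff[setdiff(.PERFUSED, active)] <- 0
  tot <- sum(ff[active])
  if (tot <= 0)
    stop("active perfused compartments carry zero total flow", call. = FALSE)
  ff[active] <- ff[active] / tot
  out <- unclass(phys)
  out[paste0("flow_fraction_", .PERFUSED)] <- ff
  structure(out, class = "physiology_params")
}

## Template compartment names -> perfused-tissue names
.perfused_from_config <- function(config) {
  map <- c(lung_tissue = "lung", fat = "fat", liver = "liver",
           kidney = "kidney", richly = "richly", slowly = "slowly",
           skin = "skin", stomach = "stomach", intestine = "intestine")
  unname(map[intersect(names(map), config$active_compartments)])
}

#' @export
print.chemical_params <- function(x, ...) {
  cat("<chemical_params> (", length(x), " parameters)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @export
print.physiology_params <- function(x, ...) {
  cat("<physiology_params> BW = ", x[["body_weight"]], " kg\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @export
print.scaled_params <- function(x, ...) {
  cat("<scaled_params> bw =", x$bw, "kg;",
      length(x$bw_dependent), "BW-dependent quantities\n")
  cat("  cardiac output", signif(x$cardiac_output, 5), "L/h; alveolar",
      signif(x$alveolar_ventilation, 5), "L/h\n")
  invisible(x)
}
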