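#' Compound physico-chemical and binding properties
#'
#' Container for the compound-level constants the PBPK model and the unit
#' conversions need. Defaults describe amiodarone: molecular weight
#' 645.31 g/mol, plasma unbound fraction 0.06, blood-to-plasma
#' concentration ratio 0.73.
#'
#' @param molecular_weight Molecular weight in g/mol, > 0.
#' @param fu_plasma Fraction of drug unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio Whole-blood to plasma concentration ratio, > 0.
#'
#' @return An object of class `compound_properties`.
#' @export
#' @examples
#' compound_properties()  # amiodarone defaults
compound_properties <- function(molecular_weight = 645.31,
                                fu_plasma = 0.06,
                                blood_plasma_ratio = 0.73) {
  check_scalar(molecular_weight, "molecular_weight", lower = 0, lower_open = TRUE)
  check_scalar(fu_plasma, "fu_plasma", lower = 0, upper = 1, lower_open = TRUE)
  check_scalar(blood_plasma_ratio, "blood_plasma_ratio", lower = 0, lower_open = TRUE)
  structure(
    list(molecular_weight = molecular_weight,
         fu_plasma = fu_plasma,
         blood_plasma_ratio = blood_plasma_ratio),
    class = "compound_properties"
  )
}

#' @export
print.compound_properties <- function(x, ...) {
  cat("Compound properties\n")
  cat(sprintf("  molecular weight   : %.2f g/mol\n", x$molecular_weight))
  cat(sprintf("  fu (plasma)        : %.3f\n", x$fu_plasma))
  cat(sprintf("  blood:plasma ratio : %.3f\n", x$blood_plasma_ratio))
  invisible(x)
}

#' Whole-body PBPK parameter set
#'
#' Assembles and validates the full physiological and compound
#' parameterization of the permeability-rate-limited whole-body model:
#' arterial and venous blood, a lung compartment, and a configurable set of
#' tissues (default ten), each split into a vascular and an extravascular
#' sub-compartment exchanging unbound drug through a permeability-surface
#' area (PS) product. Only the liver eliminates, by a constant clearance
#' acting on the unbound extravascular liver concentration.
#'
#' Tissue names are data, not code: `tissues` is a data frame with one row
#' per tissue and columns `name`, `volume_vascular` (L), `volume_tissue`
#' (L), `blood_flow` (L/h), `PS` (L/h) and `fu_tissue` (unitless fraction).
#' A tissue named `"liver"` must be present (it carries the clearance).
#'
#' @param body_weight Body weight in kg.
#' @param cardiac_output Cardiac output in L/h. Must equal the sum of the
#'   tissue blood flows to within 1e-6 relative.
#' @param blood_volumes Named list/vector with `venous`, `arterial` blood
#'   volumes in L.
#' @param lung Named list/vector with `volume_vascular`, `volume_tissue`,
#'   `PS`, `fu_tissue` for the lung (its blood flow is the cardiac output).
#' @param tissues Data frame as described above.
#' @param hepatic_clearance Hepatic clearance in L/h applied to the unbound
#'   extravascular liver concentration.
#' @param compound A [compound_properties()] object.
#'
#' @return An object of class `pbpk_params`.
#' @seealso [read_pbpk_params()] to load a parameter file,
#'   [pbpk_simulate()] to run the model.
#' @export
pbpk_params <- function(body_weight, cardiac_output, blood_volumes, lung,
                        tissues, hepatic_clearance,
                        compound = compound_properties()) {
  check_scalar(body_weight, "body_weight", lower = 0, lower_open = TRUE)
  check_scalar(cardiac_output, "cardiac_output", lower = 0, lower_open = TRUE)
  check_scalar(hepatic_clearance, "hepatic_clearance", lower = 0)
  if (!inherits(compound, "compound_properties"))
    stop_validation("compound must be a compound_properties object")

  blood_volumes <- as.list(blood_volumes)
  for (nm in c("venous", "arterial"))
    check_scalar(blood_volumes[[nm]] %||% NA_real_,
                 paste0("blood_volumes$", nm), lower = 0, lower_open = TRUE)

  lung <- as.list(lung)
  for (nm in c("volume_vascular", "volume_tissue", "PS"))
    check_scalar(lung[[nm]] %||% NA_real_, paste0("lung$", nm), lower = 0)
  check_scalar(lung$fu_tissue %||% NA_real_, "lung$fu_tissue",
               lower = 0, upper = 1, lower_open = TRUE)

  tissues <- as.data.frame(tissues, stringsAsFactors = FALSE)
  needed <- c("name", "volume_vascular", "volume_tissue", "blood_flow",
              "PS", "fu_tissue")
  missing_cols <- setdiff(needed, names(tissues))
  if (length(missing_cols))
    stop_validation("tissues is missing columns: ",
                    paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tissues$name))
    stop_validation("tissue names must be unique")
  if (!"liver" %in% tissues$name)
    stop_validation("a tissue named 'liver' is required")
  for (col in c("volume_vascular", "volume_tissue", "blood_flow", "PS")) {
    if (any(!is.finite(tissues[[col]])) || any(tissues[[col]] < 0))
      stop_validation("tissues$", col, " must be finite and >= 0")
  }
  if (any(tissues$fu_tissue <= 0) || any(tissues$fu_tissue > 1))
    stop_validation("tissues$fu_tissue must lie in (0, 1]")

  flow_sum <- sum(tissues$blood_flow)
  if (abs(flow_sum - cardiac_output) > 1e-6 * cardiac_output)
    stop_validation("sum of tissue blood flows (", format(flow_sum),
                    " L/h) must equal cardiac_output (",
                    format(cardiac_output), " L/h) within 1e-6 relative")

  structure(
    list(body_weight = body_weight,
         cardiac_output = cardiac_output,
         blood_volumes = blood_volumes[c("venous", "arterial")],
         lung = lung[c("volume_vascular", "volume_tissue", "PS", "fu_tissue")],
         tissues = tissues[, needed],
         hepatic_clearance = hepatic_clearance,
         compound = compound),
    class = "pbpk_params"
  )
}

#' @export
print.pbpk_params <- function(x, ...) {
  cat("Permeability-limited whole-body PBPK parameter set\n")
  cat(sprintf("  body weight     : %.1f kg\n", x$body_weight))
  cat(sprintf("  cardiac output  : %.1f L/h\n", x$cardiac_output))
  cat(sprintf("  hepatic CL      : %.2f L/h (on unbound liver tissue)\n",
              x$hepatic_clearance))
  cat(sprintf("  tissues (%d)     : %s\n", nrow(x$tissues),
              paste(x$tissues$name, collapse = ", ")))
  cat(sprintf("  compound        : MW %.2f g/mol, fu %.3f, B:P %.2f\n",
              x$compound$molecular_weight, x$compound$fu_plasma,
              x$compound$blood_plasma_ratio))
  invisible(x)
}

# unbound fraction referred to whole blood, used on the vascular side of
# the PS exchange terms
fu_blood <- function(params) {
  params$compound$fu_plasma / params$compound$blood_plasma_ratio
}

#' Read a PBPK parameter file
#'
#' Loads a YAML parameter file with explicit units into a validated
#' [pbpk_params()] object. Unknown top-level keys are rejected so a typo
#' cannot silently drop a parameter. The packaged human and rat fixtures
#' can be listed with
#' `system.file("extdata", package = "revdosim")`.
#'
#' @param path Path to a YAML file. See
#'   `system.file("extdata", "pbpk_human.yaml", package = "revdosim")`
#'   for the schema.
#' @return A `pbpk_params` object.
#' @export
read_pbpk_params <- function(path) {
  if (!file.exists(path)) stop_validation("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- c("description", "units", "species", "body_weight",
               "cardiac_output", "blood_volumes", "lung", "tissues",
               "hepatic_clearance", "compound")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop_validation("unknown keys in parameter file: ",
                    paste(unknown, collapse = ", "))
  for (nm in c("body_weight", "cardiac_output", "blood_volumes", "lung",
               "tissues", "hepatic_clearance", "compound"))
    if (is.null(raw[[nm]])) stop_validation("parameter file missing key: ", nm)

  tissues <- do.call(rbind, lapply(raw$tissues, function(t) {
    data.frame(name = t$name,
               volume_vascular = t$volume_vascular,
               volume_tissue = t$volume_tissue,
               blood_flow = t$blood_flow,
               PS = t$PS,
               fu_tissue = t$fu_tissue,
               stringsAsFactors = FALSE)
  }))
  comp <- raw$compound
  pbpk_params(
    body_weight = raw$body_weight,
    cardiac_output = raw$cardiac_output,
    blood_volumes = raw$blood_volumes,
    lung = raw$lung,
    tissues = tissues,
    hepatic_clearance = raw$hepatic_clearance,
    compound = compound_properties(
      molecular_weight = comp$molecular_weight,
      fu_plasma = comp$fu_plasma,
      blood_plasma_ratio = comp$blood_plasma_ratio
    )
  )
}

#' Packaged PBPK parameter fixtures
#'
#' Convenience loader for the parameter files shipped with the package:
#' `"human"` (73 kg reference subject) or `"rat"` (250 g). Both are
#' synthetic, literature-style parameterizations documented in the YAML
#' headers; the human brain entry is calibrated so that the day-14 brain
#' exposure per unit dose reproduces published amiodarone reverse-dosimetry
#' scaling.
#'
#' @param species `"human"` or `"rat"`.
#' @return A `pbpk_params` object.
#' @export
pbpk_fixture <- function(species = c("human", "rat")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("pbpk_", species, ".yaml"),
                      package = "revdosim")
  read_pbpk_params(path)
}

#' Intravenous dosing regimen
#'
#' @param dose Dose per administration in mg, >= 0.
#' @param n_doses Number of administrations (integer >= 1).
#' @param interval Dosing interval in h; required > 0 when `n_doses > 1`.
#' @param infusion_duration Infusion length in h; 0 means an instantaneous
#'   bolus into venous blood.
#' @return An object of class `dosing_regimen` (route is always
#'   intravenous).
#' @export
#' @examples
#' dosing_regimen(100)                       # single 100 mg bolus
#' dosing_regimen(50, n_doses = 14, interval = 24)  # daily for 14 days
dosing_regimen <- function(dose, n_doses = 1L, interval = 24,
                           infusion_duration = 0) {
  check_scalar(dose, "dose", lower = 0)
  if (!is.numeric(n_doses) || length(n_doses) != 1L || n_doses < 1 ||
      n_doses != round(n_doses))
    stop_validation("n_doses must be an integer >= 1")
  check_scalar(infusion_duration, "infusion_duration", lower = 0)
  if (n_doses > 1) check_scalar(interval, "interval", lower = 0, lower_open = TRUE)
  structure(
    list(dose = dose, route = "intravenous", n_doses = as.integer(n_doses),
         interval = interval, infusion_duration = infusion_duration),
    class = "dosing_regimen"
  )
}

#' @export
print.dosing_regimen <- function(x, ...) {
  kind <- if (x$infusion_duration > 0)
    sprintf("%.2g-h infusion", x$infusion_duration) else "bolus"
  if (x$n_doses == 1L)
    cat(sprintf("i.v. %s: %.4g mg\n", kind, x$dose))
  else
    cat(sprintf("i.v. %s: %.4g mg every %g h, %d doses\n",
                kind, x$dose, x$interval, x$n_doses))
  invisible(x)
}

regimen_span <- function(regimen) {
  (regimen$n_doses - 1L) * (if (regimen$n_doses > 1L) regimen$interval else 0) +
    regimen$infusion_duration
}
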