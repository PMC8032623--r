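#' Scalar dose conversions
#'
#' The three conversions that turn a benchmark dose from the intravenous
#' PBPK frame into the quantities reported for humans and rats:
#'
#' * `iv_to_oral()`: divides an i.v. dose by the oral bioavailability
#'   `F` (human amiodarone default 0.65; rat 0.35).
#' * `perkg_to_total()`: multiplies a per-kg dose by body weight
#'   (default reference subject 73 kg).
#' * `free_to_total()`: scales a free-drug dose to a total dose using the
#'   plasma unbound fraction Fu (default 0.06). Two conventions are
#'   implemented: `"fraction_standard"` divides by Fu (the dimensionally
#'   standard rule, free = Fu x total), while `"table_printed"`
#'   multiplies by `100 / Fu`, the rule used in published amiodarone
#'   nominal-concentration tables (it treats Fu as a percentage and is
#'   needed to reproduce those printed totals). The applied convention is
#'   recorded in the result's `"convention"` attribute.
#'
#' All three are linear and exactly invertible.
#'
#' @param dose_iv I.v. dose (mg/kg or mg), >= 0, vectorized.
#' @param F Oral bioavailability fraction in (0, 1].
#' @return Converted dose, same shape as the input.
#' @export
#' @examples
#' iv_to_oral(5.28, 0.65)          # 8.12 mg/kg
#' perkg_to_total(8.12, 73)        # ~593 mg
#' free_to_total(6.5, 0.06, "table_printed")  # 10833.3 mg
iv_to_oral <- function(dose_iv, F = 0.65) {
  check_scalar(F, "F", lower = 0, upper = 1, lower_open = TRUE)
  if (any(dose_iv < 0)) stop_validation("dose_iv must be >= 0")
  dose_iv / F
}

#' @rdname iv_to_oral
#' @param dose Per-kg dose (mg/kg), vectorized.
#' @param body_weight Body weight in kg, > 0.
#' @export
perkg_to_total <- function(dose, body_weight = 73) {
  check_scalar(body_weight, "body_weight", lower = 0, lower_open = TRUE)
  dose * body_weight
}

#' @rdname iv_to_oral
#' @param dose_free Free-drug dose (mg), vectorized.
#' @param fu Plasma unbound fraction in (0, 1].
#' @param convention `"fraction_standard"` (dose/fu) or
#'   `"table_printed"` (dose x 100 / fu).
#' @export
free_to_total <- function(dose_free, fu = 0.06,
                          convention = c("fraction_standard",
                                         "table_printed")) {
  convention <- match.arg(convention)
  check_scalar(fu, "fu", lower = 0, upper = 1, lower_open = TRUE)
  if (any(dose_free < 0)) stop_validation("dose_free must be >= 0")
  out <- if (convention == "table_printed") dose_free * 100 / fu
         else dose_free / fu
  attr(out, "convention") <- convention
  out
}

#' Conversion factor set
#'
#' Bundles the conversion constants for one species so the pipeline can
#' switch species by swapping a single object. Defaults are the human
#' amiodarone values (F = 0.65, 73 kg, Fu = 0.06); `species = "rat"`
#' gives F = 0.35 and 0.25 kg.
#'
#' @param F Oral bioavailability in (0, 1].
#' @param body_weight Body weight in kg.
#' @param fu_plasma Plasma unbound fraction in (0, 1].
#' @param species Convenience preset, `"human"` or `"rat"`; explicit
#'   arguments override the preset.
#' @return A list of class `conversion_factors`.
#' @export
conversion_factors <- function(F = NULL, body_weight = NULL,
                               fu_plasma = 0.06,
                               species = c("human", "rat")) {
  species <- match.arg(species)
  F <- F %||% switch(species, human = 0.65, rat = 0.35)
  body_weight <- body_weight %||% switch(species, human = 73, rat = 0.25)
  check_scalar(F, "F", lower = 0, upper = 1, lower_open = TRUE)
  check_scalar(body_weight, "body_weight", lower = 0, lower_open = TRUE)
  check_scalar(fu_plasma, "fu_plasma", lower = 0, upper = 1,
               lower_open = TRUE)
  structure(list(F = F, body_weight = body_weight, fu_plasma = fu_plasma,
                 species = species),
            class = "conversion_factors")
}

#' @export
print.conversion_factors <- function(x, ...) {
  cat(sprintf("Conversion factors (%s): F = %.2f, BW = %.3g kg, Fu = %.2f\n",
              x$species, x$F, x$body_weight, x$fu_plasma))
  invisible(x)
}

#' Convert a benchmark-dose table to oral totals
#'
#' Applies the conversion chain to a set of BMD interval rows and returns
#' the human-readable summary table: for rows from the measured-metric
#' approaches (AUC, Cmax) the i.v. mg/kg BMDU is converted to an oral
#' mg/kg dose via `F` and then to a total mg dose via body weight; for a
#' nominal-concentration row the already-oral free BMDU (mg) is scaled to
#' a total dose with the `table_printed` free-to-total rule (a notice is
#' attached, since that rule is dimensionally irregular but is what
#' published nominal-concentration totals use). Unrounded values are kept
#' alongside display-rounded ones (mg/kg to 2 decimals, totals to 1).
#'
#' @param bmdl,bmdu Numeric vectors of interval bounds, one element per
#'   approach, in mg/kg i.v. (or, for a nominal row with
#'   `nominal_input = "free_oral_mg"`, an already-converted free oral
#'   total in mg).
#' @param approach Character vector labelling each row; a row named
#'   `"nominal"` gets the free-to-total treatment.
#' @param factors A [conversion_factors()].
#' @param nominal_input Frame of the nominal row's numbers:
#'   `"iv_mg_per_kg"` (default; the full chain /F, x BW, x 100/Fu is
#'   applied) or `"free_oral_mg"` (only the free-to-total step remains,
#'   as when auditing a printed free oral dose).
#' @return A data frame with columns `approach`, `bmdl`, `bmdu`,
#'   `oral_mg_per_kg`, `total_oral_mg` (unrounded) and rounded display
#'   columns `oral_mg_per_kg_2dp`, `total_oral_mg_1dp`.
#' @export
bmd_conversion_table <- function(bmdl, bmdu, approach,
                                 factors = conversion_factors(),
                                 nominal_input = c("iv_mg_per_kg",
                                                   "free_oral_mg")) {
  nominal_input <- match.arg(nominal_input)
  if (!(length(bmdl) == length(bmdu) && length(bmdu) == length(approach)))
    stop_validation("bmdl, bmdu, approach must have equal length")
  oral <- numeric(length(bmdu))
  total <- numeric(length(bmdu))
  for (i in seq_along(bmdu)) {
    if (approach[i] == "nominal") {
      free_oral <- if (nominal_input == "iv_mg_per_kg")
        perkg_to_total(iv_to_oral(bmdu[i], factors$F), factors$body_weight)
      else bmdu[i]
      oral[i] <- NA_real_
      total[i] <- as.numeric(free_to_total(free_oral, factors$fu_plasma,
                                           "table_printed"))
    } else {
      oral[i] <- iv_to_oral(bmdu[i], factors$F)
      total[i] <- perkg_to_total(oral[i], factors$body_weight)
    }
  }
  out <- data.frame(
    approach = approach, bmdl = bmdl, bmdu = bmdu,
    oral_mg_per_kg = oral, total_oral_mg = total,
    oral_mg_per_kg_2dp = round(oral, 2),
    total_oral_mg_1dp = round(total, 1)
  )
  if ("nominal" %in% approach)
    attr(out, "notice") <-
      "nominal row converted with the table_printed (x 100/Fu) rule"
  out
}
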