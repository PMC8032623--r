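#' Convert a per-flask amount to a concentration
#'
#' In vitro biokinetic measurements are often reported as total amounts per
#' culture flask; dividing by the relevant compartment volume (medium
#' volume for the medium, lysate volume for the cell fraction) expresses
#' them as concentrations directly comparable with simulated tissue
#' concentrations.
#'
#' @param amount Amount in µg (vectorized).
#' @param volume Compartment volume in mL, > 0.
#' @return Concentration in µg/mL.
#' @export
per_flask_to_concentration <- function(amount, volume) {
  check_scalar(volume, "volume", lower = 0, lower_open = TRUE)
  if (any(!is.finite(amount)) || any(amount < 0))
    stop_validation("amount must be finite and >= 0")
  amount / volume
}

#' @rdname per_flask_to_concentration
#' @param concentration Concentration in µg/mL (vectorized).
#' @export
concentration_to_per_flask <- function(concentration, volume) {
  check_scalar(volume, "volume", lower = 0, lower_open = TRUE)
  concentration * volume
}

#' Molar/mass concentration conversions
#'
#' `micromolar_to_ugml()` converts µM to µg/mL (= mg/L) using the
#' molecular weight; `ugml_to_micromolar()` is its inverse. For amiodarone
#' (MW 645.31 g/mol) the nominal exposure levels 1.25 and 2.5 µM
#' correspond to 0.807 and 1.613 µg/mL.
#'
#' @param conc Concentration (µM or µg/mL respectively), >= 0, vectorized.
#' @param mw Molecular weight in g/mol, > 0.
#' @return Converted concentration.
#' @export
micromolar_to_ugml <- function(conc, mw) {
  check_scalar(mw, "mw", lower = 0, lower_open = TRUE)
  if (any(conc < 0)) stop_validation("conc must be >= 0")
  conc * mw / 1000
}

#' @rdname micromolar_to_ugml
#' @export
ugml_to_micromolar <- function(conc, mw) {
  check_scalar(mw, "mw", lower = 0, lower_open = TRUE)
  conc * 1000 / mw
}

#' Trapezoidal area under a concentration-time profile
#'
#' Linear-trapezoid AUC over the window `[t0, t1]`. The window must be
#' covered by the observations; the endpoint values are linearly
#' interpolated from the bracketing points when `t0` or `t1` fall between
#' samples. No extrapolation beyond the first or last observation is
#' performed.
#'
#' @param time Sampling times in h, strictly increasing, >= 2 points.
#' @param conc Concentrations (µg/mL), same length as `time`.
#' @param t0,t1 Window bounds in h, `t1 > t0`, both within
#'   `[min(time), max(time)]`.
#' @return AUC in µg·h/mL.
#' @export
#' @examples
#' auc_trapezoid(c(0, 12, 24), c(0, 0.1, 0), 0, 24)  # triangle: 1.2
auc_trapezoid <- function(time, conc, t0 = min(time), t1 = max(time)) {
  if (length(time) < 2L)
    stop_validation("at least two points are required for an AUC")
  if (length(conc) != length(time))
    stop_validation("time and conc must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop_validation("time must be strictly increasing")
  if (t1 <= t0) stop_validation("window must satisfy t1 > t0")
  if (t0 < min(time) - 1e-9 || t1 > max(time) + 1e-9)
    stop_validation(sprintf(
      "window [%g, %g] not covered by observations [%g, %g]",
      t0, t1, min(time), max(time)))

  inside <- time > t0 & time < t1
  tt <- c(t0, time[inside], t1)
  cc <- c(stats::approx(time, conc, xout = t0)$y,
          conc[inside],
          stats::approx(time, conc, xout = t1)$y)
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Observed peak concentration
#'
#' Maximum measured concentration in a profile, optionally restricted to a
#' window. Unlike a model-predicted Cmax this is taken directly over the
#' sampled points, which is how sparse in vitro profiles are summarized.
#'
#' @inheritParams auc_trapezoid
#' @return Cmax in µg/mL.
#' @export
observed_cmax <- function(time, conc, t0 = -Inf, t1 = Inf) {
  if (length(time) < 1L) stop_validation("profile is empty")
  if (length(conc) != length(time))
    stop_validation("time and conc must have equal length")
  keep <- time >= t0 & time <= t1
  if (!any(keep)) stop_validation("no observations inside the window")
  max(conc[keep])
}

#' Read an in vitro biokinetic dataset
#'
#' Reads a tidy CSV of in vitro concentration-time measurements together
#' with a YAML sidecar giving the compartment volumes. The CSV must have
#' columns `level_uM` (nominal exposure, µM), `day` (0 or 14),
#' `compartment` (`medium`, `cells`, `plastic`, optionally `metabolite`),
#' `time_h`, `value`, `value_kind` (`amount_per_flask` or `concentration`)
#' and `unit` (`ug` or `ug_per_ml`, matching `value_kind`). Per-flask
#' amounts are converted to µg/mL with the medium volume (medium) or the
#' lysate volume (cells, plastic, metabolite).
#'
#' @param csv_path Path to the measurement CSV.
#' @param volumes_path Path to a YAML file with `medium_volume_ml` and
#'   `lysate_volume_ml`. The lysate volume has no default: it must be
#'   supplied by the dataset.
#' @return An object of class `invitro_dataset`: a list with the
#'   harmonized measurement data frame (`data`, concentrations in µg/mL)
#'   and the `volumes` list.
#' @export
read_invitro_dataset <- function(csv_path, volumes_path) {
  if (!file.exists(csv_path)) stop_validation("dataset not found: ", csv_path)
  if (!file.exists(volumes_path))
    stop_validation("volumes sidecar not found: ", volumes_path)
  dat <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  vols <- yaml::read_yaml(volumes_path)
  needed <- c("level_uM", "day", "compartment", "time_h", "value",
              "value_kind", "unit")
  missing_cols <- setdiff(needed, names(dat))
  if (length(missing_cols))
    stop_validation("dataset missing columns: ",
                    paste(missing_cols, collapse = ", "))
  for (nm in c("medium_volume_ml", "lysate_volume_ml"))
    check_scalar(vols[[nm]] %||% NA_real_, nm, lower = 0, lower_open = TRUE)

  ok_units <- c(amount_per_flask = "ug", concentration = "ug_per_ml")
  bad <- dat$unit != ok_units[dat$value_kind]
  if (any(bad | is.na(bad)))
    stop_validation("unit/value_kind mismatch in rows: ",
                    paste(utils::head(which(bad | is.na(bad)), 5), collapse = ", "))
  if (any(dat$value < 0)) stop_validation("negative measurements present")

  vol_for <- ifelse(dat$compartment == "medium",
                    vols$medium_volume_ml, vols$lysate_volume_ml)
  dat$conc_ug_ml <- ifelse(dat$value_kind == "amount_per_flask",
                           dat$value / vol_for, dat$value)
  invitro_dataset(dat, vols)
}

# internal constructor shared by the reader and the synthetic generator
invitro_dataset <- function(data, volumes) {
  ord <- order(data$level_uM, data$day, data$compartment, data$time_h)
  data <- data[ord, , drop = FALSE]
  by <- interaction(data$level_uM, data$day, data$compartment, drop = TRUE)
  for (g in split(seq_len(nrow(data)), by)) {
    tg <- unique(data$time_h[g])
    if (length(tg) < 2L && data$compartment[g[1]] != "metabolite")
      stop_validation("each compartment profile needs >= 2 time points")
  }
  structure(list(data = data, volumes = volumes), class = "invitro_dataset")
}

#' @export
print.invitro_dataset <- function(x, ...) {
  d <- x$data
  cat("In vitro biokinetic dataset\n")
  cat(sprintf("  levels (uM) : %s\n",
              paste(sort(unique(d$level_uM)), collapse = ", ")))
  cat(sprintf("  days        : %s\n",
              paste(sort(unique(d$day)), collapse = ", ")))
  cat(sprintf("  compartments: %s\n",
              paste(sort(unique(d$compartment)), collapse = ", ")))
  cat(sprintf("  rows        : %d; medium %.1f mL, lysate %.2f mL\n",
              nrow(d), x$volumes$medium_volume_ml, x$volumes$lysate_volume_ml))
  invisible(x)
}

#' Kinetic exposure metric from an in vitro dataset
#'
#' Computes the AUC over `[t0, t1]` (default 0-24 h relative to the day's
#' dosing) or the observed Cmax for one compartment profile at one
#' exposure level and day. Replicate measurements at the same time point
#' are averaged before the metric is taken, i.e. the metric of the mean
#' profile.
#'
#' @param dataset An `invitro_dataset`.
#' @param level Nominal exposure level in µM.
#' @param day Day index (0 or 14).
#' @param compartment Compartment name (default `"cells"`, the
#'   intracellular fraction).
#' @param metric `"AUC"` or `"Cmax"`.
#' @param t0,t1 Metric window in h relative to that day's dose.
#' @return An object of class `kinetic_metric`: list with `kind`, `value`
#'   (µg·h/mL for AUC, µg/mL for Cmax), `window`, and `source =
#'   "measured_in_vitro"`.
#' @export
invitro_metric <- function(dataset, level, day, compartment = "cells",
                           metric = c("AUC", "Cmax"), t0 = 0, t1 = 24) {
  metric <- match.arg(metric)
  d <- dataset$data
  sel <- d$level_uM == level & d$day == day & d$compartment == compartment
  if (!any(sel))
    stop_validation(sprintf("no data for level %g uM, day %d, %s",
                            level, day, compartment))
  prof <- stats::aggregate(conc_ug_ml ~ time_h, data = d[sel, ], FUN = mean)
  value <- if (metric == "AUC")
    auc_trapezoid(prof$time_h, prof$conc_ug_ml, t0, t1)
  else
    observed_cmax(prof$time_h, prof$conc_ug_ml, t0, t1)
  kinetic_metric(metric, value, c(t0, t1), source = "measured_in_vitro")
}

kinetic_metric <- function(kind, value, window, source) {
  if (value < 0) stop_validation("metric value must be >= 0")
  structure(list(kind = kind, value = value, window = window,
                 source = source),
            class = "kinetic_metric")
}

#' @export
print.kinetic_metric <- function(x, ...) {
  unit <- if (x$kind == "AUC") "ug*h/mL" else "ug/mL"
  cat(sprintf("%s[%g-%g h] = %.4g %s (%s)\n", x$kind, x$window[1],
              x$window[2], x$value, unit, x$source))
  invisible(x)
}
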