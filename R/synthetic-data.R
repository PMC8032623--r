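#' Parameters of the synthetic in vitro biokinetic system
#'
#' Describes a three-pool linear exchange system (culture medium, cells,
#' plastic labware) under repeated every-other-day dosing, emulating the
#' structure of published amiodarone brain-cell biokinetic experiments:
#' strong adsorption to plastic, slow nearly-irreversible cellular
#' accumulation, and a small cellular loss to the desethyl metabolite
#' (2.5-3% of cellular turnover). At each re-dose the medium is fully
#' replaced with fresh drug-containing medium (configurable); cells and
#' plastic keep their load.
#'
#' Default rate constants are calibrated so that a 14-day, every-other-day
#' exposure at 1.25 and 2.5 µM yields day-14 cell AUCs near 1-2 µg·h/mL
#' with day-0 AUCs two orders of magnitude smaller (accumulation), which
#' is the regime the downstream extrapolation operates in. They are a
#' calibration, not measured ground truth.
#'
#' @param medium_volume_ml Medium volume per flask, mL.
#' @param lysate_volume_ml Cell lysate volume, mL (used to express the
#'   cell amount as a concentration).
#' @param k_medium_cells,k_cells_medium,k_medium_plastic,k_plastic_medium
#'   First-order exchange rates, 1/h, >= 0.
#' @param k_metabolism Cellular first-order loss to metabolite, 1/h.
#' @param level_uM Nominal exposure level, µM.
#' @param molecular_weight Compound molecular weight, g/mol.
#' @param n_days Treatment length in days (dosing every other day from
#'   day 0 through `n_days`).
#' @param sampling_times_h Sampling offsets within the 24 h after the
#'   day-0 and final doses (default five points).
#' @param n_replicates Replicate flasks per time point.
#' @param cv Multiplicative log-normal measurement CV (fraction).
#' @param medium_renewal `"replace"` (default: fresh medium + drug at each
#'   re-dose) or `"add"` (drug added on top of the spent medium).
#' @return A list of class `invitro_system_params`.
#' @export
invitro_system_params <- function(medium_volume_ml = 2,
                                  lysate_volume_ml = 0.1,
                                  k_medium_cells = 3.3e-5,
                                  k_cells_medium = 0.005,
                                  k_medium_plastic = 0.05,
                                  k_plastic_medium = 0.002,
                                  k_metabolism = 0.00015,
                                  level_uM = 1.25,
                                  molecular_weight = 645.31,
                                  n_days = 14L,
                                  sampling_times_h = c(0, 2, 6, 12, 24),
                                  n_replicates = 3L,
                                  cv = 0.15,
                                  medium_renewal = c("replace", "add")) {
  medium_renewal <- match.arg(medium_renewal)
  check_scalar(medium_volume_ml, "medium_volume_ml", lower = 0, lower_open = TRUE)
  check_scalar(lysate_volume_ml, "lysate_volume_ml", lower = 0, lower_open = TRUE)
  for (nm in c("k_medium_cells", "k_cells_medium", "k_medium_plastic",
               "k_plastic_medium", "k_metabolism"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(level_uM, "level_uM", lower = 0)
  check_scalar(cv, "cv", lower = 0)
  if (any(sampling_times_h < 0) || any(sampling_times_h > 24) ||
      is.unsorted(sampling_times_h, strictly = TRUE))
    stop_validation("sampling_times_h must be strictly increasing in [0, 24]")
  structure(
    list(medium_volume_ml = medium_volume_ml,
         lysate_volume_ml = lysate_volume_ml,
         k_medium_cells = k_medium_cells, k_cells_medium = k_cells_medium,
         k_medium_plastic = k_medium_plastic,
         k_plastic_medium = k_plastic_medium,
         k_metabolism = k_metabolism,
         level_uM = level_uM, molecular_weight = molecular_weight,
         n_days = as.integer(n_days),
         sampling_times_h = sampling_times_h,
         n_replicates = as.integer(n_replicates), cv = cv,
         medium_renewal = medium_renewal),
    class = "invitro_system_params"
  )
}

# deterministic trajectory of the 3-pool system in amounts (µg);
# returns a function of time plus the dosing bookkeeping
invitro_trajectory <- function(p) {
  dose_amount <- micromolar_to_ugml(p$level_uM, p$molecular_weight) *
    p$medium_volume_ml
  dose_times <- seq(0, p$n_days * 24, by = 48)

  rhs <- function(t, A, parms) {
    M <- A[1]; C <- A[2]; P <- A[3]
    dM <- -(p$k_medium_cells + p$k_medium_plastic) * M +
      p$k_cells_medium * C + p$k_plastic_medium * P
    dC <- p$k_medium_cells * M - (p$k_cells_medium + p$k_metabolism) * C
    dP <- p$k_medium_plastic * M - p$k_plastic_medium * P
    dMet <- p$k_metabolism * C
    list(c(dM, dC, dP, dMet))
  }

  solve_window <- function(state, times) {
    if (length(times) < 2L)
      return(matrix(state, nrow = 1,
                    dimnames = list(NULL, names(state))))
    out <- deSolve::lsoda(state, times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    unclass(out)[, -1L, drop = FALSE]
  }

  state <- c(medium = dose_amount, cells = 0, plastic = 0, metabolite = 0)
  removed <- 0
  segments <- list()
  for (i in seq_along(dose_times)) {
    t0 <- dose_times[i]
    t1 <- if (i < length(dose_times)) dose_times[i + 1] else t0 + 24
    times <- sort(unique(c(seq(t0, t1, by = 0.5), t0 + p$sampling_times_h)))
    times <- times[times <= t1 + 1e-9]
    traj <- solve_window(state, times - t0)
    segments[[i]] <- cbind(time = times, traj)
    end <- traj[nrow(traj), ]
    if (i < length(dose_times)) {
      if (p$medium_renewal == "replace") {
        removed <- removed + end[["medium"]]
        end[["medium"]] <- dose_amount
      } else {
        end[["medium"]] <- end[["medium"]] + dose_amount
      }
    }
    state <- c(medium = end[["medium"]], cells = end[["cells"]],
               plastic = end[["plastic"]], metabolite = end[["metabolite"]])
  }
  traj <- do.call(rbind, segments)
  list(trajectory = traj, dose_amount = dose_amount,
       dose_times = dose_times, removed = removed)
}

#' Generate a synthetic in vitro biokinetic dataset
#'
#' Simulates the three-pool medium/cells/plastic exchange system of
#' [invitro_system_params()] under every-other-day dosing, samples the
#' day-0 and final-day profiles at the configured five time points,
#' applies multiplicative log-normal measurement noise, and returns the
#' result in the same `invitro_dataset` form the CSV reader produces
#' (cell and plastic measurements as per-flask amounts, medium as a
#' concentration). Before noise, total drug plus metabolite plus medium
#' removed at renewals equals the cumulative dosed amount (linear,
#' conservative system).
#'
#' @param p An [invitro_system_params()].
#' @param seed Integer seed for the measurement noise.
#' @return An `invitro_dataset`. The noise-free trajectory, dosing times
#'   and removed-medium total are attached as attribute `"truth"`.
#' @export
generate_biokinetics <- function(p, seed = 1L) {
  if (!inherits(p, "invitro_system_params"))
    stop_validation("p must be an invitro_system_params")
  sol <- invitro_trajectory(p)
  traj <- sol$trajectory
  last_dose <- max(sol$dose_times)

  sample_day <- function(day_start, day_label) {
    tt <- day_start + p$sampling_times_h
    idx <- vapply(tt, function(t) which.min(abs(traj[, "time"] - t)),
                  integer(1))
    do.call(rbind, lapply(seq_along(tt), function(j) {
      row <- traj[idx[j], ]
      data.frame(
        day = day_label,
        time_h = p$sampling_times_h[j],
        compartment = c("medium", "cells", "plastic", "metabolite"),
        true_value = c(row[["medium"]] / p$medium_volume_ml,
                       row[["cells"]], row[["plastic"]],
                       row[["metabolite"]]),
        value_kind = c("concentration", "amount_per_flask",
                       "amount_per_flask", "amount_per_flask"),
        unit = c("ug_per_ml", "ug", "ug", "ug"),
        stringsAsFactors = FALSE
      )
    }))
  }

  base <- rbind(sample_day(0, 0L), sample_day(last_dose, p$n_days))
  base <- base[rep(seq_len(nrow(base)), each = p$n_replicates), ]
  base$replicate <- rep(seq_len(p$n_replicates), length.out = nrow(base))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sdlog <- sqrt(log(1 + p$cv^2))
  noise <- if (p$cv > 0) exp(stats::rnorm(nrow(base), 0, sdlog)) else 1
  base$value <- base$true_value * noise

  dat <- data.frame(level_uM = p$level_uM, day = base$day,
                    compartment = base$compartment, time_h = base$time_h,
                    value = base$value, value_kind = base$value_kind,
                    unit = base$unit, replicate = base$replicate,
                    stringsAsFactors = FALSE)
  dat$conc_ug_ml <- ifelse(dat$value_kind == "amount_per_flask",
                           dat$value / p$lysate_volume_ml, dat$value)
  ds <- invitro_dataset(dat, list(medium_volume_ml = p$medium_volume_ml,
                                  lysate_volume_ml = p$lysate_volume_ml))
  attr(ds, "truth") <- sol
  ds
}

#' Write an in vitro dataset to CSV + YAML sidecar
#'
#' Inverse of [read_invitro_dataset()]: writes the measurement table (raw
#' values, not the derived concentrations) and the volume sidecar.
#'
#' @param dataset An `invitro_dataset`.
#' @param csv_path,volumes_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_invitro_dataset <- function(dataset, csv_path, volumes_path) {
  cols <- c("level_uM", "day", "compartment", "time_h", "value",
            "value_kind", "unit")
  utils::write.csv(dataset$data[, cols], csv_path, row.names = FALSE)
  yaml::write_yaml(dataset$volumes, volumes_path)
  invisible(c(csv = csv_path, yaml = volumes_path))
}

#' Truth parameters for synthetic ChAT-activity responses
#'
#' Defines the underlying decreasing concentration-response curve
#' (default: 5-parameter exponential with background 100% of control)
#' from which synthetic choline-acetyltransferase activity data are
#' drawn.
#'
#' @param family Curve family (see [bmd_fit()] families).
#' @param a Background response (control = 100%).
#' @param b Potency parameter (on the axis the curve will be evaluated
#'   on).
#' @param d Shape parameter.
#' @param c Asymptotic fraction of background remaining (5-parameter
#'   families only).
#' @param sd Per-group response SD in % of control.
#' @param n Group size.
#' @return A list of class `chat_truth_params`.
#' @export
chat_truth_params <- function(family = "exp5", a = 100, b = 0.5, d = 1.5,
                              c = 0.4, sd = 5, n = 5L) {
  family <- match.arg(family, bmd_families)
  check_scalar(sd, "sd", lower = 0)
  if (n < 2) stop_validation("n must be >= 2")
  par <- list(a = a, b = b, d = d)
  if (family_has_c(family)) par$c <- c
  f <- drc_curve(family, par)
  structure(list(family = family, par = par, sd = sd, n = as.integer(n),
                 curve = f),
            class = "chat_truth_params")
}

#' Generate a synthetic ChAT dose-response dataset
#'
#' Draws group summary statistics around the truth curve: each group mean
#' is normal with mean `f(dose)` and standard error `sd/sqrt(n)`, each
#' group SD is drawn from the matching scaled chi-square distribution.
#' With `sd = 0` the means lie exactly on the curve. Fully reproducible
#' given the seed; the caller's RNG state is restored.
#'
#' @param doses Dose (or in vitro level) vector, >= 3 values including 0.
#' @param truth A [chat_truth_params()].
#' @param seed Integer seed.
#' @return A [drc_data()] (if `sd > 0`) or a plain data frame with an
#'   `sd` column of zeros (if `sd = 0`, which `drc_data` would reject).
#' @export
generate_chat_response <- function(doses, truth = chat_truth_params(),
                                   seed = 1L) {
  if (length(doses) < 3L || !any(doses == 0))
    stop_validation("at least 3 doses including a 0 control are required")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  mu <- truth$curve(doses)
  if (truth$sd == 0) {
    out <- data.frame(dose = doses, mean = mu, sd = 0, n = truth$n)
    return(out[order(out$dose), ])
  }
  m <- stats::rnorm(length(doses), mu, truth$sd / sqrt(truth$n))
  s <- truth$sd * sqrt(stats::rchisq(length(doses), truth$n - 1) /
                         (truth$n - 1))
  s <- pmax(s, 1e-6 * truth$sd)
  drc_data(dose = doses, mean = m, sd = s, n = rep(truth$n, length(doses)))
}

#' Closed-form benchmark dose of a truth curve
#'
#' For a [chat_truth_params()] truth, solves `f(0) - f(x) = bmr_sd * sd`
#' with the same bracketing root-finder the fitting path uses, but on the
#' known curve — handy as an oracle in recovery studies.
#'
#' @param truth A `chat_truth_params`.
#' @param xmax Search scale (maximum relevant dose).
#' @param bmr_sd Benchmark response in SD units.
#' @return The true BMD.
#' @export
chat_truth_bmd <- function(truth, xmax, bmr_sd = 1) {
  as.numeric(bmd_solve(truth$curve, bmr_sd * truth$sd, xmax))
}
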