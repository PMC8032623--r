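#' Dose-response summary data
#'
#' Validated container for a continuous, decreasing dose-response dataset
#' in summary form: one row per dose group with mean response (typically %
#' of control activity), sample SD and group size. A dose-0 control group
#' is required.
#'
#' @param dose Doses (e.g. mg/kg), >= 0, with at least one 0.
#' @param mean Group mean responses.
#' @param sd Group sample SDs, > 0.
#' @param n Group sizes, integers >= 2.
#' @return A data frame of class `drc_data` sorted by dose.
#' @export
#' @examples
#' drc_data(dose = c(0, 1, 3, 10), mean = c(100, 92, 75, 50),
#'          sd = c(5, 6, 5, 7), n = c(5, 5, 5, 5))
drc_data <- function(dose, mean, sd, n) {
  if (!(length(dose) == length(mean) && length(mean) == length(sd) &&
        length(sd) == length(n)))
    stop_validation("dose, mean, sd, n must have equal length")
  if (any(dose < 0)) stop_validation("doses must be >= 0")
  if (!any(dose == 0)) stop_validation("a dose-0 control group is required")
  if (anyDuplicated(dose)) stop_validation("doses must be distinct")
  if (any(sd <= 0)) stop_validation("group SDs must be > 0")
  if (any(n < 2) || any(n != round(n)))
    stop_validation("group sizes must be integers >= 2")
  out <- data.frame(dose = dose, mean = mean, sd = sd, n = as.integer(n))
  out <- out[order(out$dose), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("drc_data", "data.frame")
  out
}

# summary-data normal log-likelihood pieces ---------------------------------

# pooled within-group sum of squares plus lack-of-fit, given fitted means
drc_ss <- function(data, fitted) {
  sum((data$n - 1) * data$sd^2 + data$n * (data$mean - fitted)^2)
}

# profile log-likelihood: sigma^2 maximized out analytically
drc_loglik_from_ss <- function(ss, N) {
  -N / 2 * (log(2 * pi * ss / N) + 1)
}

# log-likelihood of the saturated model (one free mean per group,
# common sigma)
drc_loglik_saturated <- function(data) {
  N <- sum(data$n)
  drc_loglik_from_ss(sum((data$n - 1) * data$sd^2), N)
}

#' Fit a continuous dose-response model by maximum likelihood
#'
#' Fits one member of the exponential/Hill family suite to summary
#' dose-response data assuming normal residuals with a common standard
#' deviation. The likelihood is built from the group means, SDs and sizes
#' (no individual observations needed); the residual SD is profiled out
#' analytically. Optimization uses `stats::nlminb` from a deterministic
#' lattice of 10 starting points; the best converged likelihood wins,
#' ties going to the first found, so the fit is fully reproducible.
#'
#' Internally doses are rescaled by the maximum dose before optimization
#' and the parameters mapped back, making the fit exactly equivariant
#' under rescaling of the dose axis.
#'
#' @param data A [drc_data()] with at least 3 dose groups.
#' @param family One of `"exp3"`, `"exp5"`, `"hill3"`, `"hill5"`.
#' @param start Optional warm-start parameter list (natural scale); it is
#'   prepended to the start lattice.
#' @param n_starts Number of lattice starts to use (default all 10;
#'   reduced internally during bootstrap refits).
#' @return An object of class `bmd_fit`: list with `family`, `par`
#'   (natural-scale named list: `a`, `b`, `d`, optionally `c`), `sigma`
#'   (residual SD, degrees-of-freedom corrected), `loglik`, `aic`
#'   (counting curve parameters plus
#'   sigma), `gof_p` (likelihood-ratio lack-of-fit p-value against the
#'   saturated means model), `converged`, and the data.
#' @export
bmd_fit <- function(data, family = c("exp3", "exp5", "hill3", "hill5"),
                    start = NULL, n_starts = 10L) {
  family <- match.arg(family)
  if (!inherits(data, "drc_data")) stop_validation("data must be a drc_data")
  if (nrow(data) < 3L)
    stop_validation("at least 3 dose groups (including control) are needed")

  xmax <- max(data$dose)
  u <- data$dose / xmax
  N <- sum(data$n)
  a0 <- data$mean[data$dose == 0]
  floor_frac <- min(data$mean) / a0

  # profile the background a analytically: for f = a * g the ML estimate
  # given g is a-hat = sum(n m g) / sum(n g^2)
  profile_a <- function(g) {
    max(sum(data$n * data$mean * g) / sum(data$n * g^2), 1e-12)
  }
  nll <- function(theta) {
    bpar <- theta_to_bpar(family, theta)
    g <- drc_g(family, bpar)(u)
    if (any(!is.finite(g))) return(1e10)
    a_hat <- profile_a(g)
    ss <- drc_ss(data, a_hat * g)
    if (!is.finite(ss) || ss <= 0) return(1e10)
    -drc_loglik_from_ss(ss, N)
  }

  starts <- if (n_starts > 0)
    start_lattice(family, 1, floor_frac)[seq_len(min(n_starts, 10L))]
  else list()
  if (!is.null(start)) {
    # map a natural-scale warm start into the rescaled dose space
    ws <- start
    ws$b <- if (startsWith(family, "exp")) start$b * xmax^start$d
            else start$b / xmax
    starts <- c(list(bpar_to_theta(family, ws)), starts)
  }
  if (!length(starts))
    stop_validation("no starting points (n_starts = 0 without a warm start)")

  bounds <- theta_bounds(family)
  best <- NULL
  for (th0 in starts) {
    opt <- tryCatch(
      stats::nlminb(th0, nll, lower = bounds$lower, upper = bounds$upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective - 1e-10) best <- opt
  }
  if (is.null(best))
    return(structure(list(family = family, converged = FALSE, data = data),
                     class = "bmd_fit"))

  bpar_u <- theta_to_bpar(family, best$par)
  g_u <- drc_g(family, bpar_u)(u)
  par <- bpar_u
  par$a <- profile_a(g_u)
  par <- par[c("a", "b", "d", if (family_has_c(family)) "c")]
  par$b <- if (startsWith(family, "exp")) bpar_u$b / xmax^bpar_u$d
           else bpar_u$b * xmax
  fitted <- drc_curve(family, par)(data$dose)
  ss <- drc_ss(data, fitted)
  ll <- drc_loglik_from_ss(ss, N)
  k_curve <- family_npar(family)
  # reported residual SD is the df-corrected estimator (the ML sigma^2 =
  # SS/N is biased low by (N - k)/N); the likelihood itself stays ML
  sigma <- sqrt(ss / max(N - k_curve, 1L))
  aic <- 2 * (k_curve + 1) - 2 * ll   # +1 for sigma

  # lack-of-fit LR test vs the saturated means model; df counts the
  # curve parameters (sigma is common to both models)
  df <- nrow(data) - k_curve
  ll_sat <- drc_loglik_saturated(data)
  lr <- max(0, 2 * (ll_sat - ll))
  gof_p <- if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE)
           else if (lr < 1e-6) 1 else NA_real_

  structure(
    list(family = family, par = par, sigma = sigma, loglik = ll, aic = aic,
         gof_p = gof_p, gof_df = df, converged = TRUE, data = data,
         fitted = fitted),
    class = "bmd_fit"
  )
}

#' @export
print.bmd_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("bmd_fit [%s]: did not converge\n", x$family))
    return(invisible(x))
  }
  cat(sprintf("bmd_fit [%s]  logLik %.3f  AIC %.2f  lack-of-fit p %s\n",
              x$family, x$loglik, x$aic,
              if (is.na(x$gof_p)) "NA" else sprintf("%.3f", x$gof_p)))
  cat("  ", paste(sprintf("%s = %.4g", names(x$par), unlist(x$par)),
                  collapse = ", "),
      sprintf(", sigma = %.4g\n", x$sigma))
  invisible(x)
}

#' @export
coef.bmd_fit <- function(object, ...) {
  c(unlist(object$par), sigma = object$sigma)
}

#' @export
logLik.bmd_fit <- function(object, ...) {
  structure(object$loglik, df = family_npar(object$family) + 1L,
            class = "logLik")
}

#' @export
predict.bmd_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose
       else if (is.data.frame(newdata)) newdata$dose else newdata
  drc_curve(object$family, object$par)(x)
}

#' @export
residuals.bmd_fit <- function(object, ...) {
  object$data$mean - object$fitted
}

# bracketed root of f(0) - f(x) = drop on (0, 10 * xmax] ------------------

bmd_solve <- function(f, drop, xmax, rel_tol = 1e-8) {
  g <- function(x) (f(0) - f(x)) - drop
  # a curve essentially flat across the whole tested range supports no
  # benchmark dose: any crossing beyond xmax would rest purely on
  # extrapolating an unidentified shape
  if (f(0) - f(xmax) < 1e-6 * drop)
    return(structure(NA_real_, reason = "bmr_not_reached"))
  hi <- xmax
  limit <- 10 * xmax
  while (g(hi) < 0 && hi < limit) hi <- min(2 * hi, limit)
  if (g(hi) < 0)
    return(structure(NA_real_, reason = "bmr_not_reached"))
  lo <- 0
  root <- stats::uniroot(g, lower = lo, upper = hi,
                         tol = rel_tol * max(hi, 1e-12))$root
  root
}

#' Benchmark dose from a fitted curve
#'
#' The benchmark dose is the smallest positive dose at which the fitted
#' response has fallen by the benchmark response: `f(0) - f(BMD) =
#' bmr_sd * background_sd`. The default benchmark response is 1 SD of the
#' background response, with the model residual SD as the background SD
#' (the control-group sample SD can be supplied instead via
#' `background_sd`). The root is found by bracketing and bisection to a
#' relative tolerance of 1e-8, searching up to 10 times the maximum
#' tested dose.
#'
#' @param fit A converged `bmd_fit`.
#' @param bmr_sd Benchmark response magnitude in background-SD units
#'   (default 1).
#' @param background_sd Background response SD; defaults to the fit's
#'   residual `sigma`.
#' @return The BMD in dose units, or `NA` with attribute
#'   `reason = "bmr_not_reached"` if the curve never falls that far
#'   within 10x the maximum dose.
#' @export
bmd_from_fit <- function(fit, bmr_sd = 1, background_sd = NULL) {
  if (!isTRUE(fit$converged)) stop_validation("fit did not converge")
  check_scalar(bmr_sd, "bmr_sd", lower = 0, lower_open = TRUE)
  s <- background_sd %||% fit$sigma
  f <- drc_curve(fit$family, fit$par)
  bmd_solve(f, bmr_sd * s, max(fit$data$dose))
}
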