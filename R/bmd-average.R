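#' Model-averaged benchmark dose with a bootstrap 90% interval
#'
#' Full benchmark-dose workflow for a continuous, decreasing endpoint:
#' fits the requested dose-response families by maximum likelihood,
#' accepts those whose likelihood-ratio lack-of-fit p-value exceeds
#' `accept_p` (default 0.05), forms Akaike weights
#' \eqn{w_i \propto \exp(-\Delta AIC_i / 2)} over the accepted fits, and
#' reports the weight-averaged benchmark dose (averaged on the log scale).
#' The 90% confidence interval (BMDL = 5th percentile, BMDU = 95th) comes
#' from a parametric bootstrap: each replicate draws a generating model
#' with probability equal to its weight, simulates new group means (and
#' SDs) from that fit at the original design, refits every accepted
#' family, and records the replicate's weight-averaged BMD.
#'
#' @param data A [drc_data()].
#' @param families Character vector of families to fit (default all
#'   four: `"exp3"`, `"exp5"`, `"hill3"`, `"hill5"`).
#' @param bmr_sd Benchmark response in background-SD units (default 1).
#' @param background_sd Optional fixed background SD; by default each
#'   fit's residual sigma is used.
#' @param accept_p Lack-of-fit acceptance threshold (default 0.05).
#' @param n_boot Number of bootstrap replicates, >= 200 (default 1000).
#' @param seed Integer seed; required, so results are reproducible.
#' @param conf_level Confidence level of the interval (default 0.90).
#' @return An object of class `bmd_result`: list with `bmd`, `bmdl`,
#'   `bmdu`, the per-family fit table (`models`), the accepted fits with
#'   weights, the bootstrap BMD draws (`boot_bmd`), the replicate failure
#'   fraction, and the settings. `bmdl <= bmd <= bmdu` always holds.
#' @export
#' @examples
#' d <- drc_data(dose = c(0, 1, 2.5, 5, 10),
#'               mean = c(100, 95, 88, 77, 62),
#'               sd = c(5, 5, 6, 5, 6), n = rep(5, 5))
#' res <- bmd_modelaverage(d, n_boot = 200, seed = 1)
#' print(res)
bmd_modelaverage <- function(data, families = bmd_families, bmr_sd = 1,
                             background_sd = NULL, accept_p = 0.05,
                             n_boot = 1000L, seed, conf_level = 0.90) {
  if (!inherits(data, "drc_data")) stop_validation("data must be a drc_data")
  families <- match.arg(families, bmd_families, several.ok = TRUE)
  if (n_boot < 200) stop_validation("n_boot must be >= 200")
  if (missing(seed)) stop_validation("a seed is required for the bootstrap")

  fits <- lapply(families, function(fam) bmd_fit(data, fam))
  names(fits) <- families
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))

  accepted_flag <- conv & vapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(FALSE)
    !is.na(f$gof_p) && f$gof_p > accept_p
  }, logical(1))
  if (!any(accepted_flag))
    stop("no dose-response model passed the lack-of-fit acceptance (p > ",
         accept_p, ")")
  accepted <- fits[accepted_flag]

  aics <- vapply(accepted, function(f) f$aic, numeric(1))
  w <- exp(-(aics - min(aics)) / 2)
  w <- w / sum(w)

  bmds <- vapply(accepted, function(f)
    as.numeric(bmd_from_fit(f, bmr_sd, background_sd)), numeric(1))
  usable <- is.finite(bmds) & bmds > 0
  if (!any(usable))
    stop("no accepted model reaches the benchmark response")
  if (!all(usable)) {
    accepted <- accepted[usable]
    w <- w[usable] / sum(w[usable])
    bmds <- bmds[usable]
  }
  bmd_point <- exp(sum(w * log(bmds)))

  boot <- bmd_bootstrap(data, accepted, w, bmr_sd, background_sd,
                        n_boot, seed)
  fail_frac <- boot$fail_frac
  if (length(boot$bmd) == 0)
    stop("all bootstrap replicates failed")
  if (fail_frac > 0.2)
    warning(sprintf("%.0f%% of bootstrap replicates failed", 100 * fail_frac))

  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(boot$bmd, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  bmdl <- min(qs[1], bmd_point)
  bmdu <- max(qs[2], bmd_point)

  models <- data.frame(
    family = families,
    converged = conv,
    loglik = vapply(fits, function(f) if (isTRUE(f$converged)) f$loglik else NA_real_, numeric(1)),
    aic = vapply(fits, function(f) if (isTRUE(f$converged)) f$aic else NA_real_, numeric(1)),
    gof_p = vapply(fits, function(f) if (isTRUE(f$converged)) f$gof_p else NA_real_, numeric(1)),
    accepted = accepted_flag,
    row.names = NULL
  )
  models$bmd_point <- NA_real_
  models$weight <- 0
  idx <- match(names(accepted), models$family)
  models$bmd_point[idx] <- bmds
  models$weight[idx] <- w

  structure(
    list(bmd = bmd_point, bmdl = bmdl, bmdu = bmdu,
         models = models, fits = fits, accepted = accepted, weights = w,
         boot_bmd = boot$bmd, boot_fail_frac = fail_frac,
         settings = list(bmr_sd = bmr_sd, background_sd = background_sd,
                         accept_p = accept_p, n_boot = as.integer(n_boot),
                         seed = as.integer(seed), conf_level = conf_level),
         data = data),
    class = "bmd_result"
  )
}

# parametric bootstrap of the model-averaged BMD; restores the caller's
# RNG state on exit
bmd_bootstrap <- function(data, accepted, w, bmr_sd, background_sd,
                          n_boot, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n_grp <- nrow(data)
  out <- numeric(0)
  fails <- 0L
  for (r in seq_len(n_boot)) {
    j <- sample.int(length(accepted), 1L, prob = w)
    gen <- accepted[[j]]
    mu <- gen$fitted
    m_star <- stats::rnorm(n_grp, mu, gen$sigma / sqrt(data$n))
    s_star <- gen$sigma * sqrt(stats::rchisq(n_grp, data$n - 1) / (data$n - 1))
    s_star <- pmax(s_star, 1e-8 * max(gen$sigma, 1e-12))
    d_star <- data
    d_star$mean <- m_star
    d_star$sd <- s_star

    rep_bmds <- rep(NA_real_, length(accepted))
    rep_aic <- rep(NA_real_, length(accepted))
    for (k in seq_along(accepted)) {
      fk <- tryCatch(
        bmd_fit(d_star, accepted[[k]]$family, start = accepted[[k]]$par,
                n_starts = 0L),
        error = function(e) NULL)
      if (is.null(fk) || !isTRUE(fk$converged)) next
      bk <- as.numeric(bmd_from_fit(fk, bmr_sd, background_sd))
      if (is.finite(bk) && bk > 0) {
        rep_bmds[k] <- bk
        rep_aic[k] <- fk$aic
      }
    }
    ok <- is.finite(rep_bmds)
    if (!any(ok)) { fails <- fails + 1L; next }
    wk <- exp(-(rep_aic[ok] - min(rep_aic[ok])) / 2)
    wk <- wk / sum(wk)
    out <- c(out, exp(sum(wk * log(rep_bmds[ok]))))
  }
  list(bmd = out, fail_frac = fails / n_boot)
}

#' @export
print.bmd_result <- function(x, ...) {
  cat("Model-averaged benchmark dose\n")
  cat(sprintf("  BMD  = %.4g\n  BMDL = %.4g  (%.0f%% interval)\n  BMDU = %.4g\n",
              x$bmd, x$bmdl, 100 * x$settings$conf_level, x$bmdu))
  cat(sprintf("  BMR: %.2g SD of background; %d/%d models accepted; %d bootstrap draws\n",
              x$settings$bmr_sd, sum(x$models$accepted), nrow(x$models),
              length(x$boot_bmd)))
  invisible(x)
}

#' @export
summary.bmd_result <- function(object, ...) {
  cat("Model-averaged benchmark dose analysis\n\n")
  print(object$models, digits = 4)
  cat(sprintf("\nBMD %.4g [BMDL %.4g, BMDU %.4g] at BMR = %.2g SD\n",
              object$bmd, object$bmdl, object$bmdu, object$settings$bmr_sd))
  if (object$boot_fail_frac > 0)
    cat(sprintf("bootstrap replicate failures: %.1f%%\n",
                100 * object$boot_fail_frac))
  invisible(object)
}

#' @export
coef.bmd_result <- function(object, ...) {
  c(bmd = object$bmd, bmdl = object$bmdl, bmdu = object$bmdu)
}

#' @export
predict.bmd_result <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose
       else if (is.data.frame(newdata)) newdata$dose else newdata
  preds <- vapply(object$accepted, function(f) predict(f, x), numeric(length(x)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = length(x))
  as.vector(preds %*% object$weights)
}

#' @export
plot.bmd_result <- function(x, ...) {
  d <- x$data
  xs <- seq(0, max(d$dose), length.out = 200)
  ys <- predict(x, xs)
  graphics::plot(d$dose, d$mean, pch = 16,
                 ylim = range(c(d$mean - d$sd, d$mean + d$sd, ys)),
                 xlab = "dose", ylab = "response", ...)
  graphics::arrows(d$dose, d$mean - d$sd, d$dose, d$mean + d$sd,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(xs, ys, col = "steelblue", lwd = 2)
  graphics::abline(v = c(x$bmdl, x$bmd, x$bmdu),
                   lty = c(3, 2, 3), col = "firebrick")
  invisible(x)
}
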