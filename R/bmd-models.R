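# Continuous dose-response families for decreasing endpoints.
#
# All families share f(0) = a (background response) and are parameterized
# so that b controls potency, d the shape (steepness), and c (where
# present) the asymptotic fraction of background remaining at high dose:
#
#   exp3 : f(x) = a * exp(-b * x^d)
#   exp5 : f(x) = a * (c + (1 - c) * exp(-b * x^d))
#   hill3: f(x) = a * (1 - x^d / (b^d + x^d))
#   hill5: f(x) = a * (1 - (1 - c) * x^d / (b^d + x^d))
#
# These are the exponential and Hill families routinely used for
# continuous endpoints in benchmark-dose work; the 3-parameter members
# decay to zero, the 5-parameter members level off at a * c.

bmd_families <- c("exp3", "exp5", "hill3", "hill5")

family_has_c <- function(family) family %in% c("exp5", "hill5")

family_npar <- function(family) if (family_has_c(family)) 4L else 3L

# f(x; par) with par a named list/vector on the natural scale
drc_curve <- function(family, par) {
  a <- par[["a"]]; b <- par[["b"]]; d <- par[["d"]]
  cc <- if (family_has_c(family)) par[["c"]] else 0
  switch(family,
    exp3 = function(x) a * exp(-b * x^d),
    exp5 = function(x) a * (cc + (1 - cc) * exp(-b * x^d)),
    hill3 = function(x) a * (1 - x^d / (b^d + x^d)),
    hill5 = function(x) a * (1 - (1 - cc) * x^d / (b^d + x^d)),
    stop_validation("unknown family: ", family)
  )
}

# normalized curve g(x) with g(0) = 1, so that f(x) = a * g(x): the
# background a enters the likelihood linearly through a * g and is
# profiled out analytically during fitting
drc_g <- function(family, bpar) {
  b <- bpar[["b"]]; d <- bpar[["d"]]
  cc <- if (family_has_c(family)) bpar[["c"]] else 0
  switch(family,
    exp3 = function(x) exp(-b * x^d),
    exp5 = function(x) cc + (1 - cc) * exp(-b * x^d),
    hill3 = function(x) 1 - x^d / (b^d + x^d),
    hill5 = function(x) 1 - (1 - cc) * x^d / (b^d + x^d),
    stop_validation("unknown family: ", family)
  )
}

# transform between the optimizer scale (box-bounded logs / logit) and
# the natural scale of the shape parameters (b, d[, c])
theta_to_bpar <- function(family, theta) {
  bpar <- list(b = exp(theta[1L]), d = exp(theta[2L]))
  if (family_has_c(family)) bpar$c <- stats::plogis(theta[3L])
  bpar
}

bpar_to_theta <- function(family, bpar) {
  theta <- c(log(bpar[["b"]]), log(bpar[["d"]]))
  if (family_has_c(family)) theta <- c(theta, stats::qlogis(bpar[["c"]]))
  theta
}

theta_bounds <- function(family) {
  lower <- c(log(1e-10), log(0.25))
  upper <- c(log(1e10), log(15))
  if (family_has_c(family)) {
    lower <- c(lower, -12)
    upper <- c(upper, 12)
  }
  list(lower = lower, upper = upper)
}

# deterministic multi-start lattice on the optimizer scale: potency
# guesses span decay fractions at the top dose, shapes span shallow to
# steep, plateau starts near the observed floor
start_lattice <- function(family, xmax, floor_frac) {
  gs <- c(0.3, 1, 3)        # assumed b * xmax^d at the top dose (exp)
  ds <- c(1, 2)
  c0 <- min(max(floor_frac, 0.05), 0.95)
  starts <- list()
  for (g in gs) for (d in ds) {
    par <- list(d = d)
    if (startsWith(family, "exp")) par$b <- g / xmax^d
    else par$b <- xmax * (1 / g)    # hill half-max dose guess
    if (family_has_c(family)) par$c <- c0
    starts[[length(starts) + 1L]] <- par
  }
  extra <- list(
    list(b = if (startsWith(family, "exp")) 0.5 / xmax^4 else 2 * xmax, d = 4),
    list(b = if (startsWith(family, "exp")) 2 / sqrt(xmax) else xmax / 4, d = 0.5),
    list(b = if (startsWith(family, "exp")) 1 / xmax else xmax, d = 1),
    list(b = if (startsWith(family, "exp")) 1 / xmax^1.5 else xmax / 2, d = 1.5)
  )
  for (e in extra) {
    if (family_has_c(family)) e$c <- c0
    starts[[length(starts) + 1L]] <- e
  }
  lapply(starts, function(p) bpar_to_theta(family, p))
}
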