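test_that("drc_data validates structure", {
  expect_error(drc_data(c(1, 2, 3), c(9, 8, 7), c(1, 1, 1), c(5, 5, 5)),
               "control")
  expect_error(drc_data(c(0, 1), c(10, 9), c(1, 0), c(5, 5)), "SD")
  expect_error(drc_data(c(0, 1), c(10, 9), c(1, 1), c(5, 1)), "sizes")
  d <- drc_data(c(4, 0, 1), c(7, 10, 9), c(1, 1, 1), c(5, 5, 5))
  expect_equal(d$dose, c(0, 1, 4))  # sorted
})

test_that("parameters of an exponential curve are recovered from exact data", {
  truth <- list(a = 100, b = 0.1, d = 1.2)
  doses <- c(0, 1, 2, 4, 8, 16)
  mu <- truth$a * exp(-truth$b * doses^truth$d)
  d <- drc_data(doses, mu, rep(1e-4, 6), rep(5, 6))
  fit <- bmd_fit(d, "exp3")
  expect_true(fit$converged)
  expect_equal(fit$par$a, truth$a, tolerance = 0.01)
  expect_equal(fit$par$b, truth$b, tolerance = 0.01)
  expect_equal(fit$par$d, truth$d, tolerance = 0.01)
  expect_equal(predict(fit), mu, tolerance = 1e-4)
  expect_lt(max(abs(residuals(fit))), 1e-3)
  # near-interpolating fit: lack-of-fit p close to 1
  expect_gt(fit$gof_p, 0.99)
})

test_that("flat data give a null potency and no benchmark crossing", {
  d <- drc_data(c(0, 1, 4, 8), rep(100, 4), rep(2, 4), rep(5, 4))
  fit <- bmd_fit(d, "exp3")
  expect_true(fit$converged)
  expect_lt(fit$par$b * max(d$dose)^fit$par$d, 1e-6)
  bmd <- bmd_from_fit(fit)
  expect_true(is.na(bmd))
  expect_equal(attr(bmd, "reason"), "bmr_not_reached")
})

test_that("fitted curves honor the decreasing direction of the data", {
  d <- drc_data(c(0, 1, 2, 4, 8), c(100, 90, 80, 65, 45),
                c(3, 3, 3, 3, 3), rep(5, 5))
  for (fam in c("exp3", "exp5", "hill3", "hill5")) {
    fit <- bmd_fit(d, fam)
    expect_true(fit$converged)
    xs <- seq(0, 8, length.out = 50)
    expect_true(all(diff(predict(fit, xs)) <= 1e-9))
  }
})

test_that("benchmark dose solver matches closed forms", {
  # linear curve f = a - b x with background SD s: BMD = s / b
  f_lin <- function(x) 100 - 2 * x
  expect_equal(revdosim:::bmd_solve(f_lin, drop = 4, xmax = 20), 2,
               tolerance = 1e-7)
  # bmr -> 0 pushes the BMD to 0
  expect_lt(revdosim:::bmd_solve(f_lin, drop = 1e-9, xmax = 20), 1e-8)

  # exponential-5 closed form
  par <- list(a = 100, b = 0.05, d = 1.3, c = 0.4)
  f <- revdosim:::drc_curve("exp5", par)
  drop <- 5
  x_closed <- ((-log(1 - drop / (par$a * (1 - par$c)))) / par$b)^(1 / par$d)
  expect_equal(revdosim:::bmd_solve(f, drop, xmax = 10), x_closed,
               tolerance = 1e-6)
  # out-of-reach benchmark is signalled, not extrapolated
  nr <- revdosim:::bmd_solve(f, drop = 70, xmax = 10)
  expect_true(is.na(nr))
})

test_that("lack-of-fit test rejects structure the families cannot express", {
  # U-shaped response: monotone families must fail the P > 0.05 gate
  d <- drc_data(c(0, 1, 2, 4, 8), c(100, 70, 55, 70, 100),
                c(2, 2, 2, 2, 2), rep(8, 5))
  for (fam in c("exp3", "hill3")) {
    fit <- bmd_fit(d, fam)
    expect_true(fit$converged)
    expect_lt(fit$gof_p, 0.05)
    expect_gte(fit$gof_p, 0)
    expect_lte(fit$gof_p, 1)
  }
})

test_that("adding a group on the fitted curve does not materially change fit quality", {
  d <- generate_chat_response(c(0, 0.5, 1, 2, 4, 8), recovery_truth(),
                              seed = 21)
  fit <- bmd_fit(d, "exp5")
  new_dose <- 3
  d2 <- drc_data(c(d$dose, new_dose), c(d$mean, predict(fit, new_dose)),
                 c(d$sd, fit$sigma), c(d$n, 5L))
  fit2 <- bmd_fit(d2, "exp5")
  expect_gt(fit2$gof_p, fit$gof_p - 0.2)
})

test_that("the whole analysis is equivariant under rescaling of the dose axis", {
  d <- generate_chat_response(c(0, 0.5, 1, 2, 4, 8), recovery_truth(),
                              seed = 31)
  k <- 7.3
  d_scaled <- drc_data(d$dose * k, d$mean, d$sd, d$n)
  for (fam in c("exp3", "exp5")) {
    b1 <- bmd_from_fit(bmd_fit(d, fam))
    b2 <- bmd_from_fit(bmd_fit(d_scaled, fam))
    expect_equal(b2 / b1, k, tolerance = 1e-6)
  }
  r1 <- bmd_modelaverage(d, families = c("exp3", "exp5"), n_boot = 200,
                         seed = 4)
  r2 <- bmd_modelaverage(d_scaled, families = c("exp3", "exp5"),
                         n_boot = 200, seed = 4)
  expect_equal(coef(r2) / coef(r1), c(bmd = k, bmdl = k, bmdu = k),
               tolerance = 1e-6)
})

test_that("near-noiseless data give a degenerate (tight) bootstrap interval", {
  truth <- recovery_truth(sd = 0)
  doses <- c(0, 0.5, 1, 2, 4, 8)
  mu <- truth$curve(doses)
  d <- drc_data(doses, mu, rep(1e-3, 6), rep(5, 6))
  res <- bmd_modelaverage(d, families = "exp5", background_sd = 5,
                          n_boot = 500, seed = 7)
  expect_lt(res$bmdu / res$bmdl - 1, 0.02)
  expect_equal(res$bmd, chat_truth_bmd(recovery_truth(sd = 5), 8),
               tolerance = 0.01)
})

test_that("averaging two identical fits equals the single-model answer", {
  d <- generate_chat_response(c(0, 0.5, 1, 2, 4, 8), recovery_truth(),
                              seed = 41)
  one <- bmd_modelaverage(d, families = "exp5", n_boot = 200, seed = 6)
  two <- bmd_modelaverage(d, families = c("exp5", "exp5"), n_boot = 200,
                          seed = 6)
  expect_equal(two$weights, c(exp5 = 0.5, exp5 = 0.5))
  expect_equal(two$bmd, one$bmd, tolerance = 1e-9)
  expect_true(two$bmdl <= two$bmd && two$bmd <= two$bmdu)
})

test_that("model averaging weights accepted fits by AIC and orders the interval", {
  d <- generate_chat_response(c(0, 0.5, 1, 2, 4, 8), recovery_truth(),
                              seed = 51)
  res <- bmd_modelaverage(d, n_boot = 200, seed = 8)
  expect_true(res$bmdl <= res$bmd && res$bmd <= res$bmdu)
  w <- res$models$weight[res$models$accepted]
  expect_equal(sum(w), 1, tolerance = 1e-12)
  aic <- res$models$aic[res$models$accepted]
  expect_equal(order(w), order(-aic))  # lower AIC, higher weight
  # reproducibility under the same seed
  res2 <- bmd_modelaverage(d, n_boot = 200, seed = 8)
  expect_identical(coef(res), coef(res2))
})
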