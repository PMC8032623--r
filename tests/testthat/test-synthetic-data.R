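test_that("with no exchange the dose stays in the medium", {
  p <- invitro_system_params(k_medium_cells = 0, k_cells_medium = 0,
                             k_medium_plastic = 0, k_plastic_medium = 0,
                             k_metabolism = 0, cv = 0, level_uM = 1.25)
  ds <- generate_biokinetics(p, seed = 1)
  d <- ds$data
  dose_conc <- micromolar_to_ugml(1.25, 645.31) / 1  # µg/mL in medium
  med <- d[d$compartment == "medium", ]
  expect_equal(med$conc_ug_ml, rep(dose_conc, nrow(med)), tolerance = 1e-8)
  other <- d[d$compartment %in% c("cells", "plastic"), ]
  expect_true(all(other$value == 0))
})

test_that("the noise-free system conserves mass across the full schedule", {
  p <- invitro_system_params(cv = 0, level_uM = 2.5)
  sol <- attr(generate_biokinetics(p, seed = 1), "truth")
  traj <- sol$trajectory
  # within the first dosing interval (before the renewal at 48 h)
  # nothing has been removed yet
  first <- traj[traj[, "time"] < 48, , drop = FALSE]
  tot <- rowSums(first[, c("medium", "cells", "plastic", "metabolite")])
  expect_equal(tot, rep(sol$dose_amount, length(tot)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # across renewals: present + removed = administered
  end <- traj[nrow(traj), ]
  administered <- sol$dose_amount * length(sol$dose_times)
  present <- sum(end[c("medium", "cells", "plastic", "metabolite")])
  expect_equal(present + sol$removed, administered, tolerance = 1e-6)
})

test_that("symmetric medium-cell exchange reaches detailed balance", {
  p <- invitro_system_params(k_medium_cells = 0.2, k_cells_medium = 0.2,
                             k_medium_plastic = 0, k_plastic_medium = 0,
                             k_metabolism = 0, cv = 0, n_days = 2L)
  sol <- attr(generate_biokinetics(p, seed = 1), "truth")
  traj <- sol$trajectory
  end <- traj[nrow(traj), ]
  expect_equal(end[["cells"]] / end[["medium"]], 1, tolerance = 1e-3)
})

test_that("repeated dosing accumulates: final-day cell AUC exceeds day 0", {
  for (lev in c(1.25, 2.5)) {
    ds <- generate_biokinetics(invitro_system_params(level_uM = lev, cv = 0),
                               seed = 1)
    auc14 <- invitro_metric(ds, lev, 14, "cells", "AUC")$value
    auc0 <- invitro_metric(ds, lev, 0, "cells", "AUC")$value
    expect_gt(auc14, auc0)
    # defaults are calibrated into the 1-2 µg·h/mL window at 1.25-2.5 µM
    expect_gt(auc14, 0.5 * lev / 1.25)
    expect_lt(auc14, 2 * lev / 1.25)
  }
})

test_that("biokinetic generation is seed-deterministic", {
  p <- invitro_system_params(cv = 0.2)
  a <- generate_biokinetics(p, seed = 7)
  b <- generate_biokinetics(p, seed = 7)
  c <- generate_biokinetics(p, seed = 8)
  expect_identical(a$data$value, b$data$value)
  expect_false(all(a$data$value == c$data$value))
})

test_that("ChAT generator hits the truth curve exactly at zero noise", {
  truth0 <- chat_truth_params(sd = 0)
  doses <- c(0, 1, 2, 4)
  out <- generate_chat_response(doses, truth0, seed = 1)
  expect_equal(out$mean, truth0$curve(doses))
  expect_error(generate_chat_response(c(1, 2, 4), truth0, seed = 1),
               "control")

  truth <- chat_truth_params(sd = 5)
  a <- generate_chat_response(doses, truth, seed = 3)
  b <- generate_chat_response(doses, truth, seed = 3)
  c <- generate_chat_response(doses, truth, seed = 4)
  expect_identical(a$mean, b$mean)
  expect_false(all(a$mean == c$mean))
})

test_that("a zero-noise response analysed end to end recovers the truth BMD", {
  truth <- recovery_truth(sd = 0)
  doses <- recovery_doses
  mu <- truth$curve(doses)
  d <- drc_data(doses, mu, rep(1e-3, length(doses)), rep(5, length(doses)))
  res <- bmd_modelaverage(d, families = "exp5", background_sd = 5,
                          n_boot = 200, seed = 11)
  bmd_true <- chat_truth_bmd(recovery_truth(sd = 5), max(doses))
  expect_equal(res$bmd, bmd_true, tolerance = 0.02)
})
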