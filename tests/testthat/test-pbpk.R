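test_that("parameter validation rejects inconsistent physiology", {
  expect_error(compound_properties(fu_plasma = 0), "fu_plasma")
  expect_error(compound_properties(molecular_weight = -1), "molecular_weight")
  p <- toy_params()
  bad <- p$tissues
  bad$blood_flow[1] <- bad$blood_flow[1] * 2
  expect_error(
    pbpk_params(73, 100, p$blood_volumes, p$lung, bad, 5, p$compound),
    "cardiac_output")
  bad2 <- p$tissues
  bad2$PS[1] <- -1
  expect_error(
    pbpk_params(73, 100, p$blood_volumes, p$lung, bad2, 5, p$compound),
    "PS")
  bad3 <- p$tissues
  bad3$name[2] <- "hepar"
  expect_error(
    pbpk_params(73, 100, p$blood_volumes, p$lung, bad3, 5, p$compound),
    "liver")
})

test_that("packaged fixtures load, validate, and reject unknown keys", {
  for (sp in c("human", "rat")) {
    p <- pbpk_fixture(sp)
    expect_s3_class(p, "pbpk_params")
    expect_equal(sum(p$tissues$blood_flow), p$cardiac_output,
                 tolerance = 1e-9)
    expect_equal(nrow(p$tissues), 10L)
  }
  tmp <- tempfile(fileext = ".yaml")
  y <- yaml::read_yaml(system.file("extdata", "pbpk_human.yaml",
                                   package = "revdosim"))
  y$typo_key <- 1
  yaml::write_yaml(y, tmp)
  expect_error(read_pbpk_params(tmp), "unknown keys")
})

test_that("zero dose yields identically zero profiles", {
  sim <- pbpk_simulate(toy_params(), dosing_regimen(0), duration = 12,
                       grid_step = 0.5)
  expect_true(all(sim$conc == 0))
  expect_identical(mass_balance_error(sim), 0)
})

test_that("mass is conserved for bolus, multiple-dose and infusion input", {
  p <- toy_params()
  regs <- list(
    dosing_regimen(100),
    dosing_regimen(50, n_doses = 3, interval = 24),
    dosing_regimen(50, n_doses = 2, interval = 24, infusion_duration = 2)
  )
  for (reg in regs) {
    sim <- pbpk_simulate(p, reg, duration = 72, grid_step = 0.1)
    expect_lt(mass_balance_error(sim), 1e-3)
  }
})

test_that("mass-balance audit detects an artificially perturbed state", {
  sim <- pbpk_simulate(toy_params(), dosing_regimen(100), duration = 24,
                       grid_step = 0.5)
  sim$amounts[, "brain_tissue"] <- sim$amounts[, "brain_tissue"] * 2 + 1
  expect_gt(mass_balance_error(sim), 0)
})

test_that("degenerate single-pool limit matches the one-compartment closed form", {
  p <- onecomp_params(V = 5, CL = 0.5)
  D <- 100
  sim <- pbpk_simulate(p, dosing_regimen(D), duration = 24, grid_step = 0.1)
  V <- onecomp_volume(p)
  kel <- 0.5 / V
  tt <- seq(2, 20, by = 2)   # 10 points past the mixing transient
  idx <- match(tt, sim$time)
  expect_equal(sim$conc[idx, "venous_blood"], D / V * exp(-kel * tt),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("profiles are linear in dose and obey superposition", {
  p <- toy_params()
  s1 <- pbpk_simulate(p, dosing_regimen(50), duration = 48, grid_step = 0.2)
  s2 <- pbpk_simulate(p, dosing_regimen(100), duration = 48, grid_step = 0.2)
  pos <- s2$conc > 1e-12
  expect_lt(max(abs(s1$conc[pos] * 2 / s2$conc[pos] - 1)), 0.005)

  # two doses 24 h apart = sum of two shifted single-dose responses
  sd2 <- pbpk_simulate(p, dosing_regimen(50, n_doses = 2, interval = 24),
                       duration = 48, grid_step = 0.2)
  single <- pbpk_simulate(p, dosing_regimen(50), duration = 48,
                          grid_step = 0.2)
  shift <- function(m, k) rbind(matrix(0, k, ncol(m)),
                                m[seq_len(nrow(m) - k), , drop = FALSE])
  k <- sum(single$time < 24)
  recon <- single$conc + shift(single$conc, k)
  pos <- sd2$conc > 1e-9 * max(sd2$conc)
  expect_lt(max(abs(recon[pos] / sd2$conc[pos] - 1)), 0.005)
})

test_that("brain AUC rises monotonically with PS and plateaus (perfusion limit)", {
  ps_ladder <- 10^seq(-3, 3, by = 1)
  aucs <- vapply(ps_ladder, function(ps) {
    sim <- pbpk_simulate(toy_params(ps_brain = ps), dosing_regimen(100),
                         duration = 24, grid_step = 0.2)
    tissue_metric(sim, "brain_tissue", "AUC", c(0, 24))$value
  }, numeric(1))
  expect_true(all(diff(aucs) > -1e-9 * max(aucs)))
  # plateau: last doubling of PS changes AUC by far less than the first
  rel_gain_first <- aucs[2] / aucs[1] - 1
  rel_gain_last <- aucs[length(aucs)] / aucs[length(aucs) - 1] - 1
  expect_lt(rel_gain_last, 0.01)
  expect_gt(rel_gain_first, 1)
})

test_that("tissue metrics double with dose and reject bad windows", {
  p <- toy_params()
  s1 <- pbpk_simulate(p, dosing_regimen(50), duration = 24, grid_step = 0.2)
  s2 <- pbpk_simulate(p, dosing_regimen(100), duration = 24, grid_step = 0.2)
  for (metric in c("AUC", "Cmax")) {
    m1 <- tissue_metric(s1, "brain_tissue", metric, c(0, 24))$value
    m2 <- tissue_metric(s2, "brain_tissue", metric, c(0, 24))$value
    expect_equal(m2 / m1, 2, tolerance = 0.005)
  }
  expect_error(tissue_metric(s1, "brain_tissue", "AUC", c(0, 48)),
               "window")
  expect_error(tissue_metric(s1, "no_such_organ", "AUC", c(0, 24)),
               "compartment")
})

test_that("simulation export writes tidy CSV plus JSON metadata", {
  sim <- pbpk_simulate(toy_params(), dosing_regimen(10), duration = 6,
                       grid_step = 0.5)
  csv <- tempfile(fileext = ".csv")
  paths <- write_simulation(sim, csv)
  out <- read.csv(csv)
  expect_named(out, c("time_h", "compartment", "concentration_ug_per_ml"))
  expect_setequal(unique(out$compartment), sim$compartments)
  meta <- jsonlite::read_json(paths[["json"]])
  expect_equal(meta$regimen$dose, 10)
  expect_equal(meta$solver$rtol, 1e-8)
})
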