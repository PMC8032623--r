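# All searches here use a single-bolus 24-h template on the toy
# physiology so each candidate simulation is cheap; the contract under
# test (grid restriction, smallest difference, tie to smaller dose) is
# regimen-independent.

test_that("a simulated metric is recovered as a fixed point of the search", {
  p <- toy_params()
  cfg <- fast_cfg("AUC")
  D <- 25
  target <- revdosim:::revdose_metric_at(p, cfg, D)
  est <- find_dose(p, target, cfg)
  expect_equal(est$dose_mg, D)
  expect_lt(est$residual / target, 1e-9)
  # consistency: achieved metric equals re-simulation at returned dose
  expect_equal(est$achieved$value,
               revdosim:::revdose_metric_at(p, cfg, est$dose_mg),
               tolerance = 1e-6)
})

test_that("doubling the target doubles the dose to within one grid step", {
  p <- toy_params()
  cfg <- fast_cfg("AUC")
  a_ref <- revdosim:::revdose_metric_at(p, cfg, 20)
  e1 <- find_dose(p, a_ref, cfg)
  e2 <- find_dose(p, 2 * a_ref, cfg)
  expect_lte(abs(e2$dose_mg - 2 * e1$dose_mg), cfg$dose_step + 1e-9)
  expect_gte(e2$dose_mg, e1$dose_mg)  # monotonicity
})

test_that("pure scan and linearity shortcut select the same grid dose", {
  p <- toy_params()
  base_cfg <- fast_cfg("AUC")
  m1 <- revdosim:::revdose_metric_at(p, base_cfg, 1)
  for (mult in c(0.8, 1.0, 1.25)) {
    pp <- toy_params(ps_brain = 0.5 * mult, cl = 5 / mult)
    m1p <- revdosim:::revdose_metric_at(pp, base_cfg, 1)
    for (target in m1p * c(9.6, 20.1, 30.7)) {
      lin <- find_dose(pp, target, base_cfg, method = "linear")
      # narrow scan window bracketing the shortcut answer keeps the
      # exhaustive reference affordable
      scan_cfg <- fast_cfg("AUC",
                           dose_min = max(0.01, lin$dose_mg - 0.05),
                           dose_max = lin$dose_mg + 0.05)
      sc <- find_dose(pp, target, scan_cfg, method = "scan")
      expect_lte(abs(sc$dose_mg - lin$dose_mg), 0.01 + 1e-9)
    }
  }
})

test_that("step resolution: returned dose is within one step of analytic scaling", {
  p <- toy_params()
  cfg <- fast_cfg("AUC")
  m1 <- revdosim:::revdose_metric_at(p, cfg, 1)
  for (target in c(0.37, 1.9, 12.3) * m1) {
    est <- find_dose(p, target, cfg)
    expect_lte(abs(est$dose_mg - target / m1), cfg$dose_step + 1e-9)
  }
})

test_that("invalid targets and scan boundaries are signalled", {
  p <- toy_params()
  cfg <- fast_cfg("AUC", dose_max = 1)
  expect_error(find_dose(p, -1, cfg), "target")
  expect_error(find_dose(p, 0, cfg), "target")
  m1 <- revdosim:::revdose_metric_at(p, cfg, 1)
  expect_warning(find_dose(p, 100 * m1, cfg), "boundary")
})

test_that("translate_levels preserves order, duplicates, and linear ratios", {
  p <- toy_params()
  cfg <- fast_cfg("AUC")
  m1 <- revdosim:::revdose_metric_at(p, cfg, 1)
  expect_error(translate_levels(numeric(0), list(), p, cfg), "one level")
  res <- translate_levels(c(1.25, 2.5, 1.25), c(10 * m1, 20 * m1, 10 * m1),
                          p, cfg)
  expect_equal(res$level_uM, c(1.25, 2.5, 1.25))
  expect_equal(res$dose_mg[1], res$dose_mg[3])  # determinism
  expect_lte(abs(res$dose_mg[2] - 2 * res$dose_mg[1]), cfg$dose_step + 1e-9)
  expect_equal(res$dose_mg_per_kg, res$dose_mg / p$body_weight)
})
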