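test_that("per-flask and molar unit conversions are exact and invert", {
  expect_equal(per_flask_to_concentration(0, 3.5), 0)
  expect_equal(per_flask_to_concentration(1.0, 2.0), 0.5)
  expect_error(per_flask_to_concentration(1, 0), "volume")

  # amiodarone exposure levels in mass units
  expect_equal(micromolar_to_ugml(1.25, 645.31), 0.8066, tolerance = 1e-4)
  expect_equal(micromolar_to_ugml(2.5, 645.31), 1.6133, tolerance = 1e-4)
  expect_equal(micromolar_to_ugml(0, 645.31), 0)

  x <- c(0.01, 0.37, 12.5)
  expect_equal(ugml_to_micromolar(micromolar_to_ugml(x, 645.31), 645.31),
               x, tolerance = 1e-12)
  expect_equal(
    per_flask_to_concentration(concentration_to_per_flask(x, 1.7), 1.7),
    x, tolerance = 1e-12)
})

test_that("trapezoid AUC handles constants, triangles and window interpolation", {
  tt <- c(0, 6, 12, 18, 24)
  expect_equal(auc_trapezoid(tt, rep(0.05, 5), 0, 24), 1.2)
  expect_equal(auc_trapezoid(c(0, 12, 24), c(0, 0.1, 0), 0, 24), 1.2)
  # linear ramp 0 -> c over 24 h has AUC 12 c
  expect_equal(auc_trapezoid(c(0, 24), c(0, 0.3), 0, 24), 12 * 0.3)
  # endpoints interpolated from bracketing points
  expect_equal(auc_trapezoid(c(0, 24), c(0, 0.3), 6, 18),
               12 * (0.075 + 0.225) / 2)
  expect_error(auc_trapezoid(c(0), c(1), 0, 24), "two points")
  expect_error(auc_trapezoid(c(0, 12), c(1, 1), 0, 24), "not covered")
})

test_that("AUC is additive over adjacent windows and monotone in concentration", {
  set.seed(11)
  for (i in 1:20) {
    tt <- sort(runif(7, 0, 24))
    tt <- c(0, tt, 24)
    cc <- runif(9, 0, 2)
    expect_equal(auc_trapezoid(tt, cc, 0, 12) + auc_trapezoid(tt, cc, 12, 24),
                 auc_trapezoid(tt, cc, 0, 24), tolerance = 1e-12)
    cc2 <- cc + runif(9, 0, 1)
    expect_gte(auc_trapezoid(tt, cc2, 0, 24), auc_trapezoid(tt, cc, 0, 24))
  }
})

test_that("observed Cmax picks the sampled maximum", {
  expect_equal(observed_cmax(c(0, 12, 24), rep(0.7, 3)), 0.7)
  expect_equal(observed_cmax(c(0, 2, 24), c(0.01, 0.042, 0.03)), 0.042)
  expect_equal(observed_cmax(c(0, 2, 24), c(0, 0, 0)), 0)
  expect_error(observed_cmax(numeric(0), numeric(0)), "empty")
})

test_that("dataset reader round-trips the generator output and checks units", {
  p <- invitro_system_params(level_uM = 1.25, cv = 0.1)
  ds <- generate_biokinetics(p, seed = 5)
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  write_invitro_dataset(ds, csv, yml)
  back <- read_invitro_dataset(csv, yml)
  expect_s3_class(back, "invitro_dataset")
  expect_equal(sort(back$data$conc_ug_ml), sort(ds$data$conc_ug_ml),
               tolerance = 1e-9)

  bad <- ds$data
  bad$unit[1] <- "mg"
  write.csv(bad, csv, row.names = FALSE)
  expect_error(read_invitro_dataset(csv, yml), "unit")
})

test_that("in vitro metric averages replicates before integrating", {
  dat <- data.frame(
    level_uM = 1.25, day = 14L,
    compartment = "cells",
    time_h = rep(c(0, 12, 24), each = 2),
    value = c(0.1, 0.3, 0.5, 0.7, 0.2, 0.4),
    value_kind = "concentration", unit = "ug_per_ml",
    conc_ug_ml = c(0.1, 0.3, 0.5, 0.7, 0.2, 0.4)
  )
  ds <- revdosim:::invitro_dataset(dat, list(medium_volume_ml = 2,
                                             lysate_volume_ml = 0.1))
  # mean profile is (0.2, 0.6, 0.3)
  expect_equal(invitro_metric(ds, 1.25, 14, "cells", "AUC")$value,
               12 * (0.2 + 0.6) / 2 + 12 * (0.6 + 0.3) / 2)
  expect_equal(invitro_metric(ds, 1.25, 14, "cells", "Cmax")$value, 0.6)
  expect_error(invitro_metric(ds, 2.5, 14, "cells"), "no data")
})
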