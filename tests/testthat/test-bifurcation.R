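# Dose scans and the analyses on top of them, checked against
# constructions and composition identities.

test_that("a one-dose scan equals a direct integration", {
  ctl <- integration_control(dt_s = 2, sample_every_h = 0.05)
  scan <- run_dose_scan(2, horizon_h = 5, control = ctl,
                        keep_species = "p53")
  direct <- integrate_model(default_parameters(),
                            make_initial_state(2, control = ctl),
                            t_end_h = 5, control = ctl)
  expect_identical(scan$runs[[1]]$series$p53,
                   species_series(direct, "p53")$value)
})

test_that("the scan is invariant to the ordering of the dose grid", {
  ctl <- integration_control(sample_every_h = 0.1)
  a <- run_dose_scan(c(0, 2, 5), horizon_h = 2, control = ctl,
                     keep_species = "p53")
  b <- run_dose_scan(c(5, 0, 2), horizon_h = 2, control = ctl,
                     keep_species = "p53")
  expect_identical(a$doses, b$doses)
  expect_identical(a$runs, b$runs)
})

test_that("phase boundary is recovered on a constructed scan", {
  # oscillation death below 2 Gy by construction, oscillation above
  mk <- function(d) {
    if (d < 2) synth_signal("sustained", period_h = 2, amplitude = 1e-4,
                            horizon_h = 130)
    else synth_signal("sustained", period_h = 2, amplitude = 1,
                      horizon_h = 130)
  }
  sc <- synthetic_scan(seq(0, 4, by = 0.25), mk)
  ph <- phase_boundary(sc, window = c(70, 120), refine = FALSE)
  expect_equal(ph$boundary_gy, 2, tolerance = 0.25 / 2)
  expect_identical(
    unique(ph$table$phase[ph$table$dose_gy < 1.9]), "oscillation_death")
  # single-phase scan: boundary is "none", not an error
  all_osc <- synthetic_scan(seq(0, 4, 1), function(d)
    synth_signal("sustained", period_h = 2, horizon_h = 130))
  expect_true(is.na(phase_boundary(all_osc, window = c(70, 120),
                                   refine = FALSE)$boundary_gy))
})

test_that("collapse durations with a constructed slope are recovered", {
  mk <- function(d) synth_signal("collapse", period_h = 2,
                                 horizon_h = 150, collapse_start_h = 30,
                                 collapse_len_h = 2 * d)
  sc <- synthetic_scan(c(5, 10, 15, 20, 25), mk)
  cc <- collapse_curve(sc, statistic = "duration")
  expect_equal(cc$dt_h, 2 * cc$dose_gy, tolerance = 2 / 10)
  slope <- stats::coef(stats::lm(dt_h ~ dose_gy, data = cc))[["dose_gy"]]
  expect_equal(slope, 2, tolerance = 0.05)
})

test_that("collapse onset is measured and increases with dose", {
  scan <- test_scan()
  cc <- collapse_curve(scan)
  expect_identical(attr(cc, "statistic"), "onset")
  expect_equal(cc$dt_h[cc$dose_gy == 0], 0)          # normal condition
  dt5 <- cc$dt_h[cc$dose_gy == 5]
  dt10 <- cc$dt_h[cc$dose_gy == 10]
  expect_gt(dt10, dt5)
  expect_false(any(cc$censored))
})

test_that("fit is permutation invariant and reports its unit", {
  doses <- seq(0.5, 12, by = 0.5)
  fam <- generate_collapse_family(doses, A = 300, B = 0.05,
                                  noise_cv = 0.02, seed = 9)
  f1 <- fit_collapse_model(fam, time_unit = "h")
  shuffled <- structure(
    data.frame(dose_gy = rev(fam$dose_gy), dt_h = rev(fam$dt_h),
               censored = FALSE),
    time_unit = "h", class = c("ccm_collapse_curve", "data.frame"))
  f2 <- fit_collapse_model(shuffled, time_unit = "h")
  expect_equal(f1$A, f2$A)
  expect_equal(f1$B, f2$B)
  fs <- fit_collapse_model(fam, time_unit = "s")
  expect_equal(fs$A, f1$A * 3600, tolerance = 1e-6)
  expect_equal(fs$B, f1$B, tolerance = 1e-6)
  expect_error(fit_collapse_model(fam[1:3, ]), "4")
})

test_that("saturation detection matches constructed plateaus", {
  doses <- seq(0, 12, by = 0.5)
  flat_above_7 <- ifelse(doses < 7, 10 * doses, 70)
  cv <- structure(data.frame(dose_gy = doses, dt_h = flat_above_7,
                             censored = FALSE),
                  time_unit = "h",
                  class = c("ccm_collapse_curve", "data.frame"))
  sat <- saturation(cv)
  expect_true(sat$saturated)
  expect_equal(sat$r_c_gy, 7, tolerance = 0.5 / 7)
  expect_equal(sat$dt_c_h, 70)
  rising <- structure(data.frame(dose_gy = doses, dt_h = 10 * doses,
                                 censored = FALSE),
                      time_unit = "h",
                      class = c("ccm_collapse_curve", "data.frame"))
  expect_false(saturation(rising)$saturated)
})

test_that("cyclin at zero dose is one sustained segment", {
  b <- time_resolved_bifurcation(0, "cyclin", horizon_h = 150)
  expect_equal(nrow(b$segments), 1L)
  expect_identical(b$segments$label, "period_1")
  expect_gt(nrow(b$maxima), 50)
})

test_that("maxima_vs_dose summarises each dose's window maxima", {
  mk <- function(d) synth_signal("sustained", period_h = 2,
                                 amplitude = 1 + d, horizon_h = 60)
  sc <- synthetic_scan(c(1, 2, 3), mk, species = "cyclin")
  mvd <- maxima_vs_dose(sc, "cyclin", t_window = c(0, 50))
  expect_setequal(unique(mvd$dose_gy), c(1, 2, 3))
  for (d in c(1, 2, 3)) {
    v <- mvd$value[mvd$dose_gy == d]
    expect_equal(v, rep(1 + d, length(v)), tolerance = 1e-5)
  }
  expect_error(maxima_vs_dose(sc, "cyclin", t_window = c(0, 500)),
               "horizon")
})
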