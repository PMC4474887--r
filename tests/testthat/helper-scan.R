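# Shared model runs for the heavier analysis tests: computed once per
# session, memoised.  The dose grid is coarser than the one the analysis
# scripts use (0.25 Gy instead of 0.05 Gy); the phase boundary is
# bisection-refined so the coarse grid does not limit its resolution.

.test_cache <- new.env(parent = emptyenv())

test_scan <- function() {
  if (is.null(.test_cache$scan))
    .test_cache$scan <- run_dose_scan(seq(0, 12, by = 0.25),
                                      horizon_h = 250)
  .test_cache$scan
}

test_trajectory <- function(ir = 5) {
  key <- paste0("traj", ir)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- integrate_model(
      default_parameters(), make_initial_state(ir), t_end_h = 250)
  .test_cache[[key]]
}

# Clean one-instance-per-class fixture suite for the classifier.
regime_fixture_suite <- function() {
  flat <- data.frame(time_h = seq(0, 60, 0.01), value = 1)
  list(
    oscillation_death = flat,
    damped = synth_signal("damped", period_h = 2, tau_h = 6,
                          horizon_h = 60),
    period_1 = synth_signal("sustained", period_h = 2, horizon_h = 60),
    period_2 = synth_signal("period_2", period_h = 2,
                            amplitudes = c(1, 1.5), horizon_h = 60),
    period_3 = synth_signal("period_3", period_h = 2,
                            amplitudes = c(1, 1.4, 0.7), horizon_h = 90),
    chaotic = synth_signal("chaotic_logistic", period_h = 2,
                           horizon_h = 120, seed = 7)
  )
}

classify_fixture <- function(s) {
  classify_regime(find_maxima(s, transient_h = 0))$label
}

# A ccm_scan built from synthetic series instead of model runs, for
# construction-oracle tests of the scan-level analyses.
synthetic_scan <- function(doses, series_fn, species = "p53",
                           horizon_h = NULL) {
  runs <- lapply(doses, function(d) {
    s <- series_fn(d)
    ser <- list(s$value)
    names(ser) <- species
    list(dose_gy = d, time_h = s$time_h, series = ser, error = NULL)
  })
  if (is.null(horizon_h))
    horizon_h <- max(runs[[1]]$time_h)
  structure(list(doses = doses, runs = runs,
                 params = default_parameters(),
                 control = integration_control(), horizon_h = horizon_h,
                 dsb_per_gy = 40, keep_species = species,
                 init_overrides = NULL),
            class = "ccm_scan")
}
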