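# The fixture generator itself: determinism, truth-record recovery,
# parameter perturbation and the collapse-curve family.

test_that("identical spec and seed give identical realizations", {
  a <- synth_signal("chaotic_logistic", period_h = 2, horizon_h = 60,
                    noise_sd = 0.02, seed = 123)
  b <- synth_signal("chaotic_logistic", period_h = 2, horizon_h = 60,
                    noise_sd = 0.02, seed = 123)
  expect_identical(a$value, b$value)
  c <- synth_signal("chaotic_logistic", period_h = 2, horizon_h = 60,
                    noise_sd = 0.02, seed = 124)
  expect_false(identical(a$value, c$value))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(synth_signal("chaotic_logistic", horizon_h = 20, seed = 5))
  expect_identical(runif(1), before)
})

test_that("every truth record is recovered by its detector", {
  for (kind in c("sustained", "damped", "period_2", "period_3",
                 "chaotic_logistic")) {
    s <- synth_signal(kind, period_h = 2,
                      horizon_h = if (kind == "chaotic_logistic") 120
                                  else 60, seed = 17)
    tr <- attr(s, "truth")
    mx <- find_maxima(s, transient_h = 0)
    expect_identical(classify_regime(mx)$label, tr$label)
    # constructed maxima found at the constructed times/heights
    m <- merge(round(data.frame(t = mx$time_h), 1),
               round(data.frame(t = tr$maxima$time_h), 1))
    expect_gte(nrow(m), nrow(tr$maxima) - 1)
  }
  s <- synth_signal("collapse", period_h = 2, horizon_h = 170,
                    collapse_start_h = 40, collapse_len_h = 80)
  expect_equal(collapse_interval(s)$dt_h, attr(s, "truth")$collapse$dt_h,
               tolerance = 2 / 80)
})

test_that("contradictory specs are rejected", {
  expect_error(synth_signal("collapse", horizon_h = 50,
                            collapse_start_h = 30, collapse_len_h = 40),
               "horizon")
  expect_error(synth_signal("piecewise", horizon_h = 50,
                            segments = list()), "segments")
})

test_that("collapse-family fixtures are fit-recoverable", {
  doses <- seq(0, 12, by = 0.25)
  fam <- generate_collapse_family(doses, A = 5000, B = 0.01)
  fit <- fit_collapse_model(fam, time_unit = "h")
  expect_equal(fit$A, 5000, tolerance = 1e-6)
  expect_equal(fit$B, 0.01, tolerance = 1e-6)

  noisy <- generate_collapse_family(seq(0.25, 12.5, by = 0.25), A = 5000,
                                    B = 0.01, noise_cv = 0.05, seed = 42)
  fit2 <- fit_collapse_model(noisy, time_unit = "h")
  expect_equal(fit2$A, 5000, tolerance = 0.1)
  expect_equal(fit2$B, 0.01, tolerance = 0.1)

  degenerate <- generate_collapse_family(doses, A = 0, B = 0.01)
  expect_error(fit_collapse_model(degenerate), "nothing to fit")
})

test_that("parameter perturbation preserves positivity and determinism", {
  p <- default_parameters()
  expect_identical(perturb_parameters(p, cv = 0), p)
  a <- perturb_parameters(p, cv = 0.05, seed = 7)
  b <- perturb_parameters(p, cv = 0.05, seed = 7)
  expect_identical(p53cycle:::param_vector(a),
                   p53cycle:::param_vector(b))
  ka <- p53cycle:::param_vector(a)
  ka <- ka[setdiff(names(ka), c("k5", "k9"))]
  expect_true(all(ka > 0))
  expect_false(identical(ka, p53cycle:::param_vector(p)[names(ka)]))
  # typical relative deviation is on the order of cv
  rel <- abs(ka / p53cycle:::param_vector(p)[names(ka)] - 1)
  expect_lt(max(rel), 0.25)
})

test_that("fixtures are written as a CSV + JSON truth pair", {
  s <- synth_signal("period_2", period_h = 2, horizon_h = 20)
  stem <- tempfile()
  write_fixture(s, stem)
  expect_true(file.exists(paste0(stem, ".csv")))
  expect_true(file.exists(paste0(stem, ".truth.json")))
  tr <- jsonlite::read_json(paste0(stem, ".truth.json"),
                            simplifyVector = TRUE)
  expect_identical(tr$label, "period_2")
})
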