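# Maxima extraction, collapse measurement, regime classification,
# dispersion and segmentation on signals with constructed ground truth.

test_that("sine maxima are found with sub-sample accuracy", {
  s <- synth_signal("sustained", period_h = 2, amplitude = 1,
                    horizon_h = 20)
  mx <- find_maxima(s, transient_h = 0)
  expect_equal(nrow(mx), 10L)
  expect_equal(mx$value, rep(1, 10), tolerance = 1e-6)
  expect_equal(mx$time_h, seq(1, 19, by = 2), tolerance = 1e-4)
  expect_true(all(diff(mx$time_h) > 0))
})

test_that("a monotone decay has no maxima", {
  s <- data.frame(time_h = seq(0, 10, 0.01),
                  value = exp(-seq(0, 10, 0.01)))
  expect_equal(nrow(find_maxima(s, transient_h = 0)), 0L)
})

test_that("plateau maxima are reported once, at the midpoint", {
  v <- c(0, 1, 2, 2, 2, 1, 0, 3, 0)
  s <- data.frame(time_h = 1:9, value = v)
  mx <- find_maxima(s, transient_h = 0)
  expect_equal(nrow(mx), 2L)
  expect_equal(mx$value[1], 2)
  expect_equal(mx$time_h[1], 4)     # midpoint of the tied run
})

test_that("damped-sine peak heights track the known envelope", {
  s <- synth_signal("damped", period_h = 2, tau_h = 20, amplitude = 3,
                    horizon_h = 40)
  mx <- find_maxima(s, transient_h = 0)
  env <- 3 * exp(-mx$time_h / 20)
  expect_true(all(abs(mx$value - env) / env < 1e-3))
})

test_that("transient removal default discards the early window", {
  s <- synth_signal("sustained", period_h = 2, horizon_h = 100)
  mx <- find_maxima(s)     # default transient: max(10 h, 5 periods)
  expect_gte(min(mx$time_h), 10)
  expect_equal(attr(mx, "transient_h"), 10)
})

test_that("collapse measurement recovers a constructed quiet interval", {
  s <- synth_signal("collapse", period_h = 2, horizon_h = 170,
                    collapse_start_h = 50, collapse_len_h = 70)
  ci <- collapse_interval(s)
  expect_equal(ci$dt_h, 70, tolerance = 2 / 70)  # within one period
  expect_equal(ci$start_h, 50, tolerance = 2)
  expect_false(ci$censored)
  # a sustained oscillation has no collapse
  s2 <- synth_signal("sustained", period_h = 2, horizon_h = 60)
  expect_equal(collapse_interval(s2)$dt_h, 0)
  # quiescence reaching the horizon is censored
  s3 <- synth_signal("piecewise", horizon_h = 100, segments = list(
    list(kind = "sustained", period_h = 2, length_h = 40),
    list(kind = "sustained", period_h = 2, amplitude = 0, length_h = 60)))
  ci3 <- collapse_interval(s3)
  expect_true(ci3$censored)
  expect_gt(ci3$dt_h, 50)
})

test_that("regime classification matches construction on clean fixtures", {
  suite <- regime_fixture_suite()
  for (truth in names(suite))
    expect_identical(classify_fixture(suite[[truth]]), truth)
})

test_that("classification is invariant to scaling and time shifts", {
  s <- synth_signal("period_3", period_h = 2,
                    amplitudes = c(1, 1.4, 0.7), horizon_h = 90)
  base <- classify_fixture(s)
  scaled <- transform(s, value = value * 3.14)
  shifted <- transform(s, time_h = time_h + 13)
  expect_identical(classify_fixture(scaled), base)
  expect_identical(classify_fixture(shifted), base)
})

test_that("alternating maxima beyond tolerance give period 2", {
  s <- synth_signal("period_2", period_h = 2, amplitudes = c(1, 1.1),
                    horizon_h = 60)
  r <- classify_regime(find_maxima(s, transient_h = 0))
  expect_identical(r$label, "period_2")
  expect_identical(r$k, 2L)
  # within tolerance the same construction is sustained
  s2 <- synth_signal("period_2", period_h = 2,
                     amplitudes = c(1, 1.001), horizon_h = 60)
  expect_identical(classify_fixture(s2), "period_1")
})

test_that("too few peaks yield insufficient_evidence, not a regime", {
  s <- synth_signal("sustained", period_h = 2, horizon_h = 7)
  r <- classify_regime(find_maxima(s, transient_h = 0))
  expect_identical(r$label, "insufficient_evidence")
})

test_that("return-map dispersion separates periodic from chaotic maxima", {
  expect_equal(maxima_dispersion(rep(c(1, 1.4, 0.7), 20)), 0,
               tolerance = 1e-12)
  ch <- synth_signal("chaotic_logistic", period_h = 2, horizon_h = 120,
                     seed = 11)
  expect_gt(maxima_dispersion(find_maxima(ch, transient_h = 0)), 0.01)
  set.seed(3)
  noisy2 <- rep(c(1, 1.5), 30) * (1 + rnorm(60, 0, 0.001))
  expect_lt(maxima_dispersion(noisy2), 0.01)
  expect_error(maxima_dispersion(1:5), "10")
})

test_that("segmentation tiles the window and finds constructed switches", {
  s <- synth_signal("sustained", period_h = 2, horizon_h = 120)
  seg <- segment_regimes(s)
  expect_equal(nrow(seg), 1L)
  expect_identical(seg$label, "period_1")
  expect_equal(seg$t_start, 0)
  expect_equal(seg$t_end, 120)

  pw <- synth_signal("piecewise", horizon_h = 200, segments = list(
    list(kind = "period_2", period_h = 2, amplitudes = c(1, 1.5),
         length_h = 100),
    list(kind = "chaotic_logistic", period_h = 2, length_h = 100)),
    seed = 5)
  seg2 <- segment_regimes(pw)
  expect_gte(nrow(seg2), 2L)
  expect_identical(seg2$label[1], "period_2")
  expect_identical(seg2$label[nrow(seg2)], "chaotic")
  # changeover within one window of the constructed switch
  i <- which(seg2$label == "chaotic")[1]
  expect_lt(abs(seg2$t_start[i] - 100), 25)
  # segments are contiguous and cover the span
  expect_equal(seg2$t_start[-1], seg2$t_end[-nrow(seg2)])
})
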