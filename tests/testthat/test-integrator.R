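# Fixed-step RK4: closed forms, convergence order, grid invariance,
# trajectory I/O and an independent-solver cross-check.

zero_params <- function() {
  p <- default_parameters()
  for (nm in setdiff(p53cycle:::.k_names, c("k5", "k9")))
    p[[nm]] <- 0   # switch every channel off
  p
}

test_that("with all rates zero the trajectory is constant", {
  init <- make_initial_state(3, dsb_per_gy = 1, equilibrate = FALSE)
  tr <- integrate_model(zero_params(), init, t_end_h = 1,
                        control = integration_control(dt_s = 60))
  for (j in 1:13)
    expect_true(all(tr[[paste0("x", j)]] == init[[j]]))
})

test_that("irradiation decay matches its closed form to 1e-8", {
  p <- default_parameters()     # k24 = 1 per second
  init <- make_initial_state(0, overrides = c(ir = 1),
                             equilibrate = FALSE)
  ctl <- integration_control(dt_s = 0.01, sample_every_h = 10 / 3600)
  tr <- integrate_model(p, init, t_end_h = 10 / 3600, control = ctl)
  x10 <- tr$x10[nrow(tr)]
  expect_equal(x10, exp(-10), tolerance = 1e-8)
})

test_that("empirical convergence order on the full system is four", {
  p <- default_parameters()
  # equilibrated zero-dose start: no stiff channel, no cold-start kink,
  # the cyclin/MPF limit cycle provides the dynamics
  init <- make_initial_state(0)
  final <- function(dt) {
    ctl <- integration_control(dt_s = dt, sample_every_h = 1)
    tr <- integrate_model(p, init, t_end_h = 1, control = ctl)
    as.numeric(tr[nrow(tr), -1])
  }
  ref <- final(0.25)
  dts <- c(8, 4, 2, 1)
  err <- vapply(dts, function(dt) max(abs(final(dt) - ref)), numeric(1))
  # halving the step cuts the error ~16x; estimate the order as the
  # log-log slope over the step ladder
  order_hat <- unname(stats::coef(stats::lm(log2(err) ~ log2(dts)))[2])
  expect_gt(order_hat, 3.5)
  expect_lt(order_hat, 4.5)
})

test_that("integration restarted mid-run is bitwise identical", {
  p <- default_parameters()
  init <- make_initial_state(5, equilibrate = FALSE)
  ctl <- integration_control(dt_s = 2, sample_every_h = 0.05)
  full <- integrate_model(p, init, t_end_h = 2, control = ctl)
  leg1 <- integrate_model(p, init, t_end_h = 1, control = ctl)
  mid <- as.numeric(leg1[nrow(leg1), -1])
  leg2 <- integrate_model(p, mid, t_end_h = 2, control = ctl, t0_h = 1)
  expect_identical(as.numeric(leg2[nrow(leg2), -1]),
                   as.numeric(full[nrow(full), -1]))
})

test_that("argument and state errors are informative", {
  p <- default_parameters()
  expect_error(integrate_model(p, make_initial_state(0), t_end_h = 0),
               "t_end_h")
  bad <- make_initial_state(0, equilibrate = FALSE)
  bad["x5"] <- -1
  expect_error(integrate_model(p, bad, t_end_h = 1), "mdm2")
})

test_that("an independent RK4 implementation reproduces the trajectory", {
  skip_if_not_installed("deSolve")
  p <- default_parameters()
  init <- make_initial_state(0)
  ctl <- integration_control(dt_s = 2, sample_every_h = 0.1)
  ours <- integrate_model(p, init, t_end_h = 0.5, control = ctl)
  ds <- deSolve::rk4(y = init, times = seq(0, 1800, by = 2),
                     func = function(t, y, parms) list(ccm_rhs(y, parms)),
                     parms = p)
  expect_equal(as.numeric(ours[nrow(ours), -1]),
               as.numeric(ds[nrow(ds), -1]), tolerance = 1e-9)
})

test_that("trajectory CSV round trip preserves every number bit-exactly", {
  p <- default_parameters()
  tr <- integrate_model(p, make_initial_state(1, equilibrate = FALSE),
                        t_end_h = 0.5,
                        control = integration_control(dt_s = 2,
                                                      sample_every_h = 0.05))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  for (cl in names(tr)) expect_identical(back[[cl]], tr[[cl]])
  expect_identical(p53cycle:::param_vector(attr(back, "params")),
                   p53cycle:::param_vector(p))
})

test_that("sampling is decoupled from the integration step", {
  p <- default_parameters()
  init <- make_initial_state(0, equilibrate = FALSE)
  coarse <- integrate_model(p, init, t_end_h = 1,
                            control = integration_control(dt_s = 2,
                                                          sample_every_h = 0.25))
  expect_equal(nrow(coarse), 5L)
  expect_equal(coarse$time_h, seq(0, 1, by = 0.25))
})
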