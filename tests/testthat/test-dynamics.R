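test_that("illumination switch has the documented levels and monotonicity", {
  sched <- illumination_schedule(t_ilum = 4)
  # before switch-off the tanh is saturated at +1
  expect_equal(illumination(0, 4, sched), 0.2001, tolerance = 1e-12)
  # at the switch-off time tanh(0) = 0 exactly
  expect_identical(illumination(4, 4, sched), 0.1 * 1.001)
  # long after switch-off the level approaches 0.0001
  expect_equal(illumination(4 + 100, 4, sched), 1e-4, tolerance = 1e-12)
  tgrid <- seq(0, 20, by = 0.05)
  phi <- illumination(tgrid, 4, sched)
  expect_true(all(diff(phi) <= 0))
  expect_true(all(phi > 0 & phi < 0.1 * (1.001 + 1) + 1e-15))
})

test_that("right-hand side matches the Oregonator kinetics term by term", {
  params <- oregonator_params()
  q <- params$q
  # at u = q the nonlinear fraction vanishes: du = (1/eps)(q - q^2)
  net0 <- network_spec(3L, alpha = 0, beta = 0)
  sched <- illumination_schedule(c(10, 10, 10))  # phi(0) = 0.2001
  d <- oregonator_rhs(rep(q, 3), rep(q, 3), 0, params, net0, sched)
  expect_equal(d$du, rep((1 / params$epsilon) * (q - q^2), 3),
               tolerance = 1e-12)
  expect_equal(d$dv, rep(0, 3))
  # symmetric state: all-to-all coupling cancels, leaving pure alpha decay
  net <- network_spec(3L, alpha = 0.849, beta = 0.251)
  a <- 0.3
  d0 <- oregonator_rhs(rep(a, 3), rep(a, 3), 0, params, net0, sched)
  d1 <- oregonator_rhs(rep(a, 3), rep(a, 3), 0, params, net, sched)
  expect_equal(d1$du - d0$du, rep(-0.849 * a, 3), tolerance = 1e-12)
  # beta = 0: oscillators are independent (perturbing u2 leaves du1 alone)
  u <- c(0.1, 0.2, 0.3)
  dA <- oregonator_rhs(u, u, 1, params, net0, sched)
  u2 <- u; u2[2] <- 0.9
  dB <- oregonator_rhs(u2, u2, 1, params, net0, sched)
  expect_identical(dA$du[1], dB$du[1])
  # division domain violation is an error
  expect_error(oregonator_rhs(c(-1, 0.1, 0.1), u, 0, params, net0, sched),
               "instability")
})

test_that("illuminated steady state sits at u = v ~ 0.0002 and is a true root", {
  params <- oregonator_params()
  ss <- steady_state(0.2001, params, alpha = 0)
  expect_equal(signif(ss[["u"]], 1), 2e-4)
  expect_identical(ss[["u"]], ss[["v"]])
  # residual of the full rhs at the fixed point
  net <- network_spec(1L, alpha = 0, beta = 0)
  d <- oregonator_rhs(ss[["u"]], ss[["v"]], 0, params, net,
                      illumination_schedule(10))
  expect_lt(abs(d$du), 1e-9)
  expect_lt(abs(d$dv), 1e-9)
  # the extra activator decay barely moves the root
  ss_a <- steady_state(0.2001, params, alpha = 0.849)
  expect_equal(ss_a[["u"]], ss[["u"]], tolerance = 0.02)
  # strong illumination pins the activator near q
  ss_hi <- steady_state(10, params, alpha = 0)
  expect_lt(ss_hi[["u"]], params$q * 1.01)
})

test_that("a released oscillator stays quiescent before t_ilum, then spikes", {
  params <- oregonator_params()
  traj <- integrate_network(params, single_net(), illumination_schedule(4),
                            coarse_cfg(20))
  pre <- traj$times < 4
  expect_true(all(abs(traj$u[pre, 1] - 2e-4) < 0.1 * 2e-4))
  expect_gt(max(traj$u[, 1]), 0.05)
  # trajectory invariants
  expect_true(all(diff(traj$times) > 0))
  expect_identical(traj$times[1], 0)
  expect_equal(max(traj$times), 20)
  expect_true(all(is.finite(traj$u)) && all(is.finite(traj$v)))
  expect_gt(min(traj$u), -1e-6)
  # excursions above the peak threshold only after the switch-off time
  above <- traj$times[traj$u[, 1] > 0.05]
  expect_true(all(above > 4))
})

test_that("an oscillator illuminated for the whole window never fires", {
  traj <- integrate_network(oregonator_params(), single_net(),
                            illumination_schedule(20), coarse_cfg(20))
  expect_true(all(traj$u[, 1] < 0.001))
  expect_true(all(traj$u[, 1] > oregonator_params()$q / 2))
})

test_that("RK4 refinement converges at its nominal order", {
  params <- oregonator_params()
  sched <- illumination_schedule(4)
  run <- function(h, stride) {
    integrate_network(params, single_net(), sched,
                      integrator_config(20, h = h, store_stride = stride))
  }
  u1 <- run(4e-4, 25L)$u[, 1]
  u2 <- run(2e-4, 50L)$u[, 1]
  u3 <- run(1e-4, 100L)$u[, 1]
  e12 <- max(abs(u1 - u2))
  e23 <- max(abs(u2 - u3))
  expect_gt(e12 / e23, 8)  # observed order >= 3
  # halving from h = 1e-4 changes stored samples by < 1e-6
  u4 <- run(5e-5, 200L)$u[, 1]
  expect_lt(max(abs(u3 - u4)), 1e-6)
})

test_that("maxima counting is interior-only, thresholded, and zero on flat series", {
  mk <- function(u) {
    structure(list(times = seq_along(u) * 0.01 - 0.01,
                   u = matrix(u, ncol = 1), v = matrix(0, length(u), 1)),
              class = "oscnet_trajectory")
  }
  expect_identical(count_maxima(mk(rep(0.5, 10))), 0L)
  # one clear interior peak
  expect_identical(count_maxima(mk(c(0, 0.1, 0.6, 0.1, 0))), 1L)
  # peak below threshold is not counted
  expect_identical(count_maxima(mk(c(0, 0.01, 0.04, 0.01, 0))), 0L)
  # maxima at the endpoints are never counted
  expect_identical(count_maxima(mk(c(0.9, 0.1, 0.05, 0.1, 0.9))), 0L)
  # plateau: first sample of the flat top counts once (u[i-1] < u[i] >= u[i+1])
  expect_identical(count_maxima(mk(c(0, 0.6, 0.6, 0))), 1L)
})

test_that("free-running period is ~10.8 and illumination suppresses it", {
  p200 <- measure_period(cfg = integrator_config(200, h = 1e-3,
                                                 store_stride = 10L))
  expect_equal(p200, 10.8, tolerance = 0.02)
  p400 <- measure_period(cfg = integrator_config(400, h = 1e-3,
                                                 store_stride = 10L))
  expect_lt(abs(p400 - p200) / p200, 0.01)
  expect_error(measure_period(phi = 0.2001,
                              cfg = integrator_config(100, h = 1e-3,
                                                      store_stride = 10L)),
               "no sustained oscillation")
})

test_that("relabeling oscillators permutes trajectories exactly", {
  params <- oregonator_params()
  net <- network_spec(3L, alpha = 0.849, beta = 0.251)
  cfg <- coarse_cfg(20)
  t1 <- integrate_network(params, net, illumination_schedule(c(4, 7, 10)),
                          cfg)
  t2 <- integrate_network(params, net, illumination_schedule(c(7, 10, 4)),
                          cfg)
  perm <- c(2, 3, 1)  # oscillator j of run 1 is oscillator perm[j] of run 2
  expect_identical(t1$u, t2$u[, c(3, 1, 2)])
  expect_identical(t1$v, t2$v[, c(3, 1, 2)])
})

test_that("identically scheduled oscillators stay identical forever", {
  net <- network_spec(3L, alpha = 0.849, beta = 0.251)
  traj <- integrate_network(oregonator_params(), net,
                            illumination_schedule(c(5, 5, 5)),
                            coarse_cfg(20))
  expect_identical(traj$u[, 1], traj$u[, 2])
  expect_identical(traj$u[, 1], traj$u[, 3])
})

test_that("longer inhibition never yields more maxima (single oscillator)", {
  grid <- seq(0, 40, length.out = 50)
  counts <- vapply(grid, single_osc_count, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("integrator config rejects inconsistent windows", {
  expect_error(integrator_config(t_max = -1))
  expect_error(integrator_config(t_max = 1, h = 0))
  expect_error(integrator_config(t_max = 1, h = 1e-4, store_stride = 0))
})
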