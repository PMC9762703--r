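test_that("the response function is threshold-linear and continuous", {
  expect_equal(response(0.22, 0.22, 1), 0)
  expect_equal(response(1.22, 0.22, 1), 1)
  expect_equal(response(-5, 0.22, 1), 0)
  expect_equal(response(0.23, 0.22, 1), 0.01, tolerance = 1e-12)
  expect_equal(response(0.22, 0.22, 2.5), 0)
})

test_that("stationary plasticity variables match the closed forms", {
  s0 <- stationary_stp(0)
  expect_equal(s0$u, 0.8)
  expect_equal(s0$x, 1)
  s5 <- stationary_stp(5, U = 0.8, tau_f = 0.4, tau_r = 3)
  expect_equal(s5$u, 0.8 * 3 / 2.6, tolerance = 1e-12)
  expect_equal(s5$x, 1 / (1 + 3 * (0.8 * 3 / 2.6) * 5), tolerance = 1e-12)
  sInf <- stationary_stp(1e7)
  expect_equal(sInf$u, 1, tolerance = 1e-5)
  expect_lt(sInf$x, 1e-5)
})

test_that("derivatives vanish at rest and match hand evaluation under drive", {
  p <- stp_rnn_params()
  silent <- stationary_state(p, 0, 0)
  expect_true(all(abs(stp_rnn_derivatives(silent, p)) < 1e-12))
  d <- stp_rnn_derivatives(silent, p, e_P = 1, e_I = 0)
  expect_equal(unname(d["A_P"]), (1 - 0.22) / 0.015, tolerance = 1e-12)
  fps <- find_fixed_points(p)
  st <- attr(fps, "states")
  for (i in seq_len(nrow(fps)))
    expect_lt(max(abs(stp_rnn_derivatives(st[i, ], p))), 1e-9)
})

test_that("the default model is bi-stable with one unstable fixed point", {
  fps <- find_fixed_points(stp_rnn_params())
  expect_equal(nrow(fps), 3)
  expect_equal(sum(fps$stable), 2)
  silent <- fps[fps$A_P == 0 & fps$A_I == 0, ]
  expect_equal(nrow(silent), 1)
  expect_true(silent$stable)
  active <- fps[fps$stable & fps$A_P > 0, ]
  expect_equal(nrow(active), 1)
  expect_gt(active$A_P, active$A_I)  # PC rate exceeds IN rate
  expect_true(all(fps$residual < 1e-9))
})

test_that("mono-stable variants have exactly one spontaneous fixed point", {
  for (kind in c("Mono-RNNi", "Mono-RNNe")) {
    fps <- find_fixed_points(make_variant(kind))
    expect_equal(nrow(fps), 1)
    expect_true(fps$stable)
    expect_gt(fps$A_P, 0)
  }
  expect_equal(make_variant("Mono-RNNi")$theta_P, -0.18)
  v <- make_variant("Mono-RNNe")
  expect_equal(c(v$theta_P, v$theta_I, v$J_II), c(-0.3, -0.1, -1.5))
})

test_that("freezing reproduces full-system fixed points and their structure", {
  p <- stp_rnn_params()
  fps <- find_fixed_points(p)
  states <- attr(fps, "states")
  active <- states[which(fps$stable & fps$A_P > 0), ]
  silent <- states[which(fps$A_P == 0 & fps$A_I == 0), ]
  # freeze at any full-system FP: same rates appear as a 2D FP
  for (st in list(active, silent)) {
    fz <- frozen_fixed_points(freeze(p, st))
    d <- sqrt((fz$A_P - st[1])^2 + (fz$A_I - st[2])^2)
    expect_lt(min(d), 1e-9)
  }
  # frozen at silence: stable origin plus the amplification threshold,
  # no active state
  fz_s <- frozen_fixed_points(freeze(p, silent))
  expect_equal(nrow(fz_s), 2)
  expect_true(fz_s$stable[fz_s$A_P == 0 & fz_s$A_I == 0])
  expect_false(any(fz_s$stable & fz_s$A_P > 0))
  # frozen at the active state: two stable FPs (two attraction domains)
  fz_a <- frozen_fixed_points(freeze(p, active))
  expect_equal(sum(fz_a$stable), 2)
})

test_that("trajectories conserve state bounds and stay on stable fixed points", {
  p <- stp_rnn_params()
  fps <- find_fixed_points(p)
  states <- attr(fps, "states")
  active <- states[which(fps$stable & fps$A_P > 0), ]
  silent <- states[which(fps$A_P == 0 & fps$A_I == 0), ]
  tr_s <- integrate_stprnn(p, silent, 1)
  expect_lt(max(abs(tr_s$A_P)), 1e-12)
  tr_a <- integrate_stprnn(p, active, 10, record_every = 10)
  sn <- c("A_P", "A_I")
  expect_lt(max(abs(t(tr_a[, state_cols]) - active)), 1e-6)
  # bounds along a strongly driven trajectory
  tr <- integrate_stprnn(p, silent, 3,
                         pulses = data.frame(time = 0.5, e_PC = 0.25,
                                             e_IN = 0.25))
  xs <- as.matrix(tr[, c("x_PP", "x_IP", "x_PI", "x_II")])
  us <- as.matrix(tr[, c("u_PP", "u_IP", "u_PI", "u_II")])
  expect_true(all(tr$A_P >= 0 & tr$A_I >= 0))
  expect_true(all(xs > 0 & xs <= 1))
  expect_true(all(us >= 0.8 - 1e-9 & us < 1))
})

test_that("the integrator converges: halving dt and Euler cross-check", {
  p <- stp_rnn_params()
  silent <- stationary_state(p, 0, 0)
  pl <- data.frame(time = 0.1, e_PC = 0.25, e_IN = 0.25)
  a <- integrate_stprnn(p, silent, 1.5, pulses = pl, dt = 2e-4)
  b <- integrate_stprnn(p, silent, 1.5, pulses = pl, dt = 1e-4,
                        record_every = 2)
  fin_a <- as.numeric(a[nrow(a), state_cols])
  fin_b <- as.numeric(b[nrow(b), state_cols])
  expect_lt(max(abs(fin_a - fin_b) / pmax(abs(fin_b), 1e-3)), 1e-4)
  # forward-Euler cross-check at small dt on a short segment
  euler <- function(state, t_max, dt) {
    steps <- round(t_max / dt)
    for (i in seq_len(steps)) {
      e <- if (i * dt > 0.1 && i * dt <= 0.12) 0.25 else 0
      state <- state + dt * stp_rnn_derivatives(state, p, e, e)
    }
    state
  }
  fe <- euler(silent, 0.3, 2e-5)
  rk <- integrate_stprnn(p, silent, 0.3,
                         pulses = data.frame(time = 0.1 + 2e-5, e_PC = 0.25,
                                             e_IN = 0.25),
                         dt = 2e-5, record_every = 100)
  expect_lt(max(abs(as.numeric(rk[nrow(rk), state_cols]) - fe)), 1e-2)
})

test_that("pulse responses reproduce the state-dependent burst phenomenology", {
  p <- stp_rnn_params()
  # from the active state: moderate input fails to silence, no burst
  fail <- pulse_experiment(p, "active", 0.25, 0.5)
  expect_equal(fail$outcome, "to_active")
  expect_false(fail$simNB)
  # a stronger IN input silences the network
  succ <- pulse_experiment(p, "active", 0.25, 1)
  expect_equal(succ$outcome, "to_silent")
  expect_false(succ$simNB)
  # from silence: the same balanced input evokes a supra-amplification
  # burst, after which the rested network falls back to silence
  nb <- pulse_experiment(p, "silent", 0.25, 0.25)
  expect_true(nb$simNB)
  expect_equal(nb$outcome, "to_silent")
  active_total <- sum(nb$fps$active[1:2])
  expect_gt(nb$simNB_size, 2 * active_total)
})

test_that("regime classification labels the plane as expected", {
  p <- stp_rnn_params()
  sp <- find_fixed_points(p)
  act <- sp[sp$stable & sp$A_P > 0, ]
  expect_equal(classify_regime(act$A_I, act$A_P, p), "ISN")
  expect_equal(classify_regime(0, 0, p), "Non-ISN")
  # excitatory GABA: the ISN regime does not exist anywhere
  pe <- make_variant("Mono-RNNe")
  m <- regime_map(pe, n = 50, n_col = 60)
  expect_equal(unname(m$areas["ISN"]), 0)
  expect_equal(unname(sum(m$areas)), 2500, tolerance = 1e-6)
})

test_that("regime areas are stable under column refinement", {
  p <- stp_rnn_params()
  m1 <- regime_map(p, n = 50, n_col = 100)
  m2 <- regime_map(p, n = 50, n_col = 200)
  for (lab in c("ISN", "Non-ISN", "unstable"))
    expect_lt(abs(m1$areas[lab] - m2$areas[lab]) /
                max(m2$areas[lab], 1e-9), 0.02)
  expect_equal(unname(sum(m1$areas)), 2500, tolerance = 1e-6)
})

test_that("transition matrices are consistent with single-pulse runs", {
  p <- stp_rnn_params()
  eP <- c(0.25, 0.5); eI <- c(0.5, 1)
  tm <- transition_matrix(p, "active", eP, eI, settle_time = 15)
  for (i in 1:2) for (j in 1:2) {
    r <- pulse_experiment(p, "active", eP[i], eI[j], settle_time = 15)
    expect_equal(tm$outcome[i, j], r$outcome)
  }
})
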