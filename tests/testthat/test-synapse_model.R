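p_default <- synapse_params()

test_that("transfer characteristic: resting anchor, saturation, invertibility", {
  expect_equal(transfer(p_default$m_rest, p_default), 0.151,
               tolerance = 1e-12)
  expect_lt(transfer(10, p_default), 1e-9)          # depression pole
  expect_gt(transfer(-10, p_default), 0.5 - 1e-9)   # potentiation pole
  expect_true(all(diff(transfer(seq(-1, 1, by = 0.01), p_default)) < 0))

  st <- synapse_state(p_default)
  expect_equal(set_weight(st, p_default, 0.151)$m, p_default$m_rest,
               tolerance = 1e-8)
  expect_equal(transfer(set_weight(st, p_default, 0.3)$m, p_default), 0.3,
               tolerance = 1e-8)
  expect_error(set_weight(st, p_default, 0.5), "saturation")
  expect_error(set_weight(st, p_default, 0), "saturation")
})

test_that("spike events set the printed FG jumps and respect injection thresholds", {
  st <- synapse_state(p_default)
  r <- on_pre_spike(st, p_default, 0)
  expect_equal(r$state$v_fg_pre, 0.180, tolerance = 1e-12)
  # no post history: sampled s_post = 0, below 0.35 V -> storage unchanged
  expect_identical(r$state$m, p_default$m_rest)
  expect_equal(r$transmitted, 0.151, tolerance = 1e-12)

  st2 <- on_post_spike(synapse_state(p_default), p_default, 0)
  expect_equal(st2$v_fg_post, 0.135, tolerance = 1e-12)
  expect_identical(st2$m, p_default$m_rest)

  # causal pair 1 ms apart potentiates
  st3 <- on_pre_spike(synapse_state(p_default), p_default, 0)$state
  st3 <- on_post_spike(st3, p_default, 1e-3)
  expect_gt(st3$w, 0.151)

  # a pre spike long after any post transmits without plasticity
  st4 <- on_post_spike(synapse_state(p_default), p_default, 0)
  r4 <- on_pre_spike(st4, p_default, 30) # 30 s >> tau_post
  expect_identical(r4$state$m, p_default$m_rest)

  # sub-threshold sample: post trace decayed until just below 0.35 V
  dt_sub <- p_default$tau_post *
    log(p_default$gain_post * p_default$dv_post / 0.349)
  st5 <- on_post_spike(synapse_state(p_default), p_default, 0)
  r5 <- on_pre_spike(st5, p_default, dt_sub)
  expect_identical(r5$state$m, p_default$m_rest)
})

test_that("decay_to relaxes the integrators and enforces time ordering", {
  st <- on_pre_spike(synapse_state(p_default), p_default, 0)$state
  expect_identical(decay_to(st, p_default, 0)$v_fg_pre, st$v_fg_pre)
  st1 <- decay_to(st, p_default, p_default$tau_pre)
  expect_equal(st1$v_fg_pre, 0.180 / exp(1), tolerance = 1e-12)
  expect_identical(st1$m, st$m)
  expect_identical(st1$w, st$w)
  st2 <- decay_to(st, p_default, 10)
  expect_lt(st2$v_fg_pre, 1e-6)
  expect_error(decay_to(st1, p_default, 0), "time-ordering")
  expect_error(on_pre_spike(st1, p_default, -1), "time-ordering")
})

test_that("single-pair STDP curve has the pair-rule sign structure", {
  cu <- stdp_curve(p_default, dt_ms = c(-500, -50, -1, 0, 1, 50, 500))
  expect_identical(cu$dvw_V[cu$dt_ms == 0], 0)
  expect_gt(cu$dvw_V[cu$dt_ms == 1], 0)
  expect_lt(cu$dvw_V[cu$dt_ms == -1], 0)
  peak <- max(abs(cu$dvw_V))
  expect_lt(abs(cu$dvw_V[cu$dt_ms == 500]), 0.01 * peak)
  expect_lt(abs(cu$dvw_V[cu$dt_ms == -500]), 0.01 * peak)

  # sign correct over each window's support (LTP injection truncates at
  # tau_pre * log(S0/theta) ~ 37 ms), magnitude non-increasing throughout
  pos <- stdp_curve(p_default, dt_ms = 1:50)$dvw_V
  neg <- stdp_curve(p_default, dt_ms = -(1:50))$dvw_V
  expect_true(all(pos[1:35] > 0))
  expect_true(all(pos >= 0))
  expect_true(all(neg < 0))
  expect_true(all(diff(pos) <= 1e-12))
  expect_true(all(diff(abs(neg)) <= 1e-12))
})

test_that("fit_stdp recovers exact exponentials and the calibrated windows", {
  dts <- c(-seq(400, 4, by = -4), seq(4, 400, by = 4))
  truth <- ifelse(dts > 0, 0.02 * exp(-dts / 20), -0.01 * exp(dts / 80))
  f <- fit_stdp(data.frame(dt_ms = dts, dvw_V = truth))
  expect_equal(f$a_plus, 0.02, tolerance = 1e-6)
  expect_equal(f$tau_plus_ms, 20, tolerance = 1e-6)
  expect_equal(f$a_minus, 0.01, tolerance = 1e-6)
  expect_equal(f$tau_minus_ms, 80, tolerance = 1e-6)
  expect_lt(f$residual, 1e-8)

  fd <- fit_stdp(stdp_curve(p_default))
  expect_equal(fd$tau_plus_ms, 16.8, tolerance = 0.1)
  expect_equal(fd$tau_minus_ms, 76.5, tolerance = 0.1)

  only_pos <- data.frame(dt_ms = dts[dts > 0], dvw_V = truth[dts > 0])
  expect_error(fit_stdp(only_pos), "both positive and negative")
})

test_that("weight dependence vanishes at the VTC poles with an interior LTP maximum", {
  wd_ltd <- weight_dependence(p_default, -1, c(0, 0.05, 0.151))
  expect_lt(abs(wd_ltd$dvw_V[wd_ltd$w_V == 0]), 1e-6)
  expect_true(all(wd_ltd$dvw_V <= 0))

  grid <- seq(0.002, 0.498, by = 0.004)
  wd_ltp <- weight_dependence(p_default, 1, grid)
  peak <- max(wd_ltp$dvw_V)
  expect_gt(peak, 0)
  expect_lt(abs(wd_ltp$dvw_V[length(grid)]), 0.01 * peak) # near 0.5 V
  expect_lt(abs(wd_ltp$dvw_V[1]), 0.2 * peak)             # near 0 V
  imax <- which.max(wd_ltp$dvw_V)
  expect_gt(imax, 5)
  expect_lt(imax, length(grid) - 5)                       # interior maximum
})

test_that("successive causal pairs give non-increasing potentiation steps", {
  st <- synapse_state(p_default)
  steps <- numeric(40)
  t0 <- 0
  for (i in seq_along(steps)) {
    w_before <- st$w
    st <- on_pre_spike(st, p_default, t0)$state
    st <- on_post_spike(st, p_default, t0 + 1e-3)
    steps[i] <- st$w - w_before
    t0 <- t0 + 5 # 5 s clears both traces between pairs
  }
  expect_true(all(steps > 0))
  expect_true(all(diff(steps) <= 1e-12))
})

test_that("weights stay within [0, 0.5 V] over long random event streams", {
  set.seed(42)
  n <- 100000
  tt <- cumsum(stats::rexp(n, 40))
  kind <- sample(c("pre", "post"), n, replace = TRUE)
  st <- synapse_state(p_default)
  wmin <- Inf; wmax <- -Inf
  for (i in seq_len(n)) {
    if (kind[i] == "pre") st <- on_pre_spike(st, p_default, tt[i])$state
    else st <- on_post_spike(st, p_default, tt[i])
    if (st$w < wmin) wmin <- st$w
    if (st$w > wmax) wmax <- st$w
  }
  expect_gte(wmin, 0)
  expect_lte(wmax, 0.5)
})

test_that("event-driven plasticity equals the nearest-pair brute-force replay", {
  for (s in 1:100) {
    ev <- random_sequence(100, rate_hz = 8, seed = s)
    expect_equal(run_sequence(p_default, ev),
                 oracle_replay_nearest(p_default, ev), tolerance = 1e-12)
  }
})

test_that("accumulate pairing mode piles up the traces", {
  pa <- synapse_params(pairing_mode = "accumulate")
  st <- on_pre_spike(synapse_state(pa), pa, 0)$state
  st <- on_pre_spike(st, pa, 1e-4)$state
  expect_gt(st$v_fg_pre, 0.35) # two near-coincident jumps accumulate
  pn <- synapse_params()
  stn <- on_pre_spike(synapse_state(pn), pn, 0)$state
  stn <- on_pre_spike(stn, pn, 1e-4)$state
  expect_equal(stn$v_fg_pre, 0.180, tolerance = 1e-12) # nearest resets
})

test_that("imposed simultaneous pre and post spikes cause no plasticity", {
  st <- on_pre_spike(synapse_state(p_default), p_default, 0.5)$state
  st <- on_post_spike(st, p_default, 0.5)
  expect_identical(st$m, p_default$m_rest)
})
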