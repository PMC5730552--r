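test_that("tunnel current is zero at zero bias, odd in voltage, and scales as the WKB law", {
  b <- tunnel_barrier(1.1, 60 * 120, barrier_eV = 3.1, m_star = 0.4)
  expect_identical(tunnel_current(0, b, g0 = 1e6), 0)

  # value against an independent evaluation of the closed form
  got <- tunnel_current(0.2, b, g0 = 1e6)
  want <- oracle_tunnel_current(0.2, 1.1, 60 * 120, 3.1, 0.4, 1e6)
  expect_equal(got, want, tolerance = 1e-12)

  # sign follows bias; magnitude strictly increasing in |V|
  v <- c(-0.4, -0.1, 0.1, 0.3)
  expect_equal(sign(tunnel_current(v, b, g0 = 1e6)), sign(v))
  mags <- abs(tunnel_current(c(0.05, 0.1, 0.2, 0.4), b, g0 = 1e6))
  expect_true(all(diff(mags) > 0))

  # thinner barrier leaks more; double area doubles current
  b_thick <- tunnel_barrier(1.4, 60 * 120)
  expect_lt(abs(tunnel_current(0.2, b_thick, g0 = 1e6)), got)
  b2 <- tunnel_barrier(1.1, 2 * 60 * 120)
  expect_equal(tunnel_current(0.2, b2, g0 = 1e6), 2 * got,
               tolerance = 1e-12)

  expect_error(tunnel_current(NaN, b, g0 = 1e6), "finite")
})

test_that("free FG relaxation matches closed forms and a fine-step ODE oracle", {
  nd <- fg_node(2, leak_model("exponential", tau = 1))
  expect_identical(relax_fg(nd, 0.18, 0), 0.18)
  expect_equal(relax_fg(nd, 0.18, 1), 0.18 / exp(1), tolerance = 1e-12)
  expect_error(relax_fg(nd, 0.18, -1), "non-negative")

  tn <- fg_node(2, fg_integrator_leak())
  tr <- relaxation_time(tn)
  for (dur in c(0.3, 1, 5) * tr) {
    expect_equal(relax_fg(tn, 0.18, dur), oracle_relax_ode(tn, 0.18, dur),
                 tolerance = 1e-3)
  }
  # long-time asymptote
  expect_lt(abs(relax_fg(tn, 0.18, 100 * tr)), 1e-9)
})

test_that("relaxation time: exponential closed form, calibrated anchor, degenerate error", {
  for (tau in c(1e-3, 0.1, 1, 50, 1000)) {
    nd <- fg_node(2, leak_model("exponential", tau = tau))
    expect_equal(relaxation_time(nd), tau * log(2), tolerance = 1e-14)
  }
  expect_error(leak_model("exponential", tau = 0), "> 0")

  # calibration anchor: 1.3 nm barrier on 2 fF relaxes in 0.5 s
  nd <- fg_node(2, fg_integrator_leak())
  expect_equal(relaxation_time(nd), 0.5, tolerance = 2e-3)

  # a very thick barrier decays far beyond the search horizon
  lk <- fg_integrator_leak()
  thick <- leak_model("tunneling", barrier = tunnel_barrier(3.5, 60 * 120),
                      g0 = lk$g0)
  expect_error(relaxation_time(fg_node(30, thick)), "horizon")
  expect_error(relaxation_time(nd, v_peak = 0), "non-zero")
})

test_that("retention time: closed form, 70-100 s storage band, monotone in level", {
  nd <- fg_node(30, leak_model("exponential", tau = 100))
  expect_equal(retention_time(nd, -0.3), 100 * log(10 / 9),
               tolerance = 1e-12)
  expect_error(retention_time(nd, 0), "non-zero")

  stor <- fg_node(30, fg_storage_leak())
  rts <- vapply(c(-0.45, -0.3, -0.15, 0.2, 0.4),
                function(v) retention_time(stor, v), numeric(1))
  expect_true(all(rts >= 70 & rts <= 100))
  # larger stored voltage never retains longer
  ord <- vapply(c(0.1, 0.2, 0.3, 0.45), function(v) retention_time(stor, v),
                numeric(1))
  expect_true(all(diff(ord) <= 1e-6))
})

test_that("leak calibration reproduces anchors and rejects inconsistent ones", {
  m <- calibrate_leak(data.frame(c_fg_fF = 2, t_tun_nm = 1.3,
                                 tau_relax_s = 0.5))
  nd <- fg_node(2, m)
  expect_equal(relaxation_time(nd), 0.5, tolerance = 0.05)

  me <- calibrate_leak(data.frame(c_fg_fF = 5, tau_relax_s = 0.7),
                       mode = "exponential")
  expect_equal(me$tau, 0.7 / log(2), tolerance = 1e-12)

  # one-parameter law cannot satisfy two anchors at the same thickness
  # and capacitance but different relaxation times
  bad <- data.frame(c_fg_fF = c(2, 2), t_tun_nm = c(1.3, 1.3),
                    tau_relax_s = c(0.5, 5))
  expect_error(calibrate_leak(bad), "residuals")
})

test_that("relaxation time scales exponentially with thickness and linearly with capacitance", {
  sw <- device_sweep(seq(1.1, 1.6, by = 0.1), 2)
  fit <- stats::lm(log10(tau_relax_s) ~ t_tun_nm, data = sw)
  # log-linear in t_tun up to the 1e-3 bisection tolerance
  expect_lt(max(abs(stats::residuals(fit))), 1e-3)

  t13 <- sw$tau_relax_s[sw$t_tun_nm == 1.3]
  nd169 <- fg_node(2, leak_model("tunneling",
                                 barrier = tunnel_barrier(1.3 * 1.3,
                                                          60 * 120),
                                 g0 = fg_integrator_leak()$g0))
  expect_gte(relaxation_time(nd169) / t13, 30) # 30% thickness, >= 30x

  sw2 <- device_sweep(1.3, c(2, 20))
  ratio <- sw2$tau_relax_s[sw2$c_fg_fF == 20] /
    sw2$tau_relax_s[sw2$c_fg_fF == 2]
  expect_gt(ratio, 1)
  expect_lt(ratio, 100) # tenfold capacitance, under two orders
})
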