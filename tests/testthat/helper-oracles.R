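# Independent oracles used across the suite. These re-derive expected
# values from first principles (closed forms, fine-step ODE integration,
# event-by-event replay) without touching the package's internal kernels.

# physical constants, written out independently of the package source
ORC <- list(q = 1.602176634e-19, m_e = 9.1093837015e-31,
            hbar = 1.054571817e-34)

# closed-form WKB tunneling current, evaluated independently
oracle_tunnel_current <- function(v, t_nm, area_nm2, phi_eV, m_star, g0) {
  kappa <- sqrt(2 * m_star * ORC$m_e * ORC$q * phi_eV) / ORC$hbar
  area_nm2 * 1e-18 * g0 * v * exp(-2 * kappa * t_nm * 1e-9)
}

# fine-step RK4 integration of C dV/dt = -I(V) for a tunneling-mode node
oracle_relax_ode <- function(node, v0, duration, n_steps = 4000) {
  lk <- node$leak
  b <- lk$barrier
  rhs <- function(t, y, parms) {
    list(-oracle_tunnel_current(y[1], b$thickness_nm, b$area_nm2,
                                b$barrier_eV, b$m_star, lk$g0) / node$c_fg)
  }
  times <- seq(0, duration, length.out = n_steps + 1)
  out <- deSolve::ode(y = c(v = v0), times = times, func = rhs,
                      parms = NULL, method = "rk4")
  unname(out[nrow(out), "v"])
}

# brute-force replay of a spike sequence under nearest-pairing semantics:
# at each spike the counter-trace is recomputed from only the most recent
# strictly earlier counter-spike. `events` is a data.frame with columns
# t (strictly increasing) and kind ("pre"/"post"). Returns the weight
# after every event.
oracle_replay_nearest <- function(params, events) {
  vmax <- params$vtc_vmax; mid <- params$vtc_mid; slo <- params$vtc_slope
  m <- params$m_rest
  last_pre <- -Inf
  last_post <- -Inf
  w_of <- function(m) vmax / (1 + exp((m - mid) / slo))
  w_hist <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    t <- events$t[i]
    if (events$kind[i] == "pre") {
      if (is.finite(last_post)) {
        s_post <- params$gain_post * params$dv_post *
          exp(-(t - last_post) / params$tau_post)
        if (s_post > params$theta_post) {
          ex <- -(m - params$m_rest) / params$lambda_minus
          m <- m + params$c_minus * (s_post - params$theta_post) *
            exp(min(max(ex, -1.5), 1.5))
        }
      }
      last_pre <- t
    } else {
      if (is.finite(last_pre)) {
        s_pre <- params$gain_pre * params$dv_pre *
          exp(-(t - last_pre) / params$tau_pre)
        if (s_pre > params$theta_pre) {
          ex <- (m - params$m_rest) / params$lambda_plus
          m <- m - params$c_plus * (s_pre - params$theta_pre) *
            exp(min(max(ex, -1.5), 1.5))
        }
      }
      last_post <- t
    }
    w_hist[i] <- w_of(m)
  }
  w_hist
}

# run the same sequence through the package's event operations
run_sequence <- function(params, events) {
  st <- synapse_state(params)
  w_hist <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] == "pre") {
      st <- on_pre_spike(st, params, events$t[i])$state
    } else {
      st <- on_post_spike(st, params, events$t[i])
    }
    w_hist[i] <- st$w
  }
  w_hist
}

# random strictly-increasing pre/post sequence
random_sequence <- function(n, rate_hz = 8, seed = 1) {
  set.seed(seed)
  t <- cumsum(stats::rexp(n, rate_hz))
  data.frame(t = t, kind = sample(c("pre", "post"), n, replace = TRUE))
}
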