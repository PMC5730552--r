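# Behavioral floating-gate synapse.
#
# Two fast FG integrators hold the pre- and postsynaptic spike traces: a
# spike resets (nearest-pairing) or increments (accumulate) the
# corresponding FG voltage, which then relaxes through its leak. The
# sampling subcircuits amplify the FG voltages onto the state variables
# (s_pre <= 0, s_post >= 0); a counter-spike samples the opposing state
# variable and, when the sample exceeds the junction's injection threshold,
# injects charge into the storage node m. Injection is self-limiting
# (detailed balance): the further m has already moved in the injection
# direction, the smaller the next injection, via an exponential factor with
# scale lambda. The stored level maps onto the synaptic weight through a
# saturating voltage-transfer characteristic (VTC) bounded in (0, vtc_vmax).
#
# Sign convention: potentiation injects electrons into the storage node
# (m decreases), and the VTC is monotone decreasing in m, so LTP raises the
# weight. The convention is internal; only the weight is observable.

# Default calibration (see the methods vignette for the derivation):
#  - tau_pre/tau_post chosen so that the least-squares exponential fit of
#    the single-pair curve returns 16.8 / 76.5 ms windows;
#  - vtc_slope = 0.2 V so the detailed balance has enough leverage
#    between the resting weight and the pairing plateau that a single
#    causal trigger outweighs the accumulated anti-causal echo of a 20 Hz
#    input bin (the binned competition protocols die otherwise);
#  - lambda_plus = 0.25 V (successive causal-pair potentiation steps
#    shrink monotonically from rest; weaker soft-bounding would strengthen
#    competition but violate that monotonicity); lambda_minus = 0.70 V
#    keeps depression alive near the lower pole so a losing afferent stays
#    disconnected; the c_plus/c_minus ratio is then solved so that 20 Hz
#    pairing (dt = +1 ms, LTD echo at -49 ms) has its stable upper weight
#    plateau at 0.27 V;
#  - c_plus sets the absolute plasticity rate: one full-strength causal
#    pair moves the weight by ~16 mV from rest, which completes the joint
#    growth phase of the two-afferent competition within tens of seconds.
.SYN_CAL <- list(
  tau_pre_ms   = 55.3991,
  tau_post_ms  = 274.2440,
  lambda_plus  = 0.25,
  lambda_minus = 0.70,
  c_plus       = 0.100,
  c_minus      = 0.054003
)

#' Behavioral synapse parameters
#'
#' All voltages are in volts and times in seconds internally; constructor
#' arguments use the natural units stated below.
#'
#' @param dv_pre_mV FG-voltage jump per presynaptic spike (mV, default 180).
#' @param dv_post_mV FG-voltage jump per postsynaptic spike (mV, default 135).
#' @param tau_pre_ms,tau_post_ms relaxation time constants of the pre/post
#'   FG integrators (ms); defaults calibrated to the 16.8/76.5 ms STDP
#'   windows. Alternatively supply `leak_pre`/`leak_post`.
#' @param leak_pre,leak_post optional [leak_model()] objects overriding the
#'   time constants (tunneling-mode leaks use `c_pre_fF`/`c_post_fF`).
#' @param c_pre_fF,c_post_fF integrator node capacitances (fF), used only
#'   with tunneling-mode leaks (default 2).
#' @param gain_pre,gain_post sampling-subcircuit gains mapping the FG
#'   voltage onto the state variables `s_pre = -gain_pre * v_fg_pre`,
#'   `s_post = +gain_post * v_fg_post` (defaults 3.6, 4.8: both state
#'   variables peak at 0.648 V after a single spike).
#' @param theta_post_V injection threshold on the sampled postsynaptic
#'   variable (V, default 0.35; LTD junction).
#' @param theta_pre_V magnitude threshold on the sampled presynaptic
#'   variable (V, default 0.33; LTP junction).
#' @param c_plus,c_minus injection gains (V of storage shift per V of
#'   super-threshold sample); calibrated defaults.
#' @param lambda_plus,lambda_minus detailed-balance scales (V); calibrated
#'   defaults.
#' @param vtc_vmax_V upper weight bound of the VTC (V, default 0.5).
#' @param vtc_slope_V VTC slope parameter (V, default 0.2).
#' @param w_rest_V resting weight, `transfer(m_rest)` (V, default 0.151).
#'   This is the behavioral image of the storage control bias.
#' @param pairing_mode `"nearest"` (counter-trace reset per spike, default)
#'   or `"accumulate"` (traces pile up).
#' @param storage_tau_s optional storage-node relaxation time constant
#'   (seconds). `NULL` (default) disables storage leak: retention is much
#'   slower than the plasticity experiments, which all finish within 150 s.
#' @return An object of class `synapse_params`.
#' @export
#' @examples
#' p <- synapse_params()
#' transfer(0, p) # resting weight 0.151 V
synapse_params <- function(dv_pre_mV = 180, dv_post_mV = 135,
                           tau_pre_ms = .SYN_CAL$tau_pre_ms,
                           tau_post_ms = .SYN_CAL$tau_post_ms,
                           leak_pre = NULL, leak_post = NULL,
                           c_pre_fF = 2, c_post_fF = 2,
                           gain_pre = 3.6, gain_post = 4.8,
                           theta_post_V = 0.35, theta_pre_V = 0.33,
                           c_plus = .SYN_CAL$c_plus,
                           c_minus = .SYN_CAL$c_minus,
                           lambda_plus = .SYN_CAL$lambda_plus,
                           lambda_minus = .SYN_CAL$lambda_minus,
                           vtc_vmax_V = 0.5, vtc_slope_V = 0.2,
                           w_rest_V = 0.151,
                           pairing_mode = c("nearest", "accumulate"),
                           storage_tau_s = NULL) {
  pairing_mode <- match.arg(pairing_mode)
  for (nm in c("dv_pre_mV", "dv_post_mV", "gain_pre", "gain_post",
               "theta_post_V", "theta_pre_V", "vtc_vmax_V", "vtc_slope_V",
               "w_rest_V")) {
    .check_number(get(nm), nm, positive = TRUE)
  }
  .check_number(c_plus, "c_plus", nonneg = TRUE)
  .check_number(c_minus, "c_minus", nonneg = TRUE)
  .check_number(lambda_plus, "lambda_plus", positive = TRUE)
  .check_number(lambda_minus, "lambda_minus", positive = TRUE)
  resolve_tau <- function(leak, tau_ms, c_fF, what) {
    if (is.null(leak)) {
      .check_number(tau_ms, paste0("tau_", what, "_ms"), positive = TRUE)
      return(tau_ms * 1e-3)
    }
    stopifnot(inherits(leak, "fg_leak"))
    .leak_tau(fg_node(c_fF, leak))
  }
  tau_pre <- resolve_tau(leak_pre, tau_pre_ms, c_pre_fF, "pre")
  tau_post <- resolve_tau(leak_post, tau_post_ms, c_post_fF, "post")
  if (w_rest_V <= 0 || w_rest_V >= vtc_vmax_V) {
    stop("`w_rest_V` must lie strictly inside (0, vtc_vmax_V)",
         call. = FALSE)
  }
  if (!is.null(storage_tau_s)) {
    .check_number(storage_tau_s, "storage_tau_s", positive = TRUE)
  }
  m_rest <- 0
  vtc_mid <- m_rest - vtc_slope_V * log(vtc_vmax_V / w_rest_V - 1)
  structure(
    list(dv_pre = dv_pre_mV * 1e-3, dv_post = dv_post_mV * 1e-3,
         tau_pre = tau_pre, tau_post = tau_post,
         gain_pre = gain_pre, gain_post = gain_post,
         theta_post = theta_post_V, theta_pre = theta_pre_V,
         c_plus = c_plus, c_minus = c_minus,
         lambda_plus = lambda_plus, lambda_minus = lambda_minus,
         vtc_vmax = vtc_vmax_V, vtc_slope = vtc_slope_V,
         m_rest = m_rest, vtc_mid = vtc_mid, w_rest = w_rest_V,
         pairing_mode = pairing_mode,
         storage_tau = storage_tau_s),
    class = "synapse_params"
  )
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf(
    paste0("<synapse_params> dv = %.0f/%.0f mV, tau = %.3g/%.3g ms, ",
           "theta = %.2f/%.2f V, w_rest = %.3f V, mode = %s\n"),
    x$dv_pre * 1e3, x$dv_post * 1e3, x$tau_pre * 1e3, x$tau_post * 1e3,
    x$theta_pre, x$theta_post, x$w_rest, x$pairing_mode))
  invisible(x)
}

#' Storage-to-weight voltage-transfer characteristic
#'
#' Smooth, monotone-decreasing logistic map from the storage level `m`
#' onto the weight range `(0, vtc_vmax)`.
#'
#' @param m storage level(s) in volts.
#' @param params a [synapse_params()].
#' @return Weight(s) in volts.
#' @export
#' @examples
#' transfer(0, synapse_params())
transfer <- function(m, params) {
  params$vtc_vmax / (1 + exp((m - params$vtc_mid) / params$vtc_slope))
}

#' Fresh synapse state
#'
#' Integrators at zero, storage at its resting level, no spike history.
#'
#' @param params a [synapse_params()].
#' @return An object of class `synapse_state` with fields `v_fg_pre`,
#'   `v_fg_post` (trace magnitudes, V), `m` (storage level, V), `w`
#'   (cached weight, V), `last_pre_t`, `last_post_t`, `t` (s).
#' @export
synapse_state <- function(params) {
  structure(
    list(v_fg_pre = 0, v_fg_post = 0, v_fg_pre_prev = 0,
         v_fg_post_prev = 0, m = params$m_rest,
         w = transfer(params$m_rest, params),
         last_pre_t = -Inf, last_post_t = -Inf, t = 0),
    class = "synapse_state"
  )
}

# relax both integrators (and optionally the storage node) to time t;
# assumes t >= state$t (checked by callers)
.syn_relax <- function(state, params, t) {
  dt <- t - state$t
  if (dt > 0) {
    state$v_fg_pre <- state$v_fg_pre * exp(-dt / params$tau_pre)
    state$v_fg_post <- state$v_fg_post * exp(-dt / params$tau_post)
    if (!is.null(params$storage_tau)) {
      m0 <- params$m_rest
      state$m <- m0 + (state$m - m0) * exp(-dt / params$storage_tau)
      state$w <- transfer(state$m, params)
    }
    state$t <- t
  }
  state
}

#' Relax a synapse state to a later time
#'
#' Both FG integrators decay through their leaks; the storage level and
#' weight stay put unless a storage leak is configured.
#'
#' @param state a [synapse_state()].
#' @param params a [synapse_params()].
#' @param t target time in seconds (>= current state time).
#' @return The relaxed [synapse_state()].
#' @export
decay_to <- function(state, params, t) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(params, "synapse_params"))
  .check_number(t, "t")
  if (t < state$t) {
    stop("time-ordering error: `t` precedes the state time", call. = FALSE)
  }
  .syn_relax(state, params, t)
}

# plasticity kernels ---------------------------------------------------

# A spike coinciding exactly with the sampling instant contributes
# nothing (the dt = 0 branch of the pair rule): when the counter-trace was
# last updated at this very timestamp, the sample reads the trace as it
# stood just before that update, i.e. the trace of the most recent
# strictly earlier counter-spike.

# The detailed-balance factor exp(-(m - m_rest)/lambda) saturates once
# the storage node is deep in a VTC pole: the exponent is clipped at
# +/- .DB_CLIP so that a single pair can never catapult the weight across
# the transfer range, and the single-pair weight change vanishes at both
# poles as the transfer slope does.
.DB_CLIP <- 1.5

.db_factor <- function(x) exp(pmin(pmax(x, -.DB_CLIP), .DB_CLIP))

# LTD: a presynaptic spike samples the postsynaptic trace
.syn_ltd <- function(state, params, t) {
  trace <- if (state$last_post_t < t) state$v_fg_post
           else state$v_fg_post_prev
  s_post <- params$gain_post * trace
  if (s_post > params$theta_post) {
    state$m <- state$m + params$c_minus * (s_post - params$theta_post) *
      .db_factor(-(state$m - params$m_rest) / params$lambda_minus)
    state$w <- transfer(state$m, params)
  }
  state
}

# LTP: a postsynaptic spike samples the presynaptic trace
.syn_ltp <- function(state, params, t) {
  trace <- if (state$last_pre_t < t) state$v_fg_pre
           else state$v_fg_pre_prev
  s_pre_mag <- params$gain_pre * trace # sampled as -s_pre_mag
  if (s_pre_mag > params$theta_pre) {
    state$m <- state$m - params$c_plus * (s_pre_mag - params$theta_pre) *
      .db_factor((state$m - params$m_rest) / params$lambda_plus)
    state$w <- transfer(state$m, params)
  }
  state
}

#' Process a presynaptic spike
#'
#' Relaxes the state to `t`, updates the presynaptic trace (reset in
#' nearest mode, incremented in accumulate mode), samples the postsynaptic
#' state variable and applies depression if it exceeds the LTD threshold,
#' then transmits the (post-update) weight.
#'
#' @param state a [synapse_state()].
#' @param params a [synapse_params()].
#' @param t spike time in seconds.
#' @return list with `state` (updated) and `transmitted` (weight, V).
#' @export
#' @examples
#' p <- synapse_params()
#' on_pre_spike(synapse_state(p), p, 0)
on_pre_spike <- function(state, params, t) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(params, "synapse_params"))
  .check_number(t, "t")
  if (t < state$t) {
    stop("time-ordering error: `t` precedes the state time", call. = FALSE)
  }
  state <- .syn_relax(state, params, t)
  state$v_fg_pre_prev <- state$v_fg_pre
  state$v_fg_pre <- if (params$pairing_mode == "nearest") params$dv_pre
                    else state$v_fg_pre + params$dv_pre
  state <- .syn_ltd(state, params, t)
  state$last_pre_t <- t
  list(state = state, transmitted = state$w)
}

#' Process a postsynaptic spike
#'
#' Mirror of [on_pre_spike()]: updates the postsynaptic trace, samples the
#' presynaptic state variable and applies potentiation if its magnitude
#' exceeds the LTP threshold. No transmission output.
#'
#' @inheritParams on_pre_spike
#' @return The updated [synapse_state()].
#' @export
on_post_spike <- function(state, params, t) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(params, "synapse_params"))
  .check_number(t, "t")
  if (t < state$t) {
    stop("time-ordering error: `t` precedes the state time", call. = FALSE)
  }
  state <- .syn_relax(state, params, t)
  state$v_fg_post_prev <- state$v_fg_post
  state$v_fg_post <- if (params$pairing_mode == "nearest") params$dv_post
                     else state$v_fg_post + params$dv_post
  state <- .syn_ltp(state, params, t)
  state$last_post_t <- t
  state
}

#' Initialize a synapse at a target weight
#'
#' Inverts the VTC by bisection (1e-9 V tolerance on `m`) and zeroes the
#' spike traces; used to seed phase-plane grid nodes and STDP curves.
#'
#' @param state a [synapse_state()].
#' @param params a [synapse_params()].
#' @param target_w_V target weight strictly inside `(0, vtc_vmax)`.
#' @return The re-initialized [synapse_state()].
#' @export
#' @examples
#' p <- synapse_params()
#' set_weight(synapse_state(p), p, 0.3)$w
set_weight <- function(state, params, target_w_V) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(params, "synapse_params"))
  .check_number(target_w_V, "target_w_V")
  if (target_w_V <= 0 || target_w_V >= params$vtc_vmax) {
    stop("`target_w_V` must lie strictly inside (0, vtc_vmax): saturation is unreachable",
         call. = FALSE)
  }
  lo <- params$vtc_mid - 60 * params$vtc_slope
  hi <- params$vtc_mid + 60 * params$vtc_slope
  # transfer is decreasing: transfer(lo) ~ vmax, transfer(hi) ~ 0
  while (hi - lo > 1e-9) {
    mid <- 0.5 * (lo + hi)
    if (transfer(mid, params) > target_w_V) lo <- mid else hi <- mid
  }
  state$m <- 0.5 * (lo + hi)
  state$w <- transfer(state$m, params)
  state$v_fg_pre <- 0
  state$v_fg_post <- 0
  state$v_fg_pre_prev <- 0
  state$v_fg_post_prev <- 0
  state$last_pre_t <- -Inf
  state$last_post_t <- -Inf
  state$t <- 0
  state
}

# default timing-difference grid (ms), denser near the origin, |dt| <= 400
.default_dt_grid <- function() {
  pos <- c(1, 2, 4, 6, 8, seq(12, 400, by = 8))
  c(-rev(pos), pos)
}

#' Single-pair STDP curve
#'
#' For each timing difference `dt = t_post - t_pre`, a fresh synapse at
#' weight `v_w0` receives exactly one pre and one post spike separated by
#' `|dt|`; the weight change is recorded. `dt = 0` yields 0 by convention.
#'
#' @param params a [synapse_params()].
#' @param dt_ms vector of timing differences in ms (each `|dt| < 1000`).
#' @param v_w0 initial weight in volts (default, the resting weight).
#' @return data.frame with columns `dt_ms` and `dvw_V`.
#' @export
#' @examples
#' head(stdp_curve(synapse_params(), dt_ms = c(-50, -10, 10, 50)))
stdp_curve <- function(params, dt_ms = .default_dt_grid(),
                       v_w0 = params$w_rest) {
  stopifnot(inherits(params, "synapse_params"))
  if (!length(dt_ms)) stop("`dt_ms` must be non-empty", call. = FALSE)
  if (any(abs(dt_ms) >= 1000)) {
    stop("each |dt| must be below 1 s", call. = FALSE)
  }
  dvw <- vapply(dt_ms, function(dt) {
    if (dt == 0) return(0)
    st <- set_weight(synapse_state(params), params, v_w0)
    w0 <- st$w
    if (dt > 0) {
      st <- on_pre_spike(st, params, 0)$state
      st <- on_post_spike(st, params, dt * 1e-3)
    } else {
      st <- on_post_spike(st, params, 0)
      st <- on_pre_spike(st, params, -dt * 1e-3)$state
    }
    st$w - w0
  }, numeric(1))
  data.frame(dt_ms = dt_ms, dvw_V = dvw)
}

#' Fit the exponential pair-based STDP model to a curve
#'
#' Nonlinear least squares of `A+ exp(-dt/tau+)` on the causal branch
#' (`dt > 0`) and `-A- exp(dt/tau-)` on the anti-causal branch (`dt < 0`).
#'
#' @param curve data.frame as returned by [stdp_curve()].
#' @return An object of class `stdp_fit` with fields `a_plus`, `a_minus`
#'   (V), `tau_plus_ms`, `tau_minus_ms`, and `residual` (rms, V).
#' @export
#' @examples
#' fit_stdp(stdp_curve(synapse_params()))
fit_stdp <- function(curve) {
  if (!is.data.frame(curve) || !all(c("dt_ms", "dvw_V") %in% names(curve))) {
    stop("`curve` must have columns dt_ms, dvw_V", call. = FALSE)
  }
  pos <- curve[curve$dt_ms > 0, ]
  neg <- curve[curve$dt_ms < 0, ]
  if (!nrow(pos) || !nrow(neg)) {
    stop("`curve` must contain both positive and negative dt samples",
         call. = FALSE)
  }
  fit_branch <- function(t_ms, y, label) {
    a0 <- max(abs(y))
    if (a0 <= 0) {
      stop(sprintf("%s branch is identically zero; nothing to fit", label),
           call. = FALSE)
    }
    above <- t_ms[abs(y) > a0 / 2]
    tau0 <- if (length(above)) max(max(above), 5) else 20
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-t_ms / tau), start = list(a = a0, tau = tau0),
        lower = c(a = 0, tau = 1e-3),
        data = data.frame(t_ms = t_ms, y = y),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop(sprintf(
          "STDP fit did not converge on the %s branch (last start: a = %.3g, tau = %.3g ms): %s",
          label, a0, tau0, conditionMessage(e)), call. = FALSE)
      })
    stats::coef(fit)
  }
  cp <- fit_branch(pos$dt_ms, pos$dvw_V, "causal")
  cn <- fit_branch(-neg$dt_ms, -neg$dvw_V, "anti-causal")
  pred <- ifelse(curve$dt_ms > 0,
                 cp[["a"]] * exp(-curve$dt_ms / cp[["tau"]]),
          ifelse(curve$dt_ms < 0,
                 -cn[["a"]] * exp(curve$dt_ms / cn[["tau"]]), 0))
  structure(
    list(a_plus = cp[["a"]], a_minus = cn[["a"]],
         tau_plus_ms = cp[["tau"]], tau_minus_ms = cn[["tau"]],
         residual = sqrt(mean((curve$dvw_V - pred)^2))),
    class = "stdp_fit"
  )
}

#' @export
print.stdp_fit <- function(x, ...) {
  cat(sprintf(
    "<stdp_fit> A+ = %.3g V, tau+ = %.3g ms | A- = %.3g V, tau- = %.3g ms | rms %.2g V\n",
    x$a_plus, x$tau_plus_ms, x$a_minus, x$tau_minus_ms, x$residual))
  invisible(x)
}

#' Weight dependence of the single-pair weight change
#'
#' Evaluates the single-pair weight change at a fixed timing difference
#' over a grid of starting weights. Grid values at or beyond the VTC poles
#' are clamped just inside `(0, vtc_vmax)`, where the transfer slope (and
#' hence the weight change) vanishes.
#'
#' @param params a [synapse_params()].
#' @param dt_ms timing difference in ms (scalar).
#' @param w_grid starting weights in `[0, vtc_vmax]` (V).
#' @return data.frame with columns `w_V` and `dvw_V`.
#' @export
#' @examples
#' weight_dependence(synapse_params(), 1, seq(0.05, 0.45, by = 0.1))
weight_dependence <- function(params, dt_ms, w_grid) {
  stopifnot(inherits(params, "synapse_params"))
  .check_number(dt_ms, "dt_ms")
  if (any(w_grid < 0) || any(w_grid > params$vtc_vmax)) {
    stop("`w_grid` must lie within [0, vtc_vmax]", call. = FALSE)
  }
  eps <- 1e-7
  w_eff <- pmin(pmax(w_grid, eps), params$vtc_vmax - eps)
  dvw <- vapply(w_eff, function(w0) {
    stdp_curve(params, dt_ms = dt_ms, v_w0 = w0)$dvw_V
  }, numeric(1))
  data.frame(w_V = w_grid, dvw_V = dvw)
}
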