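# Stein point neuron and spike sources.
#
# The postsynaptic neuron is a leaky point neuron: between input events the
# subthreshold membrane potential decays exponentially with tau_m, and each
# presynaptic spike raises it instantaneously by alpha times the sampled
# synaptic weight. The membrane is integrated exactly event-to-event (no
# time stepping), so a postsynaptic spike can only occur at an input-event
# instant; on crossing the threshold the neuron fires and resets. There is
# no refractory period.

#' Stein neuron parameters
#'
#' @param tau_m_ms membrane time constant in ms (default 10).
#' @param threshold_mV firing threshold in mV (default 90).
#' @param alpha dimensionless weight-to-membrane coupling (default 0.3):
#'   an input spike through a synapse of weight `w` volts raises the
#'   membrane by `alpha * w * 1000` mV.
#' @param reset_mV post-spike reset potential in mV (default 0).
#' @return An object of class `stein_params`.
#' @export
#' @examples
#' stein_params()
stein_params <- function(tau_m_ms = 10, threshold_mV = 90, alpha = 0.3,
                         reset_mV = 0) {
  .check_number(tau_m_ms, "tau_m_ms", positive = TRUE)
  .check_number(threshold_mV, "threshold_mV")
  .check_number(alpha, "alpha", nonneg = TRUE)
  .check_number(reset_mV, "reset_mV")
  if (threshold_mV <= reset_mV) {
    stop("`threshold_mV` must exceed `reset_mV`", call. = FALSE)
  }
  structure(list(tau_m = tau_m_ms * 1e-3, threshold = threshold_mV,
                 alpha = alpha, reset = reset_mV),
            class = "stein_params")
}

#' Stein neuron state
#'
#' @param u_m_mV membrane potential in mV.
#' @param t_s current time in seconds.
#' @return An object of class `stein_state`.
#' @export
stein_state <- function(u_m_mV = 0, t_s = 0) {
  .check_number(u_m_mV, "u_m_mV")
  .check_number(t_s, "t_s")
  structure(list(u_m = u_m_mV, t = t_s), class = "stein_state")
}

#' Spike train
#'
#' @param times_s strictly increasing, non-negative spike times (seconds).
#' @param source_id label of the emitting source.
#' @return An object of class `spike_train`.
#' @export
#' @examples
#' spike_train(c(0.1, 0.25), "N1")
spike_train <- function(times_s = numeric(0), source_id = "src") {
  if (length(times_s)) {
    if (any(!is.finite(times_s)) || any(times_s < 0)) {
      stop("spike times must be finite and non-negative", call. = FALSE)
    }
    if (is.unsorted(times_s, strictly = TRUE)) {
      stop("spike times must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times_s), source_id = source_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes", x$source_id, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" on [%.4g, %.4g] s", x$times[1], x$times[length(x$times)]))
  }
  cat("\n")
  invisible(x)
}

#' Exact event-driven integration of the Stein neuron
#'
#' Processes time-sorted weighted input events. Between events the membrane
#' decays as `exp(-dt / tau_m)` in closed form; at each event the membrane
#' jumps by `alpha * weight * 1000` mV and, if the threshold is reached, a
#' spike is emitted at the event time and the membrane resets immediately.
#'
#' @param state a [stein_state()].
#' @param params a [stein_params()].
#' @param events data.frame with columns `t` (seconds, sorted
#'   non-decreasing) and `weight` (volts).
#' @param t_end optional final time to decay to after the last event.
#' @return list with elements `state` (final [stein_state()]) and
#'   `emitted` (a [spike_train()] of output spikes).
#' @export
#' @examples
#' p <- stein_params()
#' ev <- data.frame(t = c(0.01, 0.0101), weight = c(0.151, 0.151))
#' stein_integrate(stein_state(), p, ev)
stein_integrate <- function(state, params, events, t_end = NULL) {
  stopifnot(inherits(state, "stein_state"), inherits(params, "stein_params"))
  if (!is.data.frame(events) || !all(c("t", "weight") %in% names(events))) {
    stop("`events` must be a data.frame with columns t, weight",
         call. = FALSE)
  }
  tt <- events$t
  if (length(tt) && is.unsorted(tt)) {
    stop("`events` must be time-sorted", call. = FALSE)
  }
  if (length(tt) && tt[1] < state$t) {
    stop("events precede the current state time", call. = FALSE)
  }
  u <- state$u_m
  tcur <- state$t
  tau <- params$tau_m
  out <- numeric(0)
  for (i in seq_along(tt)) {
    u <- u * exp(-(tt[i] - tcur) / tau)
    tcur <- tt[i]
    u <- u + params$alpha * events$weight[i] * 1000
    if (u >= params$threshold) {
      out <- c(out, tcur)
      u <- params$reset
    }
  }
  if (!is.null(t_end)) {
    .check_number(t_end, "t_end")
    if (t_end < tcur) stop("`t_end` precedes last event", call. = FALSE)
    u <- u * exp(-(t_end - tcur) / tau)
    tcur <- t_end
  }
  list(state = stein_state(u, tcur), emitted = spike_train(out, "post"))
}

#' Homogeneous Poisson spike train
#'
#' Generated by accumulating i.i.d. exponential inter-spike intervals;
#' reproducible under a fixed seed.
#'
#' @param rate_hz firing rate in Hz (>= 0).
#' @param duration_s train duration in seconds (>= 0).
#' @param seed optional integer seed; when supplied the train is generated
#'   from its own RNG sub-stream without disturbing the global RNG state.
#' @param source_id train label.
#' @return A [spike_train()].
#' @export
#' @examples
#' poisson_train(5, 10, seed = 1)
poisson_train <- function(rate_hz, duration_s, seed = NULL,
                          source_id = "poisson") {
  .check_number(rate_hz, "rate_hz", nonneg = TRUE)
  .check_number(duration_s, "duration_s", nonneg = TRUE)
  if (rate_hz == 0 || duration_s == 0) {
    return(spike_train(numeric(0), source_id))
  }
  gen <- function() {
    n_guess <- max(16, ceiling(rate_hz * duration_s + 6 *
                                 sqrt(rate_hz * duration_s)))
    t <- cumsum(stats::rexp(n_guess, rate_hz))
    while (t[length(t)] < duration_s) {
      t <- c(t, t[length(t)] + cumsum(stats::rexp(n_guess, rate_hz)))
    }
    t[t < duration_s]
  }
  if (!is.null(seed)) {
    times <- local({
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      gen()
    })
  } else {
    times <- gen()
  }
  spike_train(times, source_id)
}

#' Binned alternating Poisson sources
#'
#' Splits `[0, duration_s)` into bins of `bin_width_s`; in every bin one
#' source, chosen uniformly at random, emits Poisson spikes at `rate_hz`
#' while all others stay silent.
#'
#' @param rate_hz in-bin firing rate of the active source (Hz).
#' @param bin_width_s bin width in seconds (> 0).
#' @param duration_s total duration in seconds.
#' @param n_sources number of sources (>= 2).
#' @param seed optional integer seed (sub-stream, as in [poisson_train()]).
#' @return list with `trains` (list of [spike_train()]) and `active`
#'   (integer vector, the active source per bin).
#' @export
#' @examples
#' binned_alternating_trains(20, 0.2, 2, seed = 1)
binned_alternating_trains <- function(rate_hz, bin_width_s, duration_s,
                                      n_sources = 2, seed = NULL) {
  .check_number(rate_hz, "rate_hz", nonneg = TRUE)
  .check_number(bin_width_s, "bin_width_s", positive = TRUE)
  .check_number(duration_s, "duration_s", nonneg = TRUE)
  .check_number(n_sources, "n_sources")
  if (n_sources < 2) stop("`n_sources` must be >= 2", call. = FALSE)
  gen <- function() {
    n_bins <- floor(duration_s / bin_width_s + 1e-9)
    active <- if (n_bins > 0) {
      sample.int(n_sources, n_bins, replace = TRUE)
    } else integer(0)
    times <- vector("list", n_sources)
    for (b in seq_len(n_bins)) {
      t0 <- (b - 1) * bin_width_s
      tr <- poisson_train(rate_hz, bin_width_s)$times + t0
      s <- active[b]
      times[[s]] <- c(times[[s]], tr)
    }
    list(times = times, active = active)
  }
  res <- if (!is.null(seed)) {
    local({
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      gen()
    })
  } else {
    gen()
  }
  trains <- lapply(seq_len(n_sources), function(s) {
    spike_train(res$times[[s]] %||% numeric(0), paste0("N", s))
  })
  list(trains = trains, active = res$active)
}
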