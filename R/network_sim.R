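# Event-driven network engine and experiment protocols.
#
# Networks are small: scheduled or Poisson sources feed one or two targets
# through FG synapses. The engine processes source spikes in time order; a
# presynaptic spike first updates its synapse (trace reset, possible LTD)
# and transmits the post-update weight to the target membrane, and a
# postsynaptic spike - emitted the instant the membrane crosses threshold -
# feeds back onto all afferent synapses at the same instant; the triggering
# synapse samples its freshly set trace (the causal latency is dt -> 0+),
# which is what lets the synapse that evokes firing collect the credit. Scheduled targets
# (imposed spike trains, as in the bidirectional pairing experiment) apply
# their own spikes as postsynaptic events on their afferent synapses.
# Simultaneous events are processed in ascending source order, and the
# membrane threshold is checked after each increment.

#' Build a small spiking network
#'
#' @param sources named list of [spike_train()] objects (imposed spikes).
#' @param synapses list of synapse descriptions; each element is a list
#'   with fields `from` (source name), `to` (target name), and either
#'   `params` (a [synapse_params()], plastic synapse; optional `w_init`)
#'   or `weight` (fixed transmission weight in volts, non-plastic).
#' @param neurons named list of [stein_params()] for integrate-and-fire
#'   targets. A target absent from `neurons` must itself be a source
#'   (scheduled spikes), whose spikes then act as its postsynaptic events.
#' @return An object of class `fg_network`.
#' @export
#' @examples
#' net <- network(
#'   sources = list(N1 = poisson_train(5, 10, seed = 1, source_id = "N1")),
#'   synapses = list(list(from = "N1", to = "N3",
#'                        params = synapse_params())),
#'   neurons = list(N3 = stein_params()))
network <- function(sources, synapses, neurons = list()) {
  stopifnot(is.list(sources), is.list(synapses), is.list(neurons))
  if (is.null(names(sources)) || any(names(sources) == "")) {
    stop("`sources` must be a named list", call. = FALSE)
  }
  for (s in sources) stopifnot(inherits(s, "spike_train"))
  for (p in neurons) stopifnot(inherits(p, "stein_params"))
  nodes <- union(names(sources), names(neurons))
  for (i in seq_along(synapses)) {
    sy <- synapses[[i]]
    if (!sy$from %in% names(sources)) {
      stop(sprintf("synapse %d: unknown source `%s`", i, sy$from),
           call. = FALSE)
    }
    if (!sy$to %in% nodes) {
      stop(sprintf("synapse %d: unknown target `%s`", i, sy$to),
           call. = FALSE)
    }
    has_params <- !is.null(sy$params)
    if (has_params) stopifnot(inherits(sy$params, "synapse_params"))
    if (!has_params && is.null(sy$weight)) {
      stop(sprintf("synapse %d needs either `params` or a fixed `weight`",
                   i), call. = FALSE)
    }
  }
  structure(list(sources = sources, synapses = synapses, neurons = neurons),
            class = "fg_network")
}

#' Run a network and record weight and spike traces
#'
#' @param net an [network()].
#' @param duration_s simulated duration in seconds (> 0).
#' @param sample_dt_s weight sampling interval in seconds (default 0.5).
#'   Sampling reads the recorded event log and never perturbs dynamics.
#' @return An object of class `fg_trace`: list with `times` (sample grid),
#'   `weights` (matrix, one column per synapse, step-sampled), `spikes`
#'   (input trains plus one emitted train per integrate-and-fire neuron),
#'   and `terminal` (final weights).
#' @export
run_network <- function(net, duration_s, sample_dt_s = 0.5) {
  stopifnot(inherits(net, "fg_network"))
  .check_number(duration_s, "duration_s", positive = TRUE)
  .check_number(sample_dt_s, "sample_dt_s", positive = TRUE)

  src_names <- names(net$sources)
  neu_names <- names(net$neurons)
  n_syn <- length(net$synapses)

  # ---- unpack synapses into parallel vectors for the hot loop
  syn_from <- integer(n_syn); syn_to_neu <- integer(n_syn)
  syn_to_src <- integer(n_syn)
  plastic <- logical(n_syn)
  v_pre <- numeric(n_syn); v_post <- numeric(n_syn)
  v_pre_prev <- numeric(n_syn); v_post_prev <- numeric(n_syn)
  m <- numeric(n_syn); w <- numeric(n_syn)
  lp_t <- rep(-Inf, n_syn); lq_t <- rep(-Inf, n_syn)
  st_t <- numeric(n_syn)
  dv_pre <- numeric(n_syn); dv_post <- numeric(n_syn)
  tau_pre <- rep(1, n_syn); tau_post <- rep(1, n_syn)
  g_pre <- numeric(n_syn); g_post <- numeric(n_syn)
  th_pre <- numeric(n_syn); th_post <- numeric(n_syn)
  cpl <- numeric(n_syn); cmn <- numeric(n_syn)
  lpl <- rep(1, n_syn); lmn <- rep(1, n_syn)
  vmax <- numeric(n_syn); vmid <- numeric(n_syn); vslo <- rep(1, n_syn)
  mrest <- numeric(n_syn)
  nearest <- logical(n_syn)
  syn_names <- character(n_syn)

  for (i in seq_len(n_syn)) {
    sy <- net$synapses[[i]]
    syn_from[i] <- match(sy$from, src_names)
    syn_to_neu[i] <- match(sy$to, neu_names, nomatch = 0L)
    syn_to_src[i] <- match(sy$to, src_names, nomatch = 0L)
    syn_names[i] <- sy$name %||% paste0(sy$from, "->", sy$to)
    if (!is.null(sy$params)) {
      p <- sy$params
      plastic[i] <- TRUE
      st <- synapse_state(p)
      if (!is.null(sy$w_init)) st <- set_weight(st, p, sy$w_init)
      v_pre[i] <- st$v_fg_pre; v_post[i] <- st$v_fg_post
      m[i] <- st$m; w[i] <- st$w
      dv_pre[i] <- p$dv_pre; dv_post[i] <- p$dv_post
      tau_pre[i] <- p$tau_pre; tau_post[i] <- p$tau_post
      g_pre[i] <- p$gain_pre; g_post[i] <- p$gain_post
      th_pre[i] <- p$theta_pre; th_post[i] <- p$theta_post
      cpl[i] <- p$c_plus; cmn[i] <- p$c_minus
      lpl[i] <- p$lambda_plus; lmn[i] <- p$lambda_minus
      vmax[i] <- p$vtc_vmax; vmid[i] <- p$vtc_mid; vslo[i] <- p$vtc_slope
      mrest[i] <- p$m_rest
      nearest[i] <- p$pairing_mode == "nearest"
    } else {
      plastic[i] <- FALSE
      w[i] <- sy$weight
    }
  }

  out_syn <- lapply(seq_along(src_names),
                    function(k) which(syn_from == k))
  aff_neu <- lapply(seq_along(neu_names),
                    function(k) which(syn_to_neu == k & plastic))
  aff_src <- lapply(seq_along(src_names),
                    function(k) which(syn_to_src == k & plastic))
  src_is_post <- vapply(aff_src, function(x) length(x) > 0, logical(1))

  # ---- neuron state
  n_neu <- length(neu_names)
  u <- numeric(n_neu); u_t <- numeric(n_neu)
  tau_m <- numeric(n_neu); thr <- numeric(n_neu)
  alph <- numeric(n_neu); rst <- numeric(n_neu)
  for (k in seq_len(n_neu)) {
    p <- net$neurons[[k]]
    tau_m[k] <- p$tau_m; thr[k] <- p$threshold
    alph[k] <- p$alpha; rst[k] <- p$reset
  }
  post_t <- vector("list", n_neu)
  for (k in seq_len(n_neu)) post_t[[k]] <- numeric(0)

  # ---- merged event table
  ev_t <- numeric(0); ev_nd <- integer(0)
  for (k in seq_along(src_names)) {
    tt <- net$sources[[k]]$times
    tt <- tt[tt <= duration_s]
    ev_t <- c(ev_t, tt)
    ev_nd <- c(ev_nd, rep.int(k, length(tt)))
  }
  o <- order(ev_t, ev_nd)
  ev_t <- ev_t[o]; ev_nd <- ev_nd[o]
  nE <- length(ev_t)
  if (nE > 1 && any(diff(ev_t) < 0)) {
    stop("internal-consistency error: event queue is not time-ordered",
         call. = FALSE)
  }

  # ---- weight event log
  cap <- as.integer(nE * 3 + n_syn + 8)
  log_t <- numeric(cap); log_s <- integer(cap); log_w <- numeric(cap)
  nlog <- 0L
  for (i in seq_len(n_syn)) {
    nlog <- nlog + 1L
    log_t[nlog] <- 0; log_s[nlog] <- i; log_w[nlog] <- w[i]
  }

  post_update <- function(s, t, emitted) {
    # postsynaptic event on synapse s at time t (called for plastic only).
    # `emitted` marks a spike fired by the membrane in response to input at
    # this instant: the causal pre -> post latency is infinitesimally
    # positive, so the triggering synapse samples its freshly set trace
    # (dt -> 0+). Imposed (scheduled) post spikes sharing a timestamp with
    # a pre spike carry no causal order and fall under the dt = 0 rule.
    dts <- t - st_t[s]
    if (dts > 0) {
      v_pre[s] <<- v_pre[s] * exp(-dts / tau_pre[s])
      v_post[s] <<- v_post[s] * exp(-dts / tau_post[s])
      st_t[s] <<- t
    }
    v_post_prev[s] <<- v_post[s]
    v_post[s] <<- if (nearest[s]) dv_post[s] else v_post[s] + dv_post[s]
    trace <- if (emitted || lp_t[s] < t) v_pre[s] else v_pre_prev[s]
    sp <- g_pre[s] * trace
    if (sp > th_pre[s]) {
      m[s] <<- m[s] - cpl[s] * (sp - th_pre[s]) *
        .db_factor((m[s] - mrest[s]) / lpl[s])
      w[s] <<- vmax[s] / (1 + exp((m[s] - vmid[s]) / vslo[s]))
      nlog <<- nlog + 1L
      log_t[nlog] <<- t; log_s[nlog] <<- s; log_w[nlog] <<- w[s]
    }
    lq_t[s] <<- t
  }

  for (e in seq_len(nE)) {
    t <- ev_t[e]; nd <- ev_nd[e]
    for (s in out_syn[[nd]]) {
      if (plastic[s]) {
        dts <- t - st_t[s]
        if (dts > 0) {
          v_pre[s] <- v_pre[s] * exp(-dts / tau_pre[s])
          v_post[s] <- v_post[s] * exp(-dts / tau_post[s])
          st_t[s] <- t
        }
        v_pre_prev[s] <- v_pre[s]
        v_pre[s] <- if (nearest[s]) dv_pre[s] else v_pre[s] + dv_pre[s]
        trace <- if (lq_t[s] < t) v_post[s] else v_post_prev[s]
        sq <- g_post[s] * trace
        if (sq > th_post[s]) {
          m[s] <- m[s] + cmn[s] * (sq - th_post[s]) *
            .db_factor(-(m[s] - mrest[s]) / lmn[s])
          w[s] <- vmax[s] / (1 + exp((m[s] - vmid[s]) / vslo[s]))
          nlog <- nlog + 1L
          log_t[nlog] <- t; log_s[nlog] <- s; log_w[nlog] <- w[s]
        }
        lp_t[s] <- t
      }
      # transmission to an integrate-and-fire target
      k <- syn_to_neu[s]
      if (k > 0L) {
        u[k] <- u[k] * exp(-(t - u_t[k]) / tau_m[k])
        u_t[k] <- t
        u[k] <- u[k] + alph[k] * w[s] * 1000
        if (u[k] >= thr[k]) {
          u[k] <- rst[k]
          post_t[[k]] <- c(post_t[[k]], t)
          for (a in aff_neu[[k]]) post_update(a, t, emitted = TRUE)
        }
      }
    }
    if (src_is_post[nd]) {
      for (a in aff_src[[nd]]) post_update(a, t, emitted = FALSE)
    }
  }

  # ---- assemble the trace
  times <- seq(0, duration_s, by = sample_dt_s)
  W <- matrix(NA_real_, nrow = length(times), ncol = n_syn,
              dimnames = list(NULL, syn_names))
  for (i in seq_len(n_syn)) {
    sel <- which(log_s[seq_len(nlog)] == i)
    lt <- log_t[sel]; lw <- log_w[sel]
    idx <- findInterval(times, lt)
    idx[idx == 0L] <- 1L
    W[, i] <- lw[idx]
  }
  spikes <- net$sources
  for (k in seq_len(n_neu)) {
    spikes[[neu_names[k]]] <- spike_train(post_t[[k]], neu_names[k])
  }
  structure(
    list(times = times, weights = W, spikes = spikes,
         terminal = stats::setNames(w, syn_names),
         events = list(t = log_t[seq_len(nlog)], syn = log_s[seq_len(nlog)],
                       w = log_w[seq_len(nlog)])),
    class = "fg_trace"
  )
}

#' @export
print.fg_trace <- function(x, ...) {
  cat(sprintf("<fg_trace> %d synapses over %.4g s; terminal: %s\n",
              ncol(x$weights), max(x$times),
              paste(sprintf("%s = %.3f V", names(x$terminal), x$terminal),
                    collapse = ", ")))
  invisible(x)
}

# accept a single synapse_params or a list of two (per-synapse mismatch)
.two_params <- function(params) {
  if (inherits(params, "synapse_params")) return(list(params, params))
  stopifnot(is.list(params), length(params) == 2L,
            inherits(params[[1]], "synapse_params"),
            inherits(params[[2]], "synapse_params"))
  params
}

#' Bidirectional 20 Hz pairing protocol
#'
#' Two neurons coupled by two plastic synapses exchange a deterministic
#' pair of spikes (first neuron leading by `dt_pair_ms`) every `period_ms`.
#' The causally driven synapse potentiates toward its upper plateau while
#' the reverse synapse (which sees the pair in anti-causal order, plus a
#' wide-window depression from the next pair) decays.
#'
#' @param dt_pair_ms intra-pair offset in ms (0 < dt_pair < period).
#' @param period_ms pair repetition period in ms.
#' @param duration_s protocol duration in seconds.
#' @param params a [synapse_params()] or list of two.
#' @param sample_dt_s weight sampling interval (s).
#' @return An `fg_trace` with synapses `N1->N2` and `N2->N1`.
#' @export
#' @examples
#' tr <- protocol_bidirectional_pairing(duration_s = 5)
#' tr$terminal
protocol_bidirectional_pairing <- function(dt_pair_ms = 1, period_ms = 50,
                                           duration_s = 100,
                                           params = synapse_params(),
                                           sample_dt_s = 0.5) {
  .check_number(dt_pair_ms, "dt_pair_ms", positive = TRUE)
  .check_number(period_ms, "period_ms", positive = TRUE)
  if (dt_pair_ms >= period_ms) {
    stop("`dt_pair_ms` must be smaller than `period_ms`", call. = FALSE)
  }
  pp <- .two_params(params)
  t1 <- seq(0, duration_s - period_ms * 1e-3, by = period_ms * 1e-3)
  t2 <- t1 + dt_pair_ms * 1e-3
  net <- network(
    sources = list(N1 = spike_train(t1, "N1"), N2 = spike_train(t2, "N2")),
    synapses = list(
      list(from = "N1", to = "N2", params = pp[[1]], name = "N1->N2"),
      list(from = "N2", to = "N1", params = pp[[2]], name = "N2->N1")))
  run_network(net, duration_s, sample_dt_s)
}

# shared feedforward builder: two plastic afferents (optionally a fixed
# bias) onto one Stein neuron
.feedforward_net <- function(trains, params, w_init, neuron,
                             bias_train = NULL, bias_weight = NULL) {
  pp <- .two_params(params)
  sources <- list(N1 = trains[[1]], N2 = trains[[2]])
  synapses <- list(
    list(from = "N1", to = "N3", params = pp[[1]], w_init = w_init[1],
         name = "w1"),
    list(from = "N2", to = "N3", params = pp[[2]], w_init = w_init[2],
         name = "w2"))
  if (!is.null(bias_train)) {
    sources$Nsup <- bias_train
    synapses[[3]] <- list(from = "Nsup", to = "N3", weight = bias_weight,
                          name = "wsup")
  }
  network(sources, synapses, neurons = list(N3 = neuron))
}

#' Unsupervised two-afferent competition (independent Poisson inputs)
#'
#' Two Poisson sources drive one Stein neuron through plastic synapses
#' starting from the resting weight (or `w_init`). Weights first grow
#' jointly while postsynaptic firing needs the association of both inputs,
#' then bifurcate as one synapse captures the causal credit.
#'
#' @param rates_hz firing rates of the two sources (Hz).
#' @param duration_s protocol duration (s).
#' @param seed master seed (per-source sub-streams via [derive_seed()]).
#' @param params a [synapse_params()] or list of two.
#' @param w_init initial weights (V); default resting weight for both.
#' @param neuron a [stein_params()].
#' @param sample_dt_s weight sampling interval (s).
#' @return An `fg_trace` with synapses `w1`, `w2`.
#' @export
#' @examples
#' tr <- protocol_unsupervised(duration_s = 20, seed = 1)
protocol_unsupervised <- function(rates_hz = c(5, 5), duration_s = 150,
                                  seed = 1, params = synapse_params(),
                                  w_init = NULL,
                                  neuron = stein_params(),
                                  sample_dt_s = 0.5) {
  if (length(rates_hz) == 1L) rates_hz <- rep(rates_hz, 2)
  if (any(rates_hz <= 0)) stop("`rates_hz` must be > 0", call. = FALSE)
  pp <- .two_params(params)
  if (is.null(w_init)) w_init <- c(pp[[1]]$w_rest, pp[[2]]$w_rest)
  trains <- lapply(1:2, function(i) {
    poisson_train(rates_hz[i], duration_s, seed = derive_seed(seed, i),
                  source_id = paste0("N", i))
  })
  net <- .feedforward_net(trains, pp, w_init, neuron)
  run_network(net, duration_s, sample_dt_s)
}

#' Alternating-input competition (binned 20 Hz activity)
#'
#' In every time bin exactly one of the two sources is active at
#' `rate_hz`; the active source is chosen uniformly at random per bin.
#'
#' @param rate_hz in-bin firing rate (Hz).
#' @param bin_width_s bin width (s, default 0.2).
#' @inheritParams protocol_unsupervised
#' @return An `fg_trace` with synapses `w1`, `w2`.
#' @export
protocol_alternating <- function(rate_hz = 20, bin_width_s = 0.2,
                                 duration_s = 150, seed = 1,
                                 params = synapse_params(), w_init = NULL,
                                 neuron = stein_params(),
                                 sample_dt_s = 0.5) {
  pp <- .two_params(params)
  if (is.null(w_init)) w_init <- c(pp[[1]]$w_rest, pp[[2]]$w_rest)
  alt <- binned_alternating_trains(rate_hz, bin_width_s, duration_s,
                                   n_sources = 2,
                                   seed = derive_seed(seed, 1))
  net <- .feedforward_net(alt$trains, pp, w_init, neuron)
  run_network(net, duration_s, sample_dt_s)
}

#' Supervised competition with a bias neuron
#'
#' As [protocol_alternating()], plus a bias source `Nsup` holding a fixed
#' (non-plastic) synaptic weight that emits Poisson spikes only during the
#' bins in which the synced source is active. The bias raises the membrane
#' during those bins, so the synced pathway collects the causal credit and
#' reliably wins the competition.
#'
#' @param sup_rate_hz bias firing rate during synced bins (Hz, default 50).
#' @param sup_weight_V fixed bias synaptic weight (V, default 0.05).
#' @param synced_source which input (1 or 2) the bias is in sync with.
#' @inheritParams protocol_alternating
#' @return An `fg_trace` with synapses `w1`, `w2`, `wsup`.
#' @export
protocol_supervised <- function(rate_hz = 20, bin_width_s = 0.2,
                                sup_rate_hz = 50, sup_weight_V = 0.05,
                                synced_source = 1, duration_s = 100,
                                seed = 1, params = synapse_params(),
                                w_init = NULL, neuron = stein_params(),
                                sample_dt_s = 0.5) {
  if (!synced_source %in% c(1, 2)) {
    stop("`synced_source` must be 1 or 2", call. = FALSE)
  }
  .check_number(sup_weight_V, "sup_weight_V", nonneg = TRUE)
  pp <- .two_params(params)
  if (is.null(w_init)) w_init <- c(pp[[1]]$w_rest, pp[[2]]$w_rest)
  alt <- binned_alternating_trains(rate_hz, bin_width_s, duration_s,
                                   n_sources = 2,
                                   seed = derive_seed(seed, 1))
  sup_all <- poisson_train(sup_rate_hz, duration_s,
                           seed = derive_seed(seed, 2), source_id = "Nsup")
  bin_of <- pmin(floor(sup_all$times / bin_width_s) + 1, length(alt$active))
  keep <- alt$active[bin_of] == synced_source
  sup <- spike_train(sup_all$times[keep], "Nsup")
  net <- .feedforward_net(alt$trains, pp, w_init, neuron,
                          bias_train = sup, bias_weight = sup_weight_V)
  run_network(net, duration_s, sample_dt_s)
}
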