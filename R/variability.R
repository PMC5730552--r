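# MOSFET mismatch models and Monte-Carlo propagation to synapse behavior.
#
# Random dopant fluctuation (RDF) perturbs each device's threshold voltage
# with the Pelgrom standard deviation A_RDF / sqrt(L W); line-edge
# roughness (LER) perturbs the channel length with standard deviation
# A_LER / sqrt(W). The behavioral mapping is first-order: a device's Vth
# deviation scales its per-spike increment and sampling threshold
# proportionally (1% per mV by default), its length deviation scales the
# associated time constant (or injection gain) by the relative length
# change, and storage-device Vth deviations shift the resting storage
# level, hence the initial weight.

#' MOSFET channel geometry
#'
#' @param l_nm channel length in nm.
#' @param w_nm channel width in nm.
#' @return An object of class `mosfet_geometry`.
#' @export
mosfet_geometry <- function(l_nm, w_nm) {
  .check_number(l_nm, "l_nm", positive = TRUE)
  .check_number(w_nm, "w_nm", positive = TRUE)
  structure(list(l_nm = l_nm, w_nm = w_nm), class = "mosfet_geometry")
}

#' Pelgrom threshold-voltage mismatch
#'
#' `sigma_Vt = A_RDF / sqrt(L * W)` in volts (SI).
#'
#' @param geom a [mosfet_geometry()] (or channel length in nm, with
#'   `w_nm` supplied).
#' @param a_rdf Pelgrom coefficient in V*m (default 1.27e-9).
#' @param w_nm channel width in nm when `geom` is given as a length.
#' @return Standard deviation of Vth in volts.
#' @export
#' @examples
#' sigma_vth(mosfet_geometry(60, 120)) * 1e3 # ~15 mV
sigma_vth <- function(geom, a_rdf = 1.27e-9, w_nm = NULL) {
  if (!inherits(geom, "mosfet_geometry")) {
    geom <- mosfet_geometry(geom, w_nm)
  }
  .check_number(a_rdf, "a_rdf", nonneg = TRUE)
  a_rdf / sqrt(geom$l_nm * 1e-9 * geom$w_nm * 1e-9)
}

#' Line-edge-roughness channel-length variation
#'
#' `sigma_L = A_LER / sqrt(W)`, reported in nm.
#'
#' @param w_nm channel width in nm.
#' @param a_ler LER coefficient in m^(3/2) (default 1.04e-12).
#' @return Standard deviation of channel length in nm.
#' @export
#' @examples
#' sigma_length(120) # ~3 nm
sigma_length <- function(w_nm, a_ler = 1.04e-12) {
  .check_number(w_nm, "w_nm", positive = TRUE)
  .check_number(a_ler, "a_ler", nonneg = TRUE)
  a_ler / sqrt(w_nm * 1e-9) * 1e9
}

#' Default device-role geometry table
#'
#' Channel geometries of the devices whose mismatch reaches the behavioral
#' parameters: the two state-variable integrators (60 x 120 nm), the LTD
#' and LTP injection junctions (60 x 120 and 120 x 240 nm) and the storage
#' output device (90 x 1400 nm).
#'
#' @return data.frame with columns `role`, `l_nm`, `w_nm`.
#' @export
default_geometry <- function() {
  data.frame(
    role = c("pre_integrator", "post_integrator", "ltd_junction",
             "ltp_junction", "storage"),
    l_nm = c(60, 60, 60, 120, 90),
    w_nm = c(120, 120, 120, 240, 1400)
  )
}

#' Variability model parameters
#'
#' @param a_rdf Pelgrom coefficient (V*m, default 1.27e-9).
#' @param a_ler LER coefficient (m^(3/2), default 1.04e-12).
#' @param vth_frac_per_mV relative shift of a device's behavioral
#'   parameters per mV of Vth deviation (default 0.01).
#' @param geometry device-role table, see [default_geometry()].
#' @return An object of class `variability_params`.
#' @export
variability_params <- function(a_rdf = 1.27e-9, a_ler = 1.04e-12,
                               vth_frac_per_mV = 0.01,
                               geometry = default_geometry()) {
  .check_number(a_rdf, "a_rdf", nonneg = TRUE)
  .check_number(a_ler, "a_ler", nonneg = TRUE)
  .check_number(vth_frac_per_mV, "vth_frac_per_mV", nonneg = TRUE)
  stopifnot(is.data.frame(geometry),
            all(c("role", "l_nm", "w_nm") %in% names(geometry)))
  need <- c("pre_integrator", "post_integrator", "ltd_junction",
            "ltp_junction", "storage")
  if (!all(need %in% geometry$role)) {
    stop("`geometry` must cover roles: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(a_rdf = a_rdf, a_ler = a_ler,
                 vth_frac_per_mV = vth_frac_per_mV, geometry = geometry),
            class = "variability_params")
}

#' Draw one mismatched synaptic circuit
#'
#' Samples per-device Vth and channel-length deviations from their
#' zero-mean normals and perturbs the behavioral parameters accordingly.
#' Draws violating the parameter invariants are rejected and resampled.
#'
#' @param params nominal [synapse_params()].
#' @param var a [variability_params()].
#' @param seed optional integer seed (own sub-stream).
#' @return A perturbed [synapse_params()].
#' @export
#' @examples
#' sample_circuit(synapse_params(), variability_params(), seed = 1)
sample_circuit <- function(params, var = variability_params(),
                           seed = NULL) {
  stopifnot(inherits(params, "synapse_params"),
            inherits(var, "variability_params"))
  draw <- function() {
    g <- var$geometry
    row <- function(role) g[g$role == role, ]
    dvth <- function(role) {
      r <- row(role)
      stats::rnorm(1, 0, sigma_vth(mosfet_geometry(r$l_nm, r$w_nm),
                                   var$a_rdf))
    }
    dlen_rel <- function(role) {
      r <- row(role)
      stats::rnorm(1, 0, sigma_length(r$w_nm, var$a_ler)) / r$l_nm
    }
    k <- var$vth_frac_per_mV * 1e3 # per volt
    f_pre <- 1 + k * dvth("pre_integrator")
    f_post <- 1 + k * dvth("post_integrator")
    f_ltd <- 1 + k * dvth("ltd_junction")
    f_ltp <- 1 + k * dvth("ltp_junction")
    d_storage <- dvth("storage")
    w_rest_new <- params$vtc_vmax /
      (1 + exp((params$m_rest + d_storage - params$vtc_mid) /
                 params$vtc_slope))
    synapse_params(
      dv_pre_mV = params$dv_pre * 1e3 * f_pre,
      dv_post_mV = params$dv_post * 1e3 * f_post,
      tau_pre_ms = params$tau_pre * 1e3 * (1 + dlen_rel("pre_integrator")),
      tau_post_ms = params$tau_post * 1e3 *
        (1 + dlen_rel("post_integrator")),
      gain_pre = params$gain_pre, gain_post = params$gain_post,
      theta_pre_V = params$theta_pre * f_ltp,
      theta_post_V = params$theta_post * f_ltd,
      c_plus = params$c_plus * (1 + dlen_rel("ltp_junction")),
      c_minus = params$c_minus * (1 + dlen_rel("ltd_junction")),
      lambda_plus = params$lambda_plus,
      lambda_minus = params$lambda_minus,
      vtc_vmax_V = params$vtc_vmax, vtc_slope_V = params$vtc_slope,
      w_rest_V = w_rest_new, pairing_mode = params$pairing_mode)
  }
  run_draw <- function() {
    for (i in 1:100) {
      out <- tryCatch(draw(), error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
    stop("could not draw a valid circuit in 100 attempts", call. = FALSE)
  }
  if (!is.null(seed)) {
    local({
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      run_draw()
    })
  } else {
    run_draw()
  }
}

#' Monte-Carlo ensemble over mismatched circuits
#'
#' `experiment = "stdp"`: per-circuit single-pair STDP curves plus the
#' distribution of initial (resting) weights with a normal fit.
#' `experiment = "supervised"`: per-circuit-pair supervised competition
#' (bias synced to input 2) with terminal weights at `duration_s`.
#'
#' @param n_circuits ensemble size (>= 2; 200 in the reference study).
#' @param experiment `"stdp"` or `"supervised"`.
#' @param seed master seed.
#' @param params nominal [synapse_params()].
#' @param var a [variability_params()].
#' @param dt_ms STDP-curve grid (ms) for the stdp experiment.
#' @param duration_s duration of the supervised runs (s, default 100).
#' @param synced_source bias sync target for the supervised runs.
#' @param sup_rate_hz bias firing rate for the supervised runs (Hz,
#'   default 80, the rate of the steering experiment being ensembled).
#' @return list; for `"stdp"`: `curves` (long data.frame `circuit`,
#'   `dt_ms`, `dvw_V`), `w0_V`, `w0_fit` (mean, sd, Shapiro-Wilk p),
#'   `sign_ok_frac`. For `"supervised"`: `terminal` (data.frame `circuit`,
#'   `w1_V`, `w2_V`), `p_synced_wins`, `binom_p`.
#' @export
#' @examples
#' mc <- run_mc(10, "stdp", seed = 1)
#' mc$sign_ok_frac
run_mc <- function(n_circuits = 200,
                   experiment = c("stdp", "supervised"), seed = 1,
                   params = synapse_params(), var = variability_params(),
                   dt_ms = .default_dt_grid(), duration_s = 100,
                   synced_source = 2, sup_rate_hz = 80) {
  experiment <- match.arg(experiment)
  .check_number(n_circuits, "n_circuits")
  if (n_circuits < 2) stop("`n_circuits` must be >= 2", call. = FALSE)

  if (experiment == "stdp") {
    curves <- vector("list", n_circuits)
    w0 <- numeric(n_circuits)
    sign_ok <- logical(n_circuits)
    for (i in seq_len(n_circuits)) {
      ci <- sample_circuit(params, var, seed = derive_seed(seed, i))
      cu <- stdp_curve(ci, dt_ms = dt_ms)
      cu$circuit <- i
      curves[[i]] <- cu
      w0[i] <- ci$w_rest
      pos <- cu$dvw_V[cu$dt_ms > 0]
      neg <- cu$dvw_V[cu$dt_ms < 0]
      sign_ok[i] <- pos[which.min(cu$dt_ms[cu$dt_ms > 0])] > 0 &&
        neg[which.max(cu$dt_ms[cu$dt_ms < 0])] < 0
    }
    sw <- stats::shapiro.test(w0)
    list(
      curves = do.call(rbind, curves),
      w0_V = w0,
      w0_fit = list(mean = mean(w0), sd = stats::sd(w0),
                    shapiro_p = sw$p.value),
      sign_ok_frac = mean(sign_ok)
    )
  } else {
    w1 <- numeric(n_circuits); w2 <- numeric(n_circuits)
    for (i in seq_len(n_circuits)) {
      c1 <- sample_circuit(params, var, seed = derive_seed(seed, 2 * i))
      c2 <- sample_circuit(params, var, seed = derive_seed(seed, 2 * i + 1))
      tr <- protocol_supervised(synced_source = synced_source,
                                duration_s = duration_s,
                                sup_rate_hz = sup_rate_hz,
                                seed = derive_seed(seed, 40000 + i),
                                params = list(c1, c2))
      w1[i] <- tr$terminal[["w1"]]
      w2[i] <- tr$terminal[["w2"]]
    }
    synced_w <- if (synced_source == 2) w2 > w1 else w1 > w2
    bt <- stats::binom.test(sum(synced_w), n_circuits, 0.5,
                            alternative = "greater")
    list(
      terminal = data.frame(circuit = seq_len(n_circuits),
                            w1_V = w1, w2_V = w2),
      p_synced_wins = mean(synced_w),
      binom_p = bt$p.value
    )
  }
}
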