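# Statistical estimation of the weight-plane vector field.
#
# At every (w1, w2) grid node the two plastic synapses are initialized at
# the node weights and the chosen protocol is run for a short horizon with
# fresh, independently seeded inputs; the per-replicate weight drift
# (w(t + horizon) - w(t)) / horizon is averaged into the field vector, with
# the standard error of the mean across replicates.

#' Estimate the weight-plane vector field of a competition protocol
#'
#' @param protocol `"compete"` ([protocol_unsupervised()]), `"alternate"`
#'   ([protocol_alternating()]) or `"supervise"` ([protocol_supervised()]).
#' @param grid either a single integer (n x n interior nodes over
#'   `[0.02, 0.48]` V, default 15) or a numeric vector of node weights in
#'   volts, strictly inside `(0, vtc_vmax)`.
#' @param horizon_s evaluation horizon per replicate (s, default 2).
#' @param replicates independent replicates per node (default 10).
#' @param seed master seed; each (node, replicate) gets its own sub-stream.
#' @param params a [synapse_params()] or list of two.
#' @param neuron a [stein_params()].
#' @param ... protocol arguments forwarded (e.g. `rates_hz`, `rate_hz`,
#'   `sup_rate_hz`, `synced_source`).
#' @return data.frame of class `fg_field` with columns `w1_V`, `w2_V`,
#'   `dw1_dt`, `dw2_dt`, `se1`, `se2`, `n`.
#' @export
#' @examples
#' f <- vector_field(grid = c(0.1, 0.3), replicates = 3, seed = 1)
vector_field <- function(protocol = c("compete", "alternate", "supervise"),
                         grid = 15, horizon_s = 2, replicates = 10,
                         seed = 1, params = synapse_params(),
                         neuron = stein_params(), ...) {
  protocol <- match.arg(protocol)
  .check_number(horizon_s, "horizon_s", positive = TRUE)
  .check_number(replicates, "replicates")
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  pp <- .two_params(params)
  vmax <- pp[[1]]$vtc_vmax
  if (length(grid) == 1L && grid == round(grid) && grid > 1) {
    wv <- seq(0.02, 0.48, length.out = grid)
  } else {
    wv <- as.numeric(grid)
  }
  if (any(wv <= 0) || any(wv >= vmax)) {
    stop("grid nodes must lie strictly inside (0, vtc_vmax): the VTC poles are unreachable",
         call. = FALSE)
  }
  runner <- switch(protocol,
    compete = function(w0, sd) {
      protocol_unsupervised(duration_s = horizon_s, seed = sd, params = pp,
                            w_init = w0, neuron = neuron,
                            sample_dt_s = horizon_s, ...)
    },
    alternate = function(w0, sd) {
      protocol_alternating(duration_s = horizon_s, seed = sd, params = pp,
                           w_init = w0, neuron = neuron,
                           sample_dt_s = horizon_s, ...)
    },
    supervise = function(w0, sd) {
      protocol_supervised(duration_s = horizon_s, seed = sd, params = pp,
                          w_init = w0, neuron = neuron,
                          sample_dt_s = horizon_s, ...)
    })
  nodes <- expand.grid(w1_V = wv, w2_V = wv, KEEP.OUT.ATTRS = FALSE)
  res <- matrix(0, nrow(nodes), 4)
  for (i in seq_len(nrow(nodes))) {
    d1 <- numeric(replicates); d2 <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sd_ir <- derive_seed(seed, (i - 1L) * replicates + r)
      tr <- runner(c(nodes$w1_V[i], nodes$w2_V[i]), sd_ir)
      d1[r] <- (tr$terminal[["w1"]] - nodes$w1_V[i]) / horizon_s
      d2[r] <- (tr$terminal[["w2"]] - nodes$w2_V[i]) / horizon_s
    }
    se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    res[i, ] <- c(mean(d1), mean(d2), se(d1), se(d2))
  }
  out <- cbind(nodes,
               data.frame(dw1_dt = res[, 1], dw2_dt = res[, 2],
                          se1 = res[, 3], se2 = res[, 4],
                          n = replicates))
  class(out) <- c("fg_field", "data.frame")
  out
}

# bilinear interpolation of the field (and its standard errors) at (x, y);
# returns NA outside the grid hull
.field_interp <- function(field, x, y) {
  wx <- sort(unique(field$w1_V)); wy <- sort(unique(field$w2_V))
  if (x < wx[1] || x > wx[length(wx)] || y < wy[1] || y > wy[length(wy)]) {
    return(rep(NA_real_, 4))
  }
  ix <- findInterval(x, wx, rightmost.closed = TRUE)
  iy <- findInterval(y, wy, rightmost.closed = TRUE)
  ix <- min(max(ix, 1L), length(wx) - 1L)
  iy <- min(max(iy, 1L), length(wy) - 1L)
  fx <- (x - wx[ix]) / (wx[ix + 1] - wx[ix])
  fy <- (y - wy[iy]) / (wy[iy + 1] - wy[iy])
  pick <- function(i, j) {
    row <- field[field$w1_V == wx[i] & field$w2_V == wy[j], ]
    c(row$dw1_dt[1], row$dw2_dt[1], row$se1[1], row$se2[1])
  }
  v00 <- pick(ix, iy); v10 <- pick(ix + 1, iy)
  v01 <- pick(ix, iy + 1); v11 <- pick(ix + 1, iy + 1)
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Compare weight trajectories against a vector field
#'
#' Along each trajectory the empirical displacement direction between
#' consecutive samples is compared with the interpolated field direction at
#' the segment start; the report gives the mean angular deviation over
#' segments where the field magnitude exceeds three times its (interpolated)
#' standard error. Segments leaving the grid hull are flagged and excluded.
#'
#' @param field an `fg_field` from [vector_field()].
#' @param traces a single `fg_trace` or list of them (same protocol as the
#'   field for a meaningful comparison).
#' @return data.frame with one row per trajectory: `mean_angle_deg`,
#'   `n_segments`, `n_excluded_weak`, `n_excluded_hull`.
#' @export
overlay_trajectories <- function(field, traces) {
  stopifnot(inherits(field, "fg_field"))
  if (inherits(traces, "fg_trace")) traces <- list(traces)
  out <- lapply(seq_along(traces), function(j) {
    tr <- traces[[j]]
    stopifnot(inherits(tr, "fg_trace"))
    W <- tr$weights[, c("w1", "w2"), drop = FALSE]
    n_seg <- nrow(W) - 1L
    ang <- numeric(0); weak <- 0L; hull <- 0L
    for (i in seq_len(n_seg)) {
      d <- W[i + 1L, ] - W[i, ]
      if (sqrt(sum(d^2)) == 0) next
      v <- .field_interp(field, W[i, 1], W[i, 2])
      if (any(is.na(v))) { hull <- hull + 1L; next }
      vmagn <- sqrt(v[1]^2 + v[2]^2)
      semagn <- sqrt(v[3]^2 + v[4]^2)
      if (vmagn <= 3 * semagn || vmagn == 0) { weak <- weak + 1L; next }
      cosang <- sum(d * v[1:2]) / (sqrt(sum(d^2)) * vmagn)
      ang <- c(ang, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
    }
    data.frame(trajectory = j,
               mean_angle_deg = if (length(ang)) mean(ang) else NA_real_,
               n_segments = length(ang), n_excluded_weak = weak,
               n_excluded_hull = hull)
  })
  do.call(rbind, out)
}
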