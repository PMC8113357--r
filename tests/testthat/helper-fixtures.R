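# shared fixture builders; everything is generated in code

# default 20-kHz protocol with a short current ladder so AP template
# breakpoints (0.05-ms grid) land on samples and tests stay fast
test_protocol <- function(steps = seq(-200, 300, by = 20), rate = 20000) {
  stimulus_protocol(current_steps_pA = steps, sample_rate_hz = rate)
}

# grid-aligned AP shape: t_up = 0.25 ms, t_dn = 2.1 ms at 20 kHz
test_ap_shape <- function(...) {
  args <- list(threshold_mV = -40, amplitude_mV = 50, upstroke_Vps = 200,
               halfwidth_ms = 1, ahp_mV = 10)
  args[names(list(...))] <- list(...)
  do.call(ap_template, args)
}

# a regular spiking cell: one spike more per 20 pA above 100 pA
test_spiking_spec <- function(noise = 0, ...) {
  spikes <- list(`120` = 0.15,
                 `140` = c(0.15, 0.3),
                 `160` = c(0.15, 0.25, 0.4),
                 `180` = c(0.15, 0.22, 0.3, 0.4),
                 `200` = c(0.15, 0.2, 0.26, 0.33, 0.41))
  args <- list(resting_potential_mV = -70, input_resistance_MOhm = 50,
               membrane_tau_ms = 20, spike_times_s = spikes,
               ap_shape = test_ap_shape(), noise_sd_mV = noise, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(trace_spec, args)
}

# hand-built constant-voltage sweep
flat_sweep <- function(v = -70, current = -100, rate = 20000,
                       proto = test_protocol()) {
  n <- round(proto$sweep_duration_s * rate)
  list(voltage_mV = rep(v, n), current_pA = current, repeat_index = 1L,
       sample_period_s = 1 / rate)
}

# hand-built square-response sweep: rest before onset / after offset,
# `level` during the stimulus, with optional extra piecewise overrides
square_sweep <- function(rest = -70, level = -80, current = -100,
                         proto = test_protocol(), rate = 20000) {
  dt <- 1 / rate
  t <- seq(0, proto$sweep_duration_s - dt, by = dt)
  v <- rep(rest, length(t))
  v[t >= proto$onset_s & t < proto$offset_s] <- level
  list(voltage_mV = v, t = t, current_pA = current, repeat_index = 1L,
       sample_period_s = dt)
}

# unbranched straight neurite of a given length along z
line_morphology <- function(length_um = 100, type = 3, thickness = 1000,
                            soma_depth = 0.5, step = 1) {
  n <- round(length_um / step)
  soma_z <- soma_depth * thickness
  nodes <- data.frame(
    id = seq_len(n + 1), type = c(1L, rep(type, n)),
    x = 0, y = 0, z = c(soma_z, soma_z + seq_len(n) * step),
    radius = c(6, rep(0.5, n)),
    parent = c(-1L, seq_len(n)))
  structure(list(nodes = nodes, cortical_thickness_um = thickness,
                 soma_depth_normalized = soma_depth, soma_id = 1L),
            class = "morphology")
}

# independent per-point binning oracle for z-profiles
zprofile_oracle <- function(morph, compartment, nbins = 20) {
  pts <- patchseqr:::compartment_points(morph, compartment)
  counts <- numeric(nbins)
  for (i in seq_len(nrow(pts))) {
    d <- pts[i, 3] / morph$cortical_thickness_um
    d <- min(max(d, 0), 1)
    b <- min(floor(d * nbins) + 1, nbins)
    counts[b] <- counts[b] + 1
  }
  counts / sum(counts)
}

# brute-force oracle for variable-gene selection: sweep the offset over
# each gene's critical value and report the achievable count closest to
# the target
select_genes_oracle <- function(counts, target_n, c_min = 32,
                                min_cells = 10, slope = -1.5,
                                margin = 0.002) {
  eligible <- rowSums(counts >= c_min) >= min_cells
  cm <- counts[eligible, , drop = FALSE]
  above <- cm > c_min
  mu <- rowSums(log2(pmax(cm, 1)) * above) / pmax(rowSums(above), 1)
  tau <- rowMeans(cm <= c_min)
  ok <- rowSums(above) > 0
  mu <- mu[ok]; tau <- tau[ok]
  # gene g is selected iff b < log(tau_g - margin) + (-slope) * mu_g
  crit <- rep(-Inf, length(tau))
  sel <- tau > margin
  crit[sel] <- log(tau[sel] - margin) - slope * mu[sel]
  counts_at <- vapply(sort(unique(crit)), function(b0)
    sum(crit > b0 - 1e-12), integer(1))
  counts_at <- c(counts_at, sum(is.finite(crit)))
  best <- counts_at[which.min(abs(counts_at - target_n))]
  names(mu)[rank(-crit, ties.method = "first") <= best]
}

# small standardized X, Y with a planted sparse low-rank relationship
planted_rrr_data <- function(n = 200, p = 80, q = 17, r = 3,
                             support = 1:10, snr = 2, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n))
  W <- matrix(0, p, r)
  W[support, ] <- rnorm(length(support) * r)
  V <- qr.Q(qr(matrix(rnorm(q * r), q)))
  signal <- X %*% W %*% t(V)
  noise <- matrix(rnorm(n * q), n) * sqrt(mean(signal^2) / snr)
  Y <- scale(signal + noise)
  colnames(X) <- paste0("g", seq_len(p))
  colnames(Y) <- paste0("f", seq_len(q))
  list(X = X, Y = Y, W = W, V = V, support = support)
}
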