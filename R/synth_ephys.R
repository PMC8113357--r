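#' Action-potential waveform template
#'
#' Piecewise-analytic AP shape used by the trace generator: a slow
#' pre-ramp up to threshold, a linear upstroke at `upstroke_Vps`, a linear
#' downstroke through the fast trough (threshold - `ahp_mV`), an optional
#' afterdepolarization bump, and an exponential relaxation back to the
#' baseline. With a linear upstroke and downstroke the half-width is a
#' deterministic function of amplitude and the two slopes, so exactly one
#' of `halfwidth_ms` / `downstroke_Vps` may be chosen freely: if
#' `halfwidth_ms` is supplied the downstroke slope is derived from it,
#' otherwise the half-width is derived from `downstroke_Vps`.
#'
#' @param threshold_mV AP threshold voltage.
#' @param amplitude_mV Peak voltage minus threshold voltage (> 0).
#' @param upstroke_Vps Maximal rise slope, V/s (> 0).
#' @param halfwidth_ms Width at half height, ms (optional, see above).
#' @param downstroke_Vps Fall slope, V/s, negative (optional, see above).
#' @param ahp_mV Afterhyperpolarization depth: threshold minus fast-trough
#'   voltage (> 0).
#' @param adp_mV Afterdepolarization bump height above the fast trough
#'   (>= 0; 0 disables the bump).
#' @return A list of class `ap_template` with all shape parameters made
#'   mutually consistent, including the derived `udr`
#'   (upstroke/|downstroke| ratio).
#' @export
ap_template <- function(threshold_mV = -42, amplitude_mV = 55,
                        upstroke_Vps = 250, halfwidth_ms = NULL,
                        downstroke_Vps = NULL, ahp_mV = 12, adp_mV = 0) {
  stopifnot_scalar(amplitude_mV, "amplitude_mV", positive = TRUE)
  stopifnot_scalar(upstroke_Vps, "upstroke_Vps", positive = TRUE)
  stopifnot_scalar(ahp_mV, "ahp_mV", positive = TRUE)
  stopifnot_scalar(adp_mV, "adp_mV", nonneg = TRUE)
  half <- amplitude_mV / 2
  t_up_half <- half / upstroke_Vps          # ms (mV / (mV/ms))
  if (!is.null(halfwidth_ms)) {
    stopifnot_scalar(halfwidth_ms, "halfwidth_ms", positive = TRUE)
    t_dn_half <- halfwidth_ms - t_up_half
    if (t_dn_half <= 0)
      stop("halfwidth_ms too small for the given upstroke", call. = FALSE)
    downstroke_Vps <- -half / t_dn_half
  } else {
    downstroke_Vps <- downstroke_Vps %||% -100
    if (downstroke_Vps >= 0)
      stop("downstroke_Vps must be negative", call. = FALSE)
    halfwidth_ms <- t_up_half + half / abs(downstroke_Vps)
  }
  structure(list(
    threshold_mV = threshold_mV, amplitude_mV = amplitude_mV,
    peak_mV = threshold_mV + amplitude_mV,
    upstroke_Vps = upstroke_Vps, downstroke_Vps = downstroke_Vps,
    halfwidth_ms = halfwidth_ms, ahp_mV = ahp_mV, adp_mV = adp_mV,
    udr = upstroke_Vps / abs(downstroke_Vps)
  ), class = "ap_template")
}

#' Ground-truth specification of one cell's current-clamp responses
#'
#' Holds the passive parameters, sag/rebound amplitudes, planted spike
#' times per current step and the AP shape from which
#' [generate_sweep_set()] synthesizes voltage traces.
#'
#' @param resting_potential_mV Resting membrane potential.
#' @param input_resistance_MOhm Input resistance (> 0).
#' @param membrane_tau_ms Membrane time constant in ms (> 0).
#' @param sag_amplitude_mV Depth of the sag excursion below the steady
#'   state on the most hyperpolarizing step (>= 0; scaled linearly with
#'   current on the other hyperpolarizing steps).
#' @param sag_tau_ms Time-to-trough of the sag alpha-function.
#' @param rebound_mV Post-offset rebound plateau above rest on the most
#'   hyperpolarizing step (>= 0).
#' @param spike_times_s Named list mapping current step (as character pA
#'   value) to a numeric vector of planted spike (threshold-crossing)
#'   times in seconds from sweep start.
#' @param ap_shape An [ap_template()].
#' @param noise_sd_mV Gaussian noise sd added to every sample (>= 0).
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(resting_potential_mV = -70,
                       input_resistance_MOhm = 150,
                       membrane_tau_ms = 15,
                       sag_amplitude_mV = 0, sag_tau_ms = 40,
                       rebound_mV = 0,
                       spike_times_s = list(),
                       ap_shape = ap_template(),
                       noise_sd_mV = 0, seed = 1L) {
  stopifnot_scalar(input_resistance_MOhm, "input_resistance_MOhm",
                   positive = TRUE)
  stopifnot_scalar(membrane_tau_ms, "membrane_tau_ms", positive = TRUE)
  stopifnot_scalar(sag_amplitude_mV, "sag_amplitude_mV", nonneg = TRUE)
  stopifnot_scalar(rebound_mV, "rebound_mV", nonneg = TRUE)
  stopifnot_scalar(noise_sd_mV, "noise_sd_mV", nonneg = TRUE)
  stopifnot(inherits(ap_shape, "ap_template"))
  structure(list(
    resting_potential_mV = resting_potential_mV,
    input_resistance_MOhm = input_resistance_MOhm,
    membrane_tau_ms = membrane_tau_ms,
    sag_amplitude_mV = sag_amplitude_mV, sag_tau_ms = sag_tau_ms,
    rebound_mV = rebound_mV,
    spike_times_s = spike_times_s,
    ap_shape = ap_shape,
    noise_sd_mV = noise_sd_mV, seed = as.integer(seed)
  ), class = "trace_spec")
}

# passive + sag + rebound baseline (no APs, no noise) for one current step
passive_trace <- function(spec, protocol, current_pA) {
  dt <- 1 / protocol$sample_rate_hz
  t <- seq(0, protocol$sweep_duration_s - dt, by = dt)
  v0 <- spec$resting_potential_mV
  tau <- spec$membrane_tau_ms / 1000
  dV <- current_pA * spec$input_resistance_MOhm * 1e-3   # pA * MOhm -> mV
  v <- rep(v0, length(t))
  stim <- t >= protocol$onset_s & t < protocol$offset_s
  ts <- t[stim] - protocol$onset_s
  v[stim] <- v0 + dV * (1 - exp(-ts / tau))

  hyper <- current_pA < 0
  steps <- protocol$current_steps_pA
  imin <- min(steps)
  sag_scale <- if (hyper && imin < 0) current_pA / imin else 0
  if (hyper && sag_scale > 0 && spec$sag_amplitude_mV > 0) {
    taus <- spec$sag_tau_ms / 1000
    # alpha function peaking at 1 at t = taus
    v[stim] <- v[stim] - spec$sag_amplitude_mV * sag_scale *
      (ts / taus) * exp(1 - ts / taus)
  }

  post <- t >= protocol$offset_s
  tp <- t[post] - protocol$offset_s
  v_off <- if (any(stim)) v[max(which(stim))] else v0
  reb <- if (hyper) spec$rebound_mV * sag_scale else 0
  # exponential relaxation from v_off to (v0 + reb)
  v[post] <- (v0 + reb) + (v_off - v0 - reb) * exp(-tp / tau)
  list(t = t, v = v, dt = dt)
}

# insert the AP template into baseline voltage v at threshold times (s).
# Between spikes the trace relaxes to a plateau one mV above the fast
# trough (never below it, so AHP and direct/detour ISI classification
# see the planted shape), holds it for `hold_ms`, then decays back to
# the passive baseline.
insert_aps <- function(v, t, dt, shape, spike_times_s,
                       hold_ms = 100, decay_tau_ms = 20) {
  baseline <- v
  trough <- shape$threshold_mV - shape$ahp_mV
  t_up <- shape$amplitude_mV / shape$upstroke_Vps            # ms
  t_dn <- (shape$amplitude_mV + shape$ahp_mV) / abs(shape$downstroke_Vps)
  adp_rise <- 2; adp_tau <- 10; relax_tau <- 5
  n <- length(v)
  spike_times_s <- sort(spike_times_s)
  i0s <- vapply(spike_times_s, function(ts) which.min(abs(t - ts)),
                integer(1))
  for (j in seq_along(spike_times_s)) {
    i0 <- i0s[j]
    # pre-ramp up to threshold, slope capped below the detection criterion
    v_start <- v[max(1L, i0 - 1L)]
    ramp_ms <- max(1, (shape$threshold_mV - v_start) / 15)
    ir <- max(1L, i0 - round(ramp_ms / 1000 / dt)):max(1L, i0 - 1L)
    if (length(ir) && i0 > 1)
      v[ir] <- v_start + (shape$threshold_mV - v_start) *
        seq_along(ir) / length(ir)
    v_inter <- max(baseline[i0], trough + 1)
    i_end <- if (j < length(spike_times_s)) i0s[j + 1L] - 1L else n
    idx <- i0:min(n, i_end)
    rel <- (t[idx] - t[i0]) * 1000    # ms since threshold
    t_adp_end <- t_up + t_dn + if (shape$adp_mV > 0) adp_rise else 0
    t_hold_end <- t_adp_end + hold_ms
    w <- numeric(length(idx))
    up <- rel <= t_up
    w[up] <- shape$threshold_mV + shape$upstroke_Vps * rel[up]
    dn <- rel > t_up & rel <= t_up + t_dn
    w[dn] <- shape$peak_mV + shape$downstroke_Vps * (rel[dn] - t_up)
    if (shape$adp_mV > 0) {
      ad <- rel > t_up + t_dn & rel <= t_adp_end
      w[ad] <- trough + shape$adp_mV * (rel[ad] - t_up - t_dn) / adp_rise
      rx <- rel > t_adp_end & rel <= t_hold_end
      w[rx] <- v_inter + (trough + shape$adp_mV - v_inter) *
        exp(-(rel[rx] - t_adp_end) / adp_tau)
    } else {
      rx <- rel > t_adp_end & rel <= t_hold_end
      w[rx] <- v_inter + (trough - v_inter) *
        exp(-(rel[rx] - t_adp_end) / relax_tau)
    }
    tail_i <- rel > t_hold_end
    w[tail_i] <- baseline[idx[tail_i]] +
      (v_inter - baseline[idx[tail_i]]) *
      exp(-(rel[tail_i] - t_hold_end) / decay_tau_ms)
    v[idx] <- w
  }
  v
}

#' Generate a synthetic current-clamp sweep set
#'
#' Synthesizes, for every current step of the protocol, a voltage trace
#' composed of a passive charging response (single exponential with the
#' planted membrane time constant), a sag excursion and post-offset
#' rebound on hyperpolarizing steps, stereotyped AP waveforms inserted at
#' the planted spike times, and additive Gaussian noise. The planted
#' ground truth is retained in the returned object so downstream feature
#' extraction can be scored against it.
#'
#' @param spec A [trace_spec()].
#' @param protocol A [stimulus_protocol()].
#' @param n_repeats Number of identical-stimulus repeats per current step.
#' @return A [sweep_set()] whose `ground_truth` element carries the spec
#'   plus derived true values (steady-state voltages, sag ratio, rebound).
#' @export
generate_sweep_set <- function(spec, protocol = stimulus_protocol(),
                               n_repeats = 1L) {
  stopifnot(inherits(spec, "trace_spec"),
            inherits(protocol, "stimulus_protocol"))
  dur <- protocol$sweep_duration_s
  for (st in spec$spike_times_s)
    if (any(st < 0 | st >= dur))
      stop("spike times outside trace duration", call. = FALSE)

  sweeps <- list()
  k <- 0L
  for (rep_i in seq_len(n_repeats)) {
    for (cur in protocol$current_steps_pA) {
      k <- k + 1L
      base <- passive_trace(spec, protocol, cur)
      v <- base$v
      st <- spec$spike_times_s[[as.character(cur)]]
      if (!is.null(st) && length(st))
        v <- insert_aps(v, base$t, base$dt, spec$ap_shape, sort(st))
      if (spec$noise_sd_mV > 0) {
        set.seed(derive_seed(spec$seed, k))
        v <- v + stats::rnorm(length(v), 0, spec$noise_sd_mV)
      }
      sweeps[[k]] <- list(voltage_mV = v, current_pA = cur,
                          repeat_index = rep_i, sample_period_s = base$dt)
    }
  }
  gt <- ground_truth_from_spec(spec, protocol)
  sweep_set(sweeps, protocol, ground_truth = gt)
}

# analytic ground-truth features implied by a trace_spec
ground_truth_from_spec <- function(spec, protocol) {
  v0 <- spec$resting_potential_mV
  tau <- spec$membrane_tau_ms / 1000
  steps <- protocol$current_steps_pA
  imin <- min(steps)
  steady <- v0 + imin * spec$input_resistance_MOhm * 1e-3
  # sag trough of the noiseless analytic curve on the lowest step
  tt <- seq(0, protocol$duration_s, by = 1e-5)
  dV <- imin * spec$input_resistance_MOhm * 1e-3
  curve <- v0 + dV * (1 - exp(-tt / tau))
  if (spec$sag_amplitude_mV > 0) {
    taus <- spec$sag_tau_ms / 1000
    curve <- curve - spec$sag_amplitude_mV * (tt / taus) * exp(1 - tt / taus)
  }
  trough <- min(curve)
  sag_ratio <- if (abs(steady - v0) > 1e-12)
    (trough - v0) / (steady - v0) else NA_real_
  # rebound: mean of the analytic post-offset curve over 150 ms after the
  # first upward crossing of rest
  reb <- spec$rebound_mV
  rebound <- 0
  if (reb > 0) {
    v_off <- curve[length(curve)]
    # exp(-t_c/tau) at the crossing of v0
    e_c <- reb / (reb + v0 - v_off)
    if (e_c > 0 && e_c < 1) {
      t_c <- -tau * log(e_c)
      if (t_c <= 0.3) {
        w <- min(0.15, 0.3 - t_c)
        rebound <- reb + (v_off - v0 - reb) * (tau / w) *
          (e_c - exp(-(t_c + w) / tau))
      }
    }
  }
  counts <- vapply(as.character(steps), function(s) {
    st <- spec$spike_times_s[[s]]
    if (is.null(st)) 0L else
      sum(st >= protocol$onset_s & st <= protocol$offset_s)
  }, integer(1))
  list(spec = spec,
       v_rest = v0,
       r_input = spec$input_resistance_MOhm,
       tau = spec$membrane_tau_ms,
       steady_lowest = steady,
       sag_trough = trough,
       sag_ratio = sag_ratio,
       rebound = rebound,
       ap = unclass(spec$ap_shape),
       spike_counts_in_window = counts)
}
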