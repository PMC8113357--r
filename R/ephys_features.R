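#' Electrophysiological feature extraction
#'
#' Functions extracting the 29 electrophysiological features from a
#' current-clamp [sweep_set()]: passive membrane properties from
#' hyperpolarizing sweeps, rheobase by robust regression of spike count on
#' current, AP shape features from the first AP fired, adaptation indices,
#' firing statistics on the highest firing trace, sag and rebound of the
#' lowest hyperpolarizing sweep, burstiness and wildness. Undefined
#' features propagate as `NA`, except where an explicit zeroing rule sets
#' an exact 0.
#'
#' @name ephys-features
NULL

detect_all <- function(ss) {
  lapply(ss$sweeps, detect_spikes, protocol = ss$protocol)
}

sweep_currents <- function(ss)
  vapply(ss$sweeps, function(s) s$current_pA, numeric(1))

sweep_repeats <- function(ss)
  vapply(ss$sweeps, function(s) s$repeat_index %||% 1L, numeric(1))

# order sweeps as "first" means: lowest current, then lowest repeat
sweep_order <- function(ss) order(sweep_currents(ss), sweep_repeats(ss))

baseline_window <- function(sw, protocol) {
  t <- sweep_times(sw)
  mean(sw$voltage_mV[t >= protocol$onset_s - 0.1 & t < protocol$onset_s])
}

steady_state <- function(sw, protocol) {
  t <- sweep_times(sw)
  mean(sw$voltage_mV[t >= protocol$offset_s - 0.1 & t < protocol$offset_s])
}

#' Passive membrane features
#'
#' Resting potential is the mean voltage in the 100 ms before stimulus
#' onset; input resistance is (steady state - rest) / current, where
#' steady state is the mean over the last 100 ms before offset; the
#' membrane time constant comes from an exponential fit between onset and
#' the first local minimum of the 5-ms-smoothed trace. All three are
#' medians over the hyperpolarizing sweeps.
#'
#' @param ss A [sweep_set()].
#' @return List with `v_rest` (mV), `r_input` (MOhm), `tau` (ms); all
#'   `NA` (with a flag) when no hyperpolarizing sweep exists.
#' @export
passive_features <- function(ss) {
  p <- ss$protocol
  hyp <- which(sweep_currents(ss) < 0)
  if (!length(hyp))
    return(list(v_rest = NA_real_, r_input = NA_real_, tau = NA_real_,
                flag = "no hyperpolarizing sweep"))
  vr <- ri <- ta <- numeric(0)
  for (i in hyp) {
    sw <- ss$sweeps[[i]]
    rest <- baseline_window(sw, p)
    stdy <- steady_state(sw, p)
    vr <- c(vr, rest)
    ri <- c(ri, (stdy - rest) / sw$current_pA * 1000)  # mV/pA -> MOhm
    ta <- c(ta, fit_tau(sw, p))
  }
  list(v_rest = stats::median(vr), r_input = stats::median(ri),
       tau = stats::median(ta, na.rm = TRUE), flag = NULL)
}

# single-exponential fit of the charging transient, returns tau in ms
fit_tau <- function(sw, protocol) {
  t <- sweep_times(sw)
  dt <- sw$sample_period_s
  sm <- running_mean(sw$voltage_mV, max(3L, round(0.005 / dt)))
  i0 <- which(t >= protocol$onset_s)[1]
  iend <- which(t >= protocol$offset_s)[1] - 1L
  seg <- sm[i0:iend]
  # first local minimum of the smoothed trace after onset
  dmin <- which(diff(sign(diff(seg))) > 0)
  i1 <- if (length(dmin)) i0 + dmin[1] else iend
  if (i1 - i0 < 10) i1 <- min(i0 + 50L, iend)
  tt <- t[i0:i1] - t[i0]
  vv <- sw$voltage_mV[i0:i1]
  C0 <- vv[length(vv)]
  A0 <- vv[1] - C0
  if (abs(A0) < 1e-9) return(NA_real_)
  i_e <- which(abs(vv - C0) <= abs(A0) / exp(1))[1]
  tau0 <- if (!is.na(i_e) && i_e > 1) tt[i_e] else tt[length(tt)] / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ A * exp(-tt / tau) + C,
                      start = list(A = A0, tau = max(tau0, dt), C = C0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  tau <- stats::coef(fit)[["tau"]]
  if (tau <= 0) NA_real_ else tau * 1000
}

#' Rheobase estimate by robust regression
#'
#' Fits a robust line to in-window spike count versus injected current
#' over the five lowest spiking currents (fewer if unavailable) and takes
#' its x-intercept, restricted to lie between the highest zero-spike
#' current and the lowest spiking current; if the intercept falls outside
#' that interval, the lowest spiking current is used. The robust fit is a
#' deterministic consensus variant: a line through every pair of points
#' is scored by its inlier count (|residual| <= 1 spike) and the best
#' consensus set is refit by least squares.
#'
#' @param ss A [sweep_set()].
#' @param det Optional precomputed list of [detect_spikes()] results.
#' @return Rheobase in pA, or `NA` if no sweep spikes.
#' @export
rheobase <- function(ss, det = detect_all(ss)) {
  cur <- sweep_currents(ss)
  dep <- cur > 0
  counts <- vapply(det, function(d) d$n_in, numeric(1))
  # collapse repeats: mean count per current
  agg <- tapply(counts[dep], cur[dep], mean)
  currents <- as.numeric(names(agg))
  cnt <- as.numeric(agg)
  spiking <- currents[cnt > 0]
  if (!length(spiking)) return(NA_real_)
  i_low <- min(spiking)
  zeros <- currents[cnt == 0 & currents < i_low]
  lo <- if (length(zeros)) max(zeros) else 0
  use <- currents %in% utils::head(sort(spiking), 5)
  x <- currents[use]; y <- cnt[use]
  if (length(x) < 2) return(i_low)
  line <- ransac_line(x, y, thresh = 1)
  if (is.null(line) || line[2] <= 0) return(i_low)
  x0 <- unname(-line[1] / line[2])
  if (x0 >= lo && x0 <= i_low) x0 else i_low
}

# deterministic exhaustive-consensus line fit; returns c(intercept, slope)
ransac_line <- function(x, y, thresh = 1) {
  n <- length(x)
  best <- NULL; best_n <- -1L; best_rss <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[j] == x[i]) next
    sl <- (y[j] - y[i]) / (x[j] - x[i])
    ic <- y[i] - sl * x[i]
    res <- abs(y - (ic + sl * x))
    inl <- res <= thresh
    if (sum(inl) > best_n ||
        (sum(inl) == best_n && sum(res[inl]^2) < best_rss)) {
      best_n <- sum(inl); best_rss <- sum(res[inl]^2); best <- inl
    }
  }
  if (is.null(best) || sum(best) < 2) return(NULL)
  fit <- stats::lm.fit(cbind(1, x[best]), y[best])
  fit$coefficients
}

# first spiking sweep: lowest current (then lowest repeat) with an
# in-window AP
first_spiking_index <- function(ss, det) {
  ord <- sweep_order(ss)
  for (i in ord) if (det[[i]]$n_in > 0) return(i)
  NA_integer_
}

#' AP shape features from the first AP fired
#'
#' Computed on the first AP (in the stimulation window) of the first
#' spiking sweep: threshold voltage, amplitude (peak - threshold), width
#' at half height (linear interpolation of the half-height crossings),
#' AHP (threshold - fast trough), ADP, latency of the first AP from
#' stimulus onset, upstroke-to-downstroke ratio, and the first-AP latency
#' on the sweep 20 pA above the lowest spiking current.
#'
#' @inheritParams rheobase
#' @return List with `ap_threshold` (mV), `ap_amplitude` (mV),
#'   `ap_width` (ms), `ahp` (mV), `adp` (mV), `latency` (ms),
#'   `latency_20` (ms), `udr`.
#' @export
ap_shape_features <- function(ss, det = detect_all(ss)) {
  out <- list(ap_threshold = NA_real_, ap_amplitude = NA_real_,
              ap_width = NA_real_, ahp = NA_real_, adp = NA_real_,
              latency = NA_real_, latency_20 = NA_real_, udr = NA_real_)
  i <- first_spiking_index(ss, det)
  if (is.na(i)) return(out)
  p <- ss$protocol
  d <- det[[i]]
  k <- which(d$in_window)[1]
  ap <- d$aps[k, ]
  sw <- ss$sweeps[[i]]
  v <- sw$voltage_mV; dt <- sw$sample_period_s
  t <- sweep_times(sw)
  out$ap_threshold <- ap$threshold_v
  out$ap_amplitude <- ap$peak_v - ap$threshold_v
  out$ahp <- ap$threshold_v - ap$trough_v
  out$adp <- ap$adp
  out$latency <- (ap$threshold_t - p$onset_s) * 1000
  # width at half height, interpolated
  half <- ap$threshold_v + out$ap_amplitude / 2
  i_thr <- which.min(abs(t - ap$threshold_t))
  i_pk <- which.min(abs(t - ap$peak_t))
  i_tr <- which.min(abs(t - ap$trough_t))
  up <- i_thr:i_pk; dn <- i_pk:i_tr
  cu <- which(v[up] >= half)[1]
  cd <- which(v[dn] <= half)[1]
  if (!is.na(cu) && !is.na(cd) && cu > 1 && cd > 1) {
    iu <- up[cu]; idn <- dn[cd]
    tu <- t[iu - 1] + dt * (half - v[iu - 1]) / (v[iu] - v[iu - 1])
    tdn <- t[idn - 1] + dt * (half - v[idn - 1]) / (v[idn] - v[idn - 1])
    out$ap_width <- (tdn - tu) * 1000
  }
  dvdt <- diff(v) / (dt * 1000)
  upseg <- dvdt[i_thr:max(i_thr, i_pk - 1L)]
  dnseg <- dvdt[i_pk:max(i_pk, i_tr - 1L)]
  if (length(upseg) && length(dnseg) && min(dnseg) < 0)
    out$udr <- max(upseg) / abs(min(dnseg))
  # latency at rheobase + 20 pA
  cur <- sweep_currents(ss)
  tgt <- sw$current_pA + 20
  j <- which(abs(cur - tgt) < 1e-9)
  if (length(j)) {
    j <- j[order(sweep_repeats(ss)[j])][1]
    dj <- det[[j]]
    if (dj$n_in > 0) {
      apj <- dj$aps[which(dj$in_window)[1], ]
      out$latency_20 <- (apj$threshold_t - p$onset_s) * 1000
    }
  }
  out
}

in_window_aps <- function(d) d$aps[d$in_window, , drop = FALSE]

#' Adaptation indices
#'
#' ISI adaptation is the ratio of the second ISI to the first; the
#' average index is the mean over all consecutive ISI ratios. Amplitude
#' adaptation indices are defined analogously on consecutive AP
#' amplitudes. Each index is the median over the five lowest depolarizing
#' currents with enough spikes (three for ISI indices, two for amplitude
#' indices).
#'
#' @inheritParams rheobase
#' @return List with `isi_adapt`, `isi_avg_adapt`, `amp_adapt`,
#'   `amp_avg_adapt`.
#' @export
adaptation_features <- function(ss, det = detect_all(ss)) {
  ord <- sweep_order(ss)
  cur <- sweep_currents(ss)
  dep <- ord[cur[ord] > 0]
  isi1 <- isiA <- amp1 <- ampA <- numeric(0)
  n_isi_tr <- n_amp_tr <- 0L
  for (i in dep) {
    aps <- in_window_aps(det[[i]])
    nt <- nrow(aps)
    if (nt >= 3 && n_isi_tr < 5) {
      isi <- diff(aps$threshold_t)
      r <- isi[-1] / isi[-length(isi)]
      isi1 <- c(isi1, r[1]); isiA <- c(isiA, mean(r))
      n_isi_tr <- n_isi_tr + 1L
    }
    if (nt >= 2 && n_amp_tr < 5) {
      a <- aps$peak_v - aps$threshold_v
      r <- a[-1] / a[-length(a)]
      amp1 <- c(amp1, r[1]); ampA <- c(ampA, mean(r))
      n_amp_tr <- n_amp_tr + 1L
    }
    if (n_isi_tr >= 5 && n_amp_tr >= 5) break
  }
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  list(isi_adapt = med(isi1), isi_avg_adapt = med(isiA),
       amp_adapt = med(amp1), amp_avg_adapt = med(ampA))
}

#' Select the highest firing trace
#'
#' Excludes every depolarizing sweep with at least one AP in the 100 ms
#' before onset or the 200 ms after offset, then returns the first (lowest
#' current, lowest repeat) remaining sweep with the maximum in-window AP
#' count.
#'
#' @inheritParams rheobase
#' @param allow_wild If `TRUE`, skip the out-of-window exclusion (used
#'   for the wildness feature).
#' @return Sweep index, or `NA` if no eligible spiking sweep exists.
#' @export
select_highest_firing_trace <- function(ss, det = detect_all(ss),
                                        allow_wild = FALSE) {
  ord <- sweep_order(ss)
  cur <- sweep_currents(ss)
  cand <- ord[cur[ord] > 0]
  if (!allow_wild)
    cand <- cand[vapply(det[cand], function(d) d$n_pre + d$n_post == 0,
                        logical(1))]
  if (!length(cand)) return(NA_integer_)
  counts <- vapply(det[cand], function(d) d$n_in, numeric(1))
  if (max(counts) == 0) return(NA_integer_)
  cand[which.max(counts)]   # first max in (current, repeat) order
}

#' Firing statistics of the highest firing trace
#'
#' Max AP count; spike-frequency adaptation (second-half / first-half AP
#' count, undefined below five APs); coefficient of variation and Fano
#' factor of the ISIs and of the AP amplitudes.
#'
#' @inheritParams rheobase
#' @return List with `max_num_aps`, `sfa`, `isi_cv`, `isi_fano`,
#'   `ap_cv`, `ap_fano`.
#' @export
firing_statistics <- function(ss, det = detect_all(ss)) {
  out <- list(max_num_aps = NA_real_, sfa = NA_real_, isi_cv = NA_real_,
              isi_fano = NA_real_, ap_cv = NA_real_, ap_fano = NA_real_)
  i <- select_highest_firing_trace(ss, det)
  if (is.na(i)) return(out)
  p <- ss$protocol
  aps <- in_window_aps(det[[i]])
  out$max_num_aps <- nrow(aps)
  mid <- (p$onset_s + p$offset_s) / 2
  n1 <- sum(aps$threshold_t < mid); n2 <- nrow(aps) - n1
  if (nrow(aps) >= 5 && n1 > 0) out$sfa <- n2 / n1
  if (nrow(aps) >= 3) {
    isi <- diff(aps$threshold_t)
    out$isi_cv <- stats::sd(isi) / mean(isi)
    out$isi_fano <- stats::var(isi) / mean(isi)
  }
  if (nrow(aps) >= 2) {
    a <- aps$peak_v - aps$threshold_v
    out$ap_cv <- stats::sd(a) / mean(a)
    out$ap_fano <- stats::var(a) / mean(a)
  }
  out
}

#' ISI statistics of a spike train
#'
#' Coefficient of variation and Fano factor of the inter-spike intervals
#' of an explicit spike-time vector (used directly by simulation checks;
#' [firing_statistics()] applies the same definitions to detected APs).
#'
#' @param spike_times_s Numeric vector of spike times (s).
#' @return List with `isi_cv` and `isi_fano` (`NA` below two ISIs).
#' @export
isi_statistics <- function(spike_times_s) {
  if (length(spike_times_s) < 3)
    return(list(isi_cv = NA_real_, isi_fano = NA_real_))
  isi <- diff(sort(spike_times_s))
  list(isi_cv = stats::sd(isi) / mean(isi),
       isi_fano = stats::var(isi) / mean(isi))
}

lowest_hyper_index <- function(ss) {
  cur <- sweep_currents(ss)
  hyp <- which(cur < 0)
  if (!length(hyp)) return(NA_integer_)
  hyp[order(cur[hyp], sweep_repeats(ss)[hyp])][1]
}

#' Sag features of the lowest hyperpolarizing sweep
#'
#' Sag ratio is (trough - rest) / (steady - rest), where the trough
#' voltage is averaged over a 5-ms window around the minimum. Sag time is
#' the interval between the first and second crossings of the
#' steady-state voltage after onset, and sag area the absolute integral
#' of (V - steady) over that interval. When the trough and steady-state
#' voltages differ by less than 4 mV, sag time and sag area are exactly
#' zero.
#'
#' @inheritParams rheobase
#' @param zero_threshold_mV The 4-mV zeroing threshold.
#' @return List with `sag_ratio`, `sag_time` (ms), `sag_area` (mV ms).
#' @export
sag_features <- function(ss, zero_threshold_mV = 4) {
  out <- list(sag_ratio = NA_real_, sag_time = NA_real_,
              sag_area = NA_real_)
  i <- lowest_hyper_index(ss)
  if (is.na(i)) return(out)
  p <- ss$protocol
  sw <- ss$sweeps[[i]]
  v <- sw$voltage_mV; dt <- sw$sample_period_s
  t <- sweep_times(sw)
  rest <- baseline_window(sw, p)
  stdy <- steady_state(sw, p)
  stim <- which(t >= p$onset_s & t < p$offset_s)
  # trough index: midpoint of the argmin set (robust to flat troughs)
  cands <- stim[v[stim] <= min(v[stim]) + 1e-12]
  i_tr <- cands[ceiling(length(cands) / 2)]
  w <- round(0.0025 / dt)
  tr_avg <- mean(v[max(1, i_tr - w):min(length(v), i_tr + w)])
  if (abs(stdy - rest) < 1e-12) return(out)
  out$sag_ratio <- (tr_avg - rest) / (stdy - rest)
  if (abs(tr_avg - stdy) < zero_threshold_mV) {
    out$sag_time <- 0
    out$sag_area <- 0
    return(out)
  }
  below <- v[stim] < stdy
  d <- diff(below)
  t1 <- which(d == 1)  # downward crossings of steady (voltage drops below)
  if (length(t1)) {
    i1 <- t1[1] + 1L
    t2 <- which(d[-seq_len(t1[1])] == -1)
    if (length(t2)) {
      i2 <- t1[1] + t2[1]
      out$sag_time <- (i2 - i1 + 1) * dt * 1000
      seg <- stim[i1:i2]
      out$sag_area <- abs(sum(v[seg] - stdy) * dt * 1000)
    } else {
      out$sag_time <- 0; out$sag_area <- 0
    }
  } else {
    out$sag_time <- 0; out$sag_area <- 0
  }
  out
}

#' Rebound features of the lowest hyperpolarizing sweep
#'
#' Rebound onset is the first post-offset sample at which the voltage
#' reaches the resting potential (within 300 ms of offset); the rebound
#' is the mean voltage above rest over 150 ms after onset (or whatever
#' remains until 300 ms post-offset), and the rebound AP count is taken
#' over the same window. If the voltage never reaches rest within 300 ms,
#' the rebound is exactly zero.
#'
#' @inheritParams rheobase
#' @return List with `rebound` (mV, >= 0) and `rebound_aps` (count).
#' @export
rebound_features <- function(ss, det = detect_all(ss)) {
  out <- list(rebound = NA_real_, rebound_aps = NA_real_)
  i <- lowest_hyper_index(ss)
  if (is.na(i)) return(out)
  p <- ss$protocol
  sw <- ss$sweeps[[i]]
  v <- sw$voltage_mV; t <- sweep_times(sw)
  rest <- baseline_window(sw, p)
  post <- which(t > p$offset_s & t <= p$offset_s + 0.3)
  cross <- post[v[post] >= rest][1]
  if (is.na(cross)) {
    out$rebound <- 0
    out$rebound_aps <- 0
    return(out)
  }
  t_on <- t[cross]
  w <- min(0.15, p$offset_s + 0.3 - t_on)
  win <- which(t >= t_on & t < t_on + w)
  out$rebound <- max(0, mean(v[win]) - rest)
  ap_t <- det[[i]]$aps$threshold_t
  out$rebound_aps <- sum(ap_t >= t_on & ap_t < t_on + w)
  out
}

# classify ISIs of one sweep: "detour", "direct", plus pauselike flag
classify_isis <- function(sweep, d, pause_multiple = 3) {
  aps <- in_window_aps(d)
  n <- nrow(aps)
  if (n < 2) return(NULL)
  v <- sweep$voltage_mV
  t <- sweep_times(sweep)
  isi <- diff(aps$threshold_t)
  kind <- character(n - 1)
  for (k in seq_len(n - 1)) {
    if (aps$adp[k] > 0) { kind[k] <- "detour"; next }
    # voltage drop of >= 0.5 mV below the fast trough before the next AP
    i_tr <- which.min(abs(t - aps$trough_t[k]))
    i_nx <- which.min(abs(t - aps$threshold_t[k + 1]))
    drop <- if (i_nx > i_tr + 1)
      aps$trough_v[k] - min(v[(i_tr + 1):i_nx]) else 0
    kind[k] <- if (drop >= 0.5) "detour" else "direct"
  }
  pause <- isi > pause_multiple * stats::median(isi)
  list(isi = isi, kind = kind, pause = pause)
}

#' Burstiness
#'
#' An ISI is "detour" when the preceding AP has a non-zero ADP or the
#' voltage drops at least 0.5 mV below its fast trough before the next
#' AP, and "direct" otherwise; unusually long ISIs (over
#' `pause_multiple` times the trace median) are "pauselike". A burst
#' starts where a detour ISI is followed by a direct ISI and spans the
#' following run of direct ISIs; bursts containing a pauselike ISI are
#' discarded. The burstiness of a trace is
#' (1/min ISI inside bursts - 1/min ISI outside) / (their sum), 0 when no
#' burst is detected; the cell's value is the median over the first five
#' depolarizing traces.
#'
#' @inheritParams rheobase
#' @param pause_multiple Pauselike threshold as a multiple of the trace
#'   median ISI.
#' @return Burstiness in [-1, 1].
#' @export
burstiness <- function(ss, det = detect_all(ss), pause_multiple = 3) {
  ord <- sweep_order(ss)
  cur <- sweep_currents(ss)
  dep <- utils::head(ord[cur[ord] > 0], 5)
  if (!length(dep)) return(NA_real_)
  vals <- vapply(dep, function(i) {
    cl <- classify_isis(ss$sweeps[[i]], det[[i]], pause_multiple)
    if (is.null(cl) || length(cl$isi) < 2) return(0)
    burst_member <- rep(FALSE, length(cl$isi))
    k <- 1
    while (k < length(cl$isi)) {
      if (cl$kind[k] == "detour" && cl$kind[k + 1] == "direct") {
        j <- k + 1
        while (j <= length(cl$isi) && cl$kind[j] == "direct") j <- j + 1
        members <- (k + 1):(j - 1)
        if (!any(cl$pause[members])) burst_member[members] <- TRUE
        k <- j
      } else k <- k + 1
    }
    if (!any(burst_member) || all(burst_member)) return(0)
    fi <- 1 / min(cl$isi[burst_member])
    fo <- 1 / min(cl$isi[!burst_member])
    (fi - fo) / (fi + fo)
  }, numeric(1))
  stats::median(vals)
}

#' Wildness
#'
#' The AP-count difference between the highest firing trace selected with
#' no exclusion (possibly firing before/after the stimulation window) and
#' the clean highest firing trace. Zero when no sweep fires outside the
#' window.
#'
#' @inheritParams rheobase
#' @return Count >= 0, or `NA` when no clean trace exists.
#' @export
wildness <- function(ss, det = detect_all(ss)) {
  i_clean <- select_highest_firing_trace(ss, det)
  i_any <- select_highest_firing_trace(ss, det, allow_wild = TRUE)
  if (is.na(i_clean)) return(NA_real_)
  if (is.na(i_any)) return(0)
  max(0, det[[i_any]]$n_in - det[[i_clean]]$n_in)
}

ephys_feature_names <- c(
  "v_rest", "r_input", "rheobase", "ap_threshold", "ap_amplitude",
  "ap_width", "ahp", "adp", "latency", "latency_20", "udr",
  "isi_adapt", "isi_avg_adapt", "amp_adapt", "amp_avg_adapt",
  "max_num_aps", "sfa", "tau", "sag_ratio", "sag_time", "sag_area",
  "rebound", "rebound_aps", "isi_cv", "isi_fano", "ap_cv", "ap_fano",
  "burstiness", "wildness")

#' Extract the full 29-feature electrophysiology record
#'
#' Runs spike detection once over all sweeps and assembles the 29 named
#' features.
#'
#' @param ss A [sweep_set()].
#' @return Named numeric vector of length 29 (`NA` for undefined
#'   features).
#' @export
extract_ephys_features <- function(ss) {
  det <- detect_all(ss)
  pas <- passive_features(ss)
  shp <- ap_shape_features(ss, det)
  ada <- adaptation_features(ss, det)
  fir <- firing_statistics(ss, det)
  sag <- sag_features(ss)
  reb <- rebound_features(ss, det)
  out <- c(
    v_rest = pas$v_rest, r_input = pas$r_input,
    rheobase = rheobase(ss, det),
    ap_threshold = shp$ap_threshold, ap_amplitude = shp$ap_amplitude,
    ap_width = shp$ap_width, ahp = shp$ahp, adp = shp$adp,
    latency = shp$latency, latency_20 = shp$latency_20, udr = shp$udr,
    isi_adapt = ada$isi_adapt, isi_avg_adapt = ada$isi_avg_adapt,
    amp_adapt = ada$amp_adapt, amp_avg_adapt = ada$amp_avg_adapt,
    max_num_aps = fir$max_num_aps, sfa = fir$sfa,
    tau = pas$tau,
    sag_ratio = sag$sag_ratio, sag_time = sag$sag_time,
    sag_area = sag$sag_area,
    rebound = reb$rebound, rebound_aps = reb$rebound_aps,
    isi_cv = fir$isi_cv, isi_fano = fir$isi_fano,
    ap_cv = fir$ap_cv, ap_fano = fir$ap_fano,
    burstiness = burstiness(ss, det),
    wildness = wildness(ss, det))
  out[ephys_feature_names]
}

analysis_feature_names <- c(
  "v_rest", "r_input", "rheobase", "ap_threshold", "ap_amplitude",
  "ap_width", "ahp", "latency", "udr", "isi_adapt", "amp_adapt",
  "max_num_aps", "tau", "sag_ratio", "rebound", "isi_cv", "ap_cv")

log_transformed_features <- c("ap_cv", "isi_cv", "isi_adapt", "latency")

#' Assemble the 17-feature analysis vector
#'
#' Retains 17 of the 29 features (dropping the mostly-zero, redundant,
#' skewed and sometimes-undefined ones) and natural-log-transforms the AP
#' CV, ISI CV, ISI adaptation index and latency. A cell whose 17 features
#' are not all present (or whose log-transformed features are not
#' positive) is flagged incomplete.
#'
#' @param features Named 29-feature vector from
#'   [extract_ephys_features()], or a matrix/data frame of such rows.
#' @return For a vector input: named numeric vector of length 17 with
#'   attribute `complete`. For matrix input: a matrix with one row per
#'   cell and a `complete` logical attribute vector.
#' @export
assemble_analysis_vector <- function(features) {
  if (is.matrix(features) || is.data.frame(features)) {
    m <- t(apply(as.matrix(features), 1, assemble_analysis_vector))
    colnames(m) <- analysis_feature_names
    attr(m, "complete") <- apply(m, 1, function(r) all(is.finite(r)))
    return(m)
  }
  x <- features[analysis_feature_names]
  names(x) <- analysis_feature_names
  for (f in log_transformed_features)
    x[f] <- if (is.na(x[f]) || x[f] <= 0) NA_real_ else log(x[f])
  attr(x, "complete") <- all(is.finite(x))
  x
}
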