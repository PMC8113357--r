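#' Detect action potentials in a sweep
#'
#' Threshold-based spike detection: a spike is a local voltage maximum
#' above `peak_min_mV` whose preceding depolarization exceeded
#' `dvdt_threshold_Vps`. For each AP the threshold point (first crossing
#' of the dV/dt criterion before the peak), peak, fast trough (minimum
#' before the next AP's threshold or within 100 ms) and
#' afterdepolarization are located, and window membership relative to the
#' stimulation window is recorded: the stimulation window itself, the
#' 100 ms before onset, and the 200 ms after offset.
#'
#' @param sweep A single sweep (list with `voltage_mV`,
#'   `sample_period_s`, `current_pA`).
#' @param protocol A [stimulus_protocol()].
#' @param dvdt_threshold_Vps dV/dt criterion defining the AP threshold
#'   (default 20 V/s).
#' @param peak_min_mV Minimum peak voltage for a candidate AP (default
#'   -20 mV).
#' @param adp_floor_mV Minimum bump height counted as a non-zero ADP.
#' @return A list of class `detected_spikes` with a data frame `aps`
#'   (one row per AP: threshold/peak/trough times and voltages, ADP) and
#'   window counts `n_in`, `n_pre`, `n_post`.
#' @export
detect_spikes <- function(sweep, protocol, dvdt_threshold_Vps = 20,
                          peak_min_mV = -20, adp_floor_mV = 0.2) {
  v <- sweep$voltage_mV
  dt <- sweep$sample_period_s
  if (is.null(dt) || !is.finite(dt) || dt <= 0)
    stop("non-uniform or invalid sampling", call. = FALSE)
  t <- (seq_along(v) - 1) * dt
  n <- length(v)
  dvdt <- c(diff(v) / (dt * 1000), 0)   # V/s; dvdt[i] = slope after sample i

  # candidate peaks: local maxima above peak_min with a fast upstroke
  # in the preceding 10 ms
  is_peak <- c(FALSE, diff(sign(diff(v))) < 0, FALSE) & v > peak_min_mV
  cand <- which(is_peak)
  look <- max(1L, round(0.01 / dt))
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - look)
    any(dvdt[lo:max(lo, i - 1L)] >= dvdt_threshold_Vps)
  }, logical(1))
  cand <- cand[keep]

  # threshold index: nearest upward crossing of the dV/dt criterion
  # before the peak
  thr_idx <- vapply(cand, function(i) {
    j <- i - 1L
    while (j > 1L && dvdt[j] >= dvdt_threshold_Vps) j <- j - 1L
    j
  }, integer(1))
  # deduplicate: several local maxima after one threshold -> keep highest
  if (length(cand) > 1) {
    keep <- !duplicated(thr_idx)
    grp <- cumsum(keep)
    best <- tapply(seq_along(cand), grp, function(ii) ii[which.max(v[cand[ii]])])
    cand <- cand[as.integer(best)]
    thr_idx <- thr_idx[as.integer(best)]
  }

  n_ap <- length(cand)
  if (n_ap == 0L) {
    aps <- data.frame(threshold_t = numeric(0), threshold_v = numeric(0),
                      peak_t = numeric(0), peak_v = numeric(0),
                      trough_t = numeric(0), trough_v = numeric(0),
                      adp = numeric(0))
  } else {
    trough_idx <- integer(n_ap)
    adp <- numeric(n_ap)
    w5 <- round(0.005 / dt)    # fast-trough search window
    w10 <- round(0.01 / dt)    # ADP search window after the trough
    for (k in seq_len(n_ap)) {
      nxt <- if (k < n_ap) thr_idx[k + 1L] else n
      # fast trough: minimum within 5 ms of the peak (or up to the next
      # AP threshold if that comes first)
      lim <- min(max(cand[k] + w5, cand[k] + 1L), nxt, n)
      seg <- v[(cand[k] + 1L):lim]
      trough_idx[k] <- cand[k] + which.min(seg)
      # ADP: bump above the fast trough within 10 ms, followed by decay
      ti <- trough_idx[k]
      lim2 <- min(ti + w10, nxt, n)
      if (ti < lim2 - 2L) {
        seg2 <- running_mean(v[ti:lim2], max(3L, round(0.001 / dt)))
        m <- which.max(seg2)
        if (m > 1 && m < length(seg2)) {
          h <- seg2[m] - v[ti]
          if (h >= adp_floor_mV) adp[k] <- h
        }
      }
    }
    aps <- data.frame(
      threshold_t = t[thr_idx], threshold_v = v[thr_idx],
      peak_t = t[cand], peak_v = v[cand],
      trough_t = t[trough_idx], trough_v = v[trough_idx],
      adp = adp)
  }

  onset <- protocol$onset_s; offset <- protocol$offset_s
  in_win <- aps$threshold_t >= onset & aps$threshold_t <= offset
  pre <- aps$threshold_t >= onset - 0.1 & aps$threshold_t < onset
  post <- aps$threshold_t > offset & aps$threshold_t <= offset + 0.2
  structure(list(aps = aps, in_window = in_win,
                 n_in = sum(in_win), n_pre = sum(pre), n_post = sum(post),
                 current_pA = sweep$current_pA,
                 repeat_index = sweep$repeat_index %||% 1L),
            class = "detected_spikes")
}
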