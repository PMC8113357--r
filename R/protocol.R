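#' Current-clamp stimulation protocol
#'
#' Describes the square-pulse current injection paradigm: a 600-ms pulse
#' with onset after a baseline period, delivered at increasing current
#' amplitudes (by default -200 pA to +1380 pA in 20-pA steps).
#'
#' @param onset_s Stimulus onset, seconds from sweep start (default 0.1 s;
#'   at least 0.1 s of baseline is required for the resting-potential
#'   window).
#' @param duration_s Pulse duration in seconds (default 0.6).
#' @param current_steps_pA Strictly increasing injected current amplitudes
#'   in pA.
#' @param inter_sweep_s Interval between successive pulses in seconds.
#' @param sample_rate_hz Sampling rate of generated/expected traces.
#' @param post_s Recorded time after stimulus offset in seconds (must be
#'   >= 0.3 s so that rebound features are computable).
#'
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(onset_s = 0.1, duration_s = 0.6,
                              current_steps_pA = seq(-200, 1380, by = 20),
                              inter_sweep_s = 1.3,
                              sample_rate_hz = 10000,
                              post_s = 0.4) {
  stopifnot_scalar(onset_s, "onset_s", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(post_s, "post_s", positive = TRUE)
  if (onset_s < 0.1)
    stop("onset_s must be >= 0.1 s (baseline window)", call. = FALSE)
  if (post_s < 0.3)
    stop("post_s must be >= 0.3 s (rebound window)", call. = FALSE)
  if (any(diff(current_steps_pA) <= 0))
    stop("current_steps_pA must be strictly increasing", call. = FALSE)
  structure(list(
    onset_s = onset_s,
    offset_s = onset_s + duration_s,
    duration_s = duration_s,
    current_steps_pA = current_steps_pA,
    inter_sweep_s = inter_sweep_s,
    sample_rate_hz = sample_rate_hz,
    post_s = post_s,
    sweep_duration_s = onset_s + duration_s + post_s
  ), class = "stimulus_protocol")
}

#' Assemble a sweep set
#'
#' A sweep set bundles one cell's current-clamp sweeps with their protocol.
#' Each sweep is a list with elements `voltage_mV` (numeric vector),
#' `current_pA` (scalar), `repeat_index` (integer) and `sample_period_s`.
#'
#' @param sweeps List of sweeps as described above.
#' @param protocol A [stimulus_protocol()].
#' @param ground_truth Optional list of planted ground-truth values
#'   (attached by the synthetic generator).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, protocol, ground_truth = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"), is.list(sweeps))
  for (s in sweeps) {
    if (is.null(s$voltage_mV) || is.null(s$current_pA) ||
        is.null(s$sample_period_s))
      stop("each sweep needs voltage_mV, current_pA, sample_period_s",
           call. = FALSE)
  }
  structure(list(sweeps = sweeps, protocol = protocol,
                 ground_truth = ground_truth), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cur <- vapply(x$sweeps, function(s) s$current_pA, numeric(1))
  cat(sprintf("<sweep_set> %d sweeps, %g to %g pA, %g kHz\n",
              length(x$sweeps), min(cur), max(cur),
              1e-3 / x$sweeps[[1]]$sample_period_s))
  invisible(x)
}

sweep_times <- function(sw) {
  (seq_along(sw$voltage_mV) - 1) * sw$sample_period_s
}

#' Write / read a sweep set as a CSV sweep table
#'
#' The sweep-table dialect is long-format CSV with columns
#' `sweep`, `current_pA`, `repeat_index`, `time_s`, `voltage_mV`.
#' Protocol parameters are stored in `#`-prefixed header comments.
#'
#' @param x A `sweep_set`.
#' @param path Output CSV path.
#' @return `write_sweep_table` returns `path` invisibly;
#'   `read_sweep_table` returns a `sweep_set`.
#' @export
write_sweep_table <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  p <- x$protocol
  hdr <- c(
    sprintf("# onset_s=%.17g", p$onset_s),
    sprintf("# duration_s=%.17g", p$duration_s),
    sprintf("# post_s=%.17g", p$post_s),
    sprintf("# sample_rate_hz=%.17g", p$sample_rate_hz)
  )
  rows <- lapply(seq_along(x$sweeps), function(i) {
    sw <- x$sweeps[[i]]
    data.frame(sweep = i, current_pA = sw$current_pA,
               repeat_index = sw$repeat_index %||% 1L,
               time_s = sweep_times(sw), voltage_mV = sw$voltage_mV)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_table
#' @export
read_sweep_table <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(".*=", "", m[1])) else default
  }
  tab <- utils::read.csv(path, comment.char = "#")
  proto <- stimulus_protocol(
    onset_s = getv("onset_s", 0.1),
    duration_s = getv("duration_s", 0.6),
    sample_rate_hz = getv("sample_rate_hz", 10000),
    post_s = getv("post_s", 0.4)
  )
  sweeps <- lapply(split(tab, tab$sweep), function(d) {
    d <- d[order(d$time_s), ]
    list(voltage_mV = d$voltage_mV,
         current_pA = d$current_pA[1],
         repeat_index = as.integer(d$repeat_index[1]),
         sample_period_s = stats::median(diff(d$time_s)))
  })
  names(sweeps) <- NULL
  sweep_set(sweeps, proto)
}
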