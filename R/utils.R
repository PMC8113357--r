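#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shannon entropy in bits of a vector of category labels
entropy_bits <- function(x) {
  p <- table(x)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# running mean with window w (odd), mirror-padded at the ends
running_mean <- function(x, w) {
  if (w <= 1 || length(x) < 2) return(x)
  w <- min(w, length(x) - (length(x) + 1) %% 2)
  half <- w %/% 2
  xp <- c(rev(x[seq_len(half) + 1]), x, rev(x[length(x) - seq_len(half)]))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[half + seq_along(x)]
}

# population variance (divides by n, not n - 1)
pop_var <- function(x) mean((x - mean(x))^2)

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# deterministic per-stage seed fan-out from a single master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
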