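# Independent brute-force oracles used to check the package's vectorized
# implementations. These are deliberately naive (explicit loops, power-sum
# polynomial evaluation) and share no code with the package internals.

# |H| at one frequency by direct power-sum polynomial evaluation
oracle_mag_analog <- function(num, den, f) {
  s <- 2i * pi * f
  pows <- function(p) sum(p * s^(rev(seq_along(p)) - 1))
  Mod(pows(num) / pows(den))
}

oracle_mag_digital <- function(b, a, f, fs) {
  z <- exp(2i * pi * f / fs)
  pows <- function(p) sum(p * z^(-(seq_along(p) - 1)))
  Mod(pows(b) / pows(a))
}

# causal direct-form IIR filtering by explicit recursion
oracle_iir <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  na <- length(a)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(nb)) if (i - k + 1 >= 1) acc <- acc + b[k] * x[i - k + 1]
    for (k in 2:na) if (i - k + 1 >= 1) acc <- acc - a[k] * y[i - k + 1]
    y[i] <- acc
  }
  y
}

# the whole count pipeline as one straight-line per-axis loop
oracle_axis_counts <- function(x, b, a, fs, saturation = 2.13,
                               dead = 0.068, scale = 0.001664,
                               gain = 0.96, epoch_s = 1) {
  y <- oracle_iir(b, a, x)
  for (i in seq_along(y)) {
    v <- abs(y[i])
    if (v > saturation) v <- saturation
    if (v < dead) v <- 0
    y[i] <- gain * v / scale
  }
  n_per <- as.integer(round(fs * epoch_s))
  n_ep <- length(y) %/% n_per
  out <- numeric(n_ep)
  for (e in seq_len(n_ep))
    out[e] <- sum(y[((e - 1) * n_per + 1):(e * n_per)]) / fs
  out
}

# sliding-window counts-per-minute by explicit per-second slicing
oracle_window_cpm <- function(v, window_s = 60L) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 30L)
    hi <- min(n, i + window_s - 31L)
    out[i] <- sum(v[lo:hi]) * 60 / (hi - lo + 1L)
  }
  out
}

# formula-by-formula agreement statistics
oracle_agreement <- function(a, b) {
  d <- b - a
  m <- (a + b) / 2
  md <- sum(d) / length(d)
  sdd <- sqrt(sum((d - md)^2) / (length(d) - 1))
  lo <- md - 1.96 * sdd
  hi <- md + 1.96 * sdd
  xb <- mean(m)
  yb <- mean(abs(d))
  slope <- sum((m - xb) * (abs(d) - yb)) / sum((m - xb)^2)
  list(pearson = sum((a - mean(a)) * (b - mean(b))) /
         sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
       spearman = stats::cor(rank(a), rank(b)),
       md = md, lo = lo, hi = hi,
       n_out = sum(d < lo | d > hi),
       rel = 100 * (sum(b) - sum(a)) / sum(a),
       slope = slope, intercept = yb - slope * xb)
}

# dominant DFT frequency (Hz) of a demeaned signal
oracle_peak_freq <- function(x, fs) {
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(length(x) / 2))]
  (which.max(sp) - 1) * fs / length(x)
}
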