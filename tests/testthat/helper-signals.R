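# Shared fixtures and independent oracles, built in code at test time.

tone_wave <- function(freq, duration_s = 1, rate = 8000, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * seq_len(round(duration_s * rate)) / rate),
           rate)
}

noise_wave <- function(duration_s = 1, rate = 8000, amp = 0.2, seed = 1) {
  waveform(with_seed(seed, stats::rnorm(round(duration_s * rate))) * amp, rate)
}

# FFT-peak oracle: dominant frequency of a waveform, Hz.
fft_peak_hz <- function(w) {
  n <- length(w$samples)
  sp <- Mod(stats::fft(w$samples))[seq_len(n %/% 2)]
  (which.max(sp) - 1) * w$rate / n
}

# Octave-band-averaged PSD in dB (coarse Welch oracle for flatness checks).
band_levels_db <- function(x, rate, f_lo = 200, f_hi = 3200, n_bands = 8) {
  p <- welch_psd(x, rate)
  edges <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands + 1))
  vapply(seq_len(n_bands), function(b) {
    sel <- p$freq >= edges[b] & p$freq < edges[b + 1]
    10 * log10(mean(p$psd[sel]))
  }, numeric(1))
}

# Exhaustive DTW oracle: enumerate every monotone alignment path for tiny
# frame matrices (steps (1,0), (0,1), (1,1)), summing Euclidean local costs.
dtw_bruteforce <- function(a, b) {
  C <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
  C <- matrix(pmax(C, 0), nrow(a), nrow(b))
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(C[1, 1])
    opts <- c()
    if (i > 1) opts <- c(opts, rec(i - 1, j))
    if (j > 1) opts <- c(opts, rec(i, j - 1))
    if (i > 1 && j > 1) opts <- c(opts, rec(i - 1, j - 1))
    C[i, j] + min(opts)
  }
  rec(nrow(a), nrow(b))
}

# Independent two-piece oracle: exhaustive breakpoint search using lm().
two_piece_bruteforce <- function(y, x = seq_along(y)) {
  n <- length(y)
  best <- NULL
  for (i in 2:(n - 2)) {
    m1 <- stats::lm(y[1:i] ~ x[1:i])
    m2 <- stats::lm(y[(i + 1):n] ~ x[(i + 1):n])
    sse <- sum(stats::resid(m1)^2) + sum(stats::resid(m2)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(breakpoint = x[i], sse = sse,
                   slope1 = unname(stats::coef(m1)[2]),
                   slope2 = unname(stats::coef(m2)[2]))
    }
  }
  best
}
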