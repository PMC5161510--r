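# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Root-mean-square of a numeric vector.
rms <- function(x) sqrt(mean(x^2))

# Linear amplitude ratio <-> decibels.
db <- function(x) 20 * log10(x)
undb <- function(x) 10^(x / 20)

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Periodic Hann window of length n.
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# 4-term Blackman-Harris window (-92 dB sidelobes), for peak-picking where
# Hann's -31 dB sidelobes would masquerade as spectral peaks.
blackman_harris <- function(n) {
  k <- 2 * pi * (seq_len(n) - 1) / n
  0.35875 - 0.48829 * cos(k) + 0.14128 * cos(2 * k) - 0.01168 * cos(3 * k)
}

# Short-time Fourier transform: complex matrix (nfft/2 + 1) x n_frames.
# Frames start at 1 + (k-1)*hop; the last partial frame is zero-padded.
stft <- function(x, win, hop, nfft = length(win)) {
  n <- length(x)
  nw <- length(win)
  n_frames <- max(1L, as.integer(ceiling((n - nw) / hop)) + 1L)
  out <- matrix(0 + 0i, nrow = nfft %/% 2 + 1, ncol = n_frames)
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * hop + 1L
    seg <- x[i0:min(i0 + nw - 1L, n)]
    if (length(seg) < nw) seg <- c(seg, numeric(nw - length(seg)))
    sp <- stats::fft(c(seg * win, numeric(nfft - nw)))
    out[, k] <- sp[seq_len(nfft %/% 2 + 1)]
  }
  attr(out, "hop") <- hop
  attr(out, "win_length") <- nw
  out
}

# Inverse STFT by windowed overlap-add with squared-window normalization.
istft <- function(S, win, hop, n_out = NULL) {
  nfft <- 2L * (nrow(S) - 1L)
  nw <- length(win)
  n_frames <- ncol(S)
  n <- (n_frames - 1L) * hop + nw
  y <- numeric(n)
  wsum <- numeric(n)
  for (k in seq_len(n_frames)) {
    full <- c(S[, k], Conj(S[seq(nfft %/% 2, 2), k]))
    seg <- Re(stats::fft(full, inverse = TRUE)) / nfft
    idx <- ((k - 1L) * hop + 1L):((k - 1L) * hop + nw)
    y[idx] <- y[idx] + seg[seq_len(nw)] * win
    wsum[idx] <- wsum[idx] + win^2
  }
  y <- y / pmax(wsum, 1e-8)
  if (!is.null(n_out)) {
    y <- if (n_out <= n) y[seq_len(n_out)] else c(y, numeric(n_out - n))
  }
  y
}

# Welch power spectral density estimate (used for broad-band spectrum checks).
welch_psd <- function(x, rate, win_length = 512L, overlap = 0.5) {
  win <- hann(win_length)
  hop <- max(1L, as.integer(round(win_length * (1 - overlap))))
  S <- stft(x, win, hop, win_length)
  psd <- rowMeans(Mod(S)^2) / (sum(win^2) * rate)
  list(freq = seq(0, rate / 2, length.out = nrow(S)), psd = psd)
}
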