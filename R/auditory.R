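#' Cochlear-model auditory spectrograms
#'
#' The auditory spectrogram is a frames x channels matrix of non-negative
#' values produced by a peripheral auditory model: a bank of constant-Q
#' cochlear-like bandpass filters, a hair-cell stage (memoryless sigmoid
#' compression followed by a one-pole low-pass), a lateral inhibitory
#' network (first-order difference across adjacent channels, half-wave
#' rectified), and leaky temporal integration sampled at the frame rate.
#'
#' Defaults: 128 channels spaced 24 per octave from 90 Hz (top centre
#' frequency ~3526 Hz, top filter edge ~3.6 kHz), 8-ms frames, 128-ms
#' integration time constant, 8 kHz input rate. At these defaults one second
#' of audio yields 125 frames x 128 channels = 16000 coefficients.
#'
#' @name auditory_model
NULL

#' Constant-Q channel centre frequencies
#'
#' Geometric progression `f_low * 2^(k / channels_per_octave)` for
#' `k = 0 ... n_channels - 1`.
#'
#' @param n_channels Number of filterbank channels.
#' @param f_low Centre frequency of the lowest channel, Hz.
#' @param channels_per_octave Channel density (default 24).
#' @return Numeric vector of ascending centre frequencies in Hz.
#' @export
channel_center_frequencies <- function(n_channels = 128, f_low = 90,
                                       channels_per_octave = 24) {
  stopifnot(n_channels >= 1, f_low > 0, channels_per_octave > 0)
  f_low * 2^((seq_len(n_channels) - 1) / channels_per_octave)
}

#' Auditory-model configuration
#'
#' Bundles the analysis parameters of the cochlear model. The defaults are
#' the standard configuration: 8 kHz input, 128 channels at 24 per octave
#' from 90 Hz, 8-ms frames, 128-ms integration.
#'
#' @param rate Input sampling rate, Hz.
#' @param n_channels Number of filterbank channels.
#' @param f_low Lowest channel centre frequency, Hz.
#' @param channels_per_octave Channel density.
#' @param frame_length Frame length, seconds.
#' @param time_constant Leaky-integration time constant, seconds.
#' @return A list of model parameters including the channel CFs.
#' @export
aud_config <- function(rate = 8000, n_channels = 128, f_low = 90,
                       channels_per_octave = 24, frame_length = 0.008,
                       time_constant = 0.128) {
  list(rate = rate, n_channels = n_channels, f_low = f_low,
       channels_per_octave = channels_per_octave,
       frame_length = frame_length, time_constant = time_constant,
       cfs = channel_center_frequencies(n_channels, f_low,
                                        channels_per_octave))
}

# Frequency responses of the filterbank: (nfft/2 + 1) x n_channels matrix of
# Gaussian-on-log-frequency magnitude responses, one sigma = one channel
# spacing (in octaves).
filterbank_response <- function(cfg, nfft) {
  freqs <- seq(0, cfg$rate / 2, length.out = nfft %/% 2 + 1)
  # half a channel spacing per sigma: narrow enough that a pure tone's
  # rising-flank response peaks at the nearest channel
  sigma_oct <- 0.5 / cfg$channels_per_octave
  H <- matrix(0, nfft %/% 2 + 1, cfg$n_channels)
  lf <- c(-Inf, log2(freqs[-1]))
  for (k in seq_len(cfg$n_channels)) {
    H[, k] <- exp(-0.5 * ((lf - log2(cfg$cfs[k])) / sigma_oct)^2)
  }
  H[1, ] <- 0
  H
}

# Subband decomposition via FFT filtering: n x n_channels matrix.
subband_filter <- function(x, cfg, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- next_pow2(n + cfg$rate %/% 8)  # guard tail
  H <- filterbank_response(cfg, nfft)
  X <- stats::fft(c(x, numeric(nfft - n)))
  half <- nfft %/% 2 + 1
  out <- matrix(0, n, cfg$n_channels)
  for (k in seq_len(cfg$n_channels)) {
    Y <- numeric(nfft) + 0i
    Y[seq_len(half)] <- X[seq_len(half)] * H[, k]
    Y[seq(nfft, half + 1)] <- Conj(Y[seq(2, half - 1)])
    out[, k] <- Re(stats::fft(Y, inverse = TRUE))[seq_len(n)] / nfft
  }
  out
}

# Hair cell + lateral inhibition + leaky integration + frame sampling,
# applied to a subband matrix. Returns frames x channels.
spectrogram_stages <- function(S, cfg) {
  n <- nrow(S)
  # hair cell: sigmoid compression then one-pole low-pass (~1 kHz)
  Hc <- tanh(S)
  a1 <- exp(-2 * pi * 1000 / cfg$rate)
  Hc <- apply(Hc, 2, function(col)
    as.numeric(stats::filter((1 - a1) * col, a1, method = "recursive")))
  # lateral inhibition across channels, half-wave rectified
  D <- Hc - cbind(0, Hc[, -ncol(Hc), drop = FALSE])
  D[D < 0] <- 0
  # leaky integration (time constant cfg$time_constant) sampled every frame
  a2 <- exp(-1 / (cfg$time_constant * cfg$rate))
  Y <- apply(D, 2, function(col)
    as.numeric(stats::filter((1 - a2) * col, a2, method = "recursive")))
  flen <- round(cfg$frame_length * cfg$rate)
  n_frames <- as.integer(ceiling(n / flen))
  idx <- pmin(seq_len(n_frames) * flen, n)
  out <- Y[idx, , drop = FALSE]
  structure(out,
            class = c("aud_spec", "matrix"),
            frame_length = cfg$frame_length,
            time_constant = cfg$time_constant,
            channel_cfs = cfg$cfs,
            source_rate = cfg$rate)
}

#' Compute the auditory spectrogram of a waveform
#'
#' @param w A [waveform], already resampled to `cfg$rate` (8 kHz by default;
#'   a mismatching rate is an error, not silently resampled).
#' @param cfg Model configuration from `aud_config()`; defaults reproduce
#'   the standard 128-channel, 8-ms, 128-ms model.
#' @return A `frames x channels` matrix of class `aud_spec` with attributes
#'   `frame_length`, `time_constant`, `channel_cfs`, `source_rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 1000 * seq_len(8000) / 8000), 8000)
#' dim(auditory_spectrogram(w))  # 125 x 128
#' @export
auditory_spectrogram <- function(w, cfg = aud_config()) {
  stopifnot(inherits(w, "waveform"))
  if (!isTRUE(all.equal(w$rate, cfg$rate))) {
    stop(sprintf("auditory_spectrogram expects input at %g Hz, got %g Hz; resample first",
                 cfg$rate, w$rate))
  }
  if (length(w$samples) == 0) stop("empty waveform")
  S <- subband_filter(w$samples, cfg)
  spectrogram_stages(S, cfg)
}

#' Invert an auditory spectrogram back to a waveform
#'
#' Iterative magnitude projection. The estimate is initialized as a bank of
#' sinusoids at the channel centre frequencies, each carrying the target
#' channel's (interpolated) frame envelope, with seeded random phases and a
#' low-level seeded noise floor. Each iteration analyzes the estimate with
#' the same model, applies smoothly interpolated per-channel gains
#' `target / current` to its subband signals, and resums. The iterate with
#' the lowest relative Frobenius reconstruction error is returned, so
#' reconstruction error is non-increasing in `n_iterations`.
#'
#' @param s An `aud_spec` matrix (frames x channels).
#' @param n_iterations Maximum number of projection iterations (default 50).
#' @param seed RNG seed for initial phases and the noise floor.
#' @param tol Early stop when the relative error improves by less than this.
#' @param cfg Model configuration; must match the one used for analysis.
#' @param init Optional [waveform] used as the starting estimate instead of
#'   the sine bank (an analysis-by-synthesis warm start; the projection
#'   still converges to the given spectrogram). Must be at `cfg$rate`.
#' @return A [waveform] at the spectrogram's source rate whose duration
#'   matches the spectrogram's time span.
#' @export
invert_auditory_spectrogram <- function(s, n_iterations = 50, seed = 0,
                                        tol = 1e-4, cfg = aud_config(),
                                        init = NULL) {
  stopifnot(n_iterations >= 1)
  if (length(s) == 0 || nrow(s) == 0) stop("empty spectrogram")
  n_frames <- nrow(s)
  flen <- round(cfg$frame_length * cfg$rate)
  n <- n_frames * flen
  target <- unclass(s)
  tnorm <- sqrt(sum(target^2))
  if (tnorm == 0) return(waveform(numeric(n), cfg$rate))
  t_frames <- (seq_len(n_frames) - 0.5) * flen   # frame centres, samples
  if (!is.null(init)) {
    stopifnot(inherits(init, "waveform"))
    if (!isTRUE(all.equal(init$rate, cfg$rate))) {
      stop("init waveform must be at the model rate")
    }
    x <- init$samples
    x <- if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
  } else {
    # sine-bank initialization: coherent carriers avoid the
    # phase-incoherent fixed points that a pure noise start converges to
    phases <- with_seed(seed, stats::runif(cfg$n_channels, 0, 2 * pi))
    tt <- seq_len(n) / cfg$rate
    x <- numeric(n)
    for (k in seq_len(cfg$n_channels)) {
      if (max(target[, k]) <= 0) next
      a <- stats::approx(t_frames, target[, k], xout = seq_len(n), rule = 2)$y
      x <- x + a * cos(2 * pi * cfg$cfs[k] * tt + phases[k])
    }
    x <- x / max(max(abs(x)), 1e-12) * 0.5
    x <- x + with_seed(seed + 1, stats::rnorm(n)) * 0.005
  }
  delta <- 1e-3 * max(target)
  best <- list(err = Inf, x = x, it = 0L)
  for (it in seq_len(n_iterations)) {
    SB <- subband_filter(x, cfg)
    A <- unclass(spectrogram_stages(SB, cfg))
    err <- sqrt(sum((A - target)^2)) / tnorm
    if (err < best$err - tol) best <- list(err = err, x = x, it = it)
    else if (err < best$err) best[c("err", "x")] <- list(err, x)
    # patience: stop when the best error has not improved by tol in 8 rounds
    if (it - best$it >= 8L) break
    G <- (target + delta) / (A + delta)
    G[G < 0.2] <- 0.2
    G[G > 5] <- 5
    Gs <- apply(G, 2, function(g)
      stats::approx(t_frames, g, xout = seq_len(n), rule = 2)$y)
    x <- rowSums(SB * Gs)
    peak <- max(abs(x))
    if (peak > 4) x <- x * 4 / peak
  }
  waveform(best$x, cfg$rate)
}

#' @export
print.aud_spec <- function(x, ...) {
  cat(sprintf("<aud_spec> %d frames x %d channels (%.0f ms frames, %g-%g Hz)\n",
              nrow(x), ncol(x), attr(x, "frame_length") * 1000,
              min(attr(x, "channel_cfs")), max(attr(x, "channel_cfs"))))
  invisible(x)
}

# Relative Frobenius error between a spectrogram and the spectrogram of a
# waveform (utility used by tests and the inversion's contract).
spectrogram_error <- function(s, w, cfg = aud_config()) {
  a <- unclass(auditory_spectrogram(w, cfg))
  t <- unclass(s)
  fr <- min(nrow(a), nrow(t))
  sqrt(sum((a[seq_len(fr), ] - t[seq_len(fr), ])^2)) /
    max(sqrt(sum(t^2)), .Machine$double.eps)
}
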