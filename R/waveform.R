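#' Waveform objects
#'
#' A `waveform` is the carrier for all audio in the package: a numeric vector
#' of dimensionless amplitudes (nominally in \[-1, 1\]) together with its
#' sampling rate in Hz.
#'
#' @param samples Numeric vector of finite sample amplitudes.
#' @param rate Sampling rate in samples per second (Hz), > 0.
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' wave_duration(w)
#' @export
waveform <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(rate) == 1, rate > 0)
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "waveform")
}

#' @rdname waveform
#' @param w A `waveform`.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), rms %.4g\n",
              length(x$samples), x$rate, wave_duration(x),
              rms(x$samples)))
  invisible(x)
}

#' Read a mono waveform from a WAV file
#'
#' Reads RIFF/WAVE files containing 16-bit PCM or 32-bit IEEE float samples.
#' Multi-channel files are down-mixed to mono by averaging channels.
#'
#' @param path Path to a WAV file.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        code = sum(as.integer(raw_fmt[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(raw_fmt[3:4]) * c(1, 256)),
        rate = sum(as.integer(raw_fmt[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw_fmt[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk")
      if (fmt$code == 1 && fmt$bits == 16) {
        x <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                     endian = "little") / 32768
      } else if (fmt$code == 3 && fmt$bits == 32) {
        x <- readBin(con, "double", sz / 4, 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                     fmt$code, fmt$bits))
      }
      if (fmt$n_channels > 1) {
        x <- colMeans(matrix(x, nrow = fmt$n_channels))
      }
      return(waveform(x, fmt$rate))
    } else {
      readBin(con, "raw", sz + (sz %% 2))
    }
  }
}

#' Write a waveform to a WAV file
#'
#' @param path Output path.
#' @param w A [waveform].
#' @param bit_depth 16 (PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, w, bit_depth = 16) {
  stopifnot(inherits(w, "waveform"), bit_depth %in% c(16, 32))
  n <- length(w$samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  code <- if (bit_depth == 16) 1L else 3L
  writeBin(c(code, 1L), con, 2, endian = "little")       # format, mono
  writeBin(as.integer(round(w$rate)), con, 4, endian = "little")
  writeBin(as.integer(round(w$rate) * bytes_per), con, 4, endian = "little")
  writeBin(c(as.integer(bytes_per), as.integer(bit_depth)), con, 2,
           endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16) {
    q <- as.integer(pmax(pmin(round(w$samples * 32768), 32767), -32768))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(w$samples, con, 4, endian = "little")
  }
  invisible(path)
}

#' Resample a waveform to a new rate
#'
#' Band-limited (anti-aliased) polyphase resampling via [signal::resample()].
#' Duration is preserved to within one sample period.
#'
#' @param w A [waveform].
#' @param target_rate Target sampling rate in Hz.
#' @return A [waveform] at `target_rate`.
#' @export
resample <- function(w, target_rate) {
  stopifnot(inherits(w, "waveform"), target_rate > 0)
  if (isTRUE(all.equal(w$rate, target_rate))) return(w)
  # rational approximation of the rate ratio
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  p <- round(target_rate)
  q <- round(w$rate)
  if (abs(p - target_rate) > 1e-9 || abs(q - w$rate) > 1e-9) {
    frac <- (target_rate / w$rate) * 1e6
    p <- round(frac); q <- 1e6
  }
  d <- g(p, q)
  y <- signal::resample(w$samples, p / d, q / d)
  n_target <- round(length(w$samples) * target_rate / w$rate)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  waveform(y, target_rate)
}

#' Time-stretch a waveform with a phase vocoder
#'
#' Stretches (or compresses) a signal to a target duration while preserving
#' its spectral content (no pitch shift), using an STFT phase vocoder with
#' standard phase propagation. The analysis window is 1024 samples at rates
#' up to 16 kHz and 2048 above, with 75% overlap.
#'
#' @param w A [waveform].
#' @param target_duration_s Desired output duration in seconds.
#' @return A [waveform] of duration `target_duration_s` (within one hop).
#' @export
time_stretch <- function(w, target_duration_s) {
  stopifnot(inherits(w, "waveform"), target_duration_s > 0)
  n <- length(w$samples)
  N <- if (w$rate <= 16000) 1024L else 2048L
  if (n < N) stop("input shorter than one analysis window (", N, " samples)")
  n_target <- round(target_duration_s * w$rate)
  Hs <- N %/% 4L
  factor <- n_target / n
  Ha <- Hs / factor
  win <- hann(N)
  K <- max(1L, as.integer(ceiling((n_target - N) / Hs)) + 1L)
  omega <- 2 * pi * (0:(N %/% 2)) / N         # bin frequencies, rad/sample
  y <- numeric((K - 1L) * Hs + N)
  wsum <- numeric(length(y))
  spec_at <- function(pos) {
    seg <- w$samples[pos:(pos + N - 1L)]
    stats::fft(seg * win)[seq_len(N %/% 2 + 1)]
  }
  pos_prev <- 1L
  X_prev <- spec_at(pos_prev)
  psi <- Arg(X_prev)
  for (k in seq_len(K)) {
    if (k == 1L) {
      Y <- X_prev
    } else {
      pos <- min(as.integer(round((k - 1) * Ha)) + 1L, n - N + 1L)
      X <- spec_at(pos)
      dp <- pos - pos_prev
      if (dp < 1L) dp <- 1L
      dphi <- Arg(X) - Arg(X_prev) - omega * dp
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      inst <- omega + dphi / dp
      psi <- psi + inst * Hs
      Y <- Mod(X) * exp(1i * psi)
      X_prev <- X
      pos_prev <- pos
    }
    full <- c(Y, Conj(Y[seq(N %/% 2, 2)]))
    seg <- Re(stats::fft(full, inverse = TRUE)) / N
    idx <- ((k - 1L) * Hs + 1L):((k - 1L) * Hs + N)
    y[idx] <- y[idx] + seg * win
    wsum[idx] <- wsum[idx] + win^2
  }
  y <- y / pmax(wsum, 1e-8)
  y <- if (length(y) >= n_target) y[seq_len(n_target)] else
    c(y, numeric(n_target - length(y)))
  waveform(y, w$rate)
}

#' Equalize the RMS level of a waveform
#'
#' Scales a signal so its RMS level equals a target in dBFS (dB re full
#' scale, where a full-scale sine has RMS level ~ -3 dBFS). The operation is
#' a pure gain: waveform shape is unchanged, and it is idempotent.
#'
#' @param w A [waveform] with non-zero energy.
#' @param target_dbfs Target RMS level in dBFS (e.g. -20).
#' @return The scaled [waveform].
#' @export
equalize_level <- function(w, target_dbfs = -20) {
  stopifnot(inherits(w, "waveform"))
  r <- rms(w$samples)
  if (r == 0) stop("cannot equalize an all-zero waveform (undefined gain)")
  waveform(w$samples * undb(target_dbfs) / r, w$rate)
}
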