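#' Tonal/noise decomposition by sinusoidal partial tracking
#'
#' Separates a waveform into a tonal component (a sum of tracked sinusoidal
#' partials) and a noise component (the time-domain residual). Partials are
#' found by STFT peak picking and frame-to-frame frequency continuation;
#' the tonal component is resynthesized by windowed overlap-add of the
#' measured per-frame amplitude, frequency and phase, so the residual
#' `input - tonal` is exact by construction.
#'
#' @name decompose
NULL

#' Partial-tracking configuration
#'
#' @param win_s Analysis window length in seconds (Hann; default 46 ms).
#' @param rel_threshold_db Peaks below this level relative to the frame
#'   maximum are ignored (default -50 dB).
#' @param salience_db Peaks must exceed the frame's median spectral
#'   magnitude by this many dB; suppresses spurious peaks in broadband
#'   noise (default 12 dB).
#' @param max_jump_hz Maximum frequency change between consecutive frames
#'   for a track to continue (default 50 Hz).
#' @param min_track_frames Minimum track length in frames (default 4).
#' @param f_max Partials above this frequency are ignored (default 4000 Hz).
#' @return A list of tracking parameters.
#' @export
partial_config <- function(win_s = 0.046, rel_threshold_db = -50,
                           salience_db = 12, max_jump_hz = 50,
                           min_track_frames = 4, f_max = 4000) {
  list(win_s = win_s, rel_threshold_db = rel_threshold_db,
       salience_db = salience_db, max_jump_hz = max_jump_hz,
       min_track_frames = min_track_frames, f_max = f_max)
}

# Pick salient spectral peaks in one magnitude frame.
# Returns data.frame(freq, amp, phase) using parabolic interpolation on
# log-magnitude. `X` is the complex half-spectrum of a zero-phase-windowed
# frame, `wsum` the window sum for amplitude scaling.
pick_peaks <- function(X, rate, nfft, wsum, cfg) {
  mag <- Mod(X)
  n <- length(mag)
  if (n < 3) return(data.frame(freq = numeric(0), amp = numeric(0),
                               phase = numeric(0)))
  mid <- mag[2:(n - 1)]
  is_peak <- mid > mag[1:(n - 2)] & mid >= mag[3:n] & mid > 0
  floor_abs <- max(mag) * undb(cfg$rel_threshold_db)
  floor_sal <- stats::median(mag) * undb(cfg$salience_db)
  idx <- which(is_peak & mid >= max(floor_abs, floor_sal)) + 1L
  if (!length(idx)) return(data.frame(freq = numeric(0), amp = numeric(0),
                                      phase = numeric(0)))
  lm <- log(pmax(mag, 1e-300))
  a <- lm[idx - 1L]; b <- lm[idx]; c <- lm[idx + 1L]
  denom <- a - 2 * b + c
  d <- ifelse(abs(denom) > 1e-12, 0.5 * (a - c) / denom, 0)
  d <- pmax(pmin(d, 0.5), -0.5)
  freq <- (idx - 1 + d) * rate / nfft
  amp <- exp(b - 0.25 * (a - c) * d) * 2 / wsum
  keep <- freq > 0 & freq < min(cfg$f_max, rate / 2)
  data.frame(freq = freq[keep], amp = amp[keep],
             phase = Arg(X)[idx[keep]])
}

#' Track sinusoidal partials
#'
#' @param w A [waveform].
#' @param cfg Tracking parameters from [partial_config()].
#' @return A list of tracks, each a data.frame with columns `frame`, `time`
#'   (seconds, frame centre), `freq` (Hz), `amp` (linear), `phase`
#'   (radians at frame centre). The empty list is a valid result.
#' @export
track_partials <- function(w, cfg = partial_config()) {
  stopifnot(inherits(w, "waveform"))
  N <- 2L * (as.integer(round(cfg$win_s * w$rate)) %/% 2L)
  hop <- N %/% 4L
  if (length(w$samples) < 4L * N) {
    stop("input too short for partial tracking (need >= 4 analysis windows)")
  }
  nfft <- next_pow2(2L * N)
  win <- blackman_harris(N)
  wsum <- sum(win)
  n <- length(w$samples)
  n_frames <- (n - N) %/% hop + 1L
  active <- list()   # open tracks: list(rows = data.frame)
  done <- list()
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * hop + 1L
    seg <- w$samples[i0:(i0 + N - 1L)] * win
    seg <- c(seg[(N %/% 2 + 1):N], numeric(nfft - N), seg[1:(N %/% 2)])
    X <- stats::fft(seg)[seq_len(nfft %/% 2 + 1)]
    pk <- pick_peaks(X, w$rate, nfft, wsum, cfg)
    t_center <- (i0 - 1 + N / 2) / w$rate
    used <- rep(FALSE, nrow(pk))
    keep_active <- list()
    for (tr in active) {
      last <- tr[nrow(tr), ]
      if (nrow(pk)) {
        dist <- abs(pk$freq - last$freq)
        dist[used] <- Inf
        j <- which.min(dist)
        if (length(j) && dist[j] <= cfg$max_jump_hz) {
          used[j] <- TRUE
          tr <- rbind(tr, data.frame(frame = k, time = t_center,
                                     freq = pk$freq[j], amp = pk$amp[j],
                                     phase = pk$phase[j]))
          keep_active[[length(keep_active) + 1L]] <- tr
          next
        }
      }
      done[[length(done) + 1L]] <- tr
    }
    if (nrow(pk)) {
      for (j in which(!used)) {
        keep_active[[length(keep_active) + 1L]] <-
          data.frame(frame = k, time = t_center, freq = pk$freq[j],
                     amp = pk$amp[j], phase = pk$phase[j])
      }
    }
    active <- keep_active
  }
  done <- c(done, active)
  done <- Filter(function(tr) nrow(tr) >= cfg$min_track_frames, done)
  lapply(done, function(tr) { rownames(tr) <- NULL; tr })
}

# Resynthesize tracked partials by windowed overlap-add: each frame
# contributes a Hann-windowed sinusoid with the measured frequency,
# amplitude and phase at the frame centre.
synthesize_partials <- function(tracks, n, rate, cfg = partial_config()) {
  N <- 2L * (as.integer(round(cfg$win_s * rate)) %/% 2L)
  win <- hann(N)
  y <- numeric(n)
  half <- N %/% 2
  rel_t <- (seq_len(N) - 1 - half) / rate   # time re: frame centre
  for (tr in tracks) {
    # each track is overlap-added and normalized by its own window sum, so
    # simultaneous tracks do not dilute one another
    yt <- numeric(n)
    wsum <- numeric(n)
    for (r in seq_len(nrow(tr))) {
      tc <- tr$time[r]
      i0 <- as.integer(round(tc * rate)) - half + 1L
      idx <- i0:(i0 + N - 1L)
      ok <- idx >= 1L & idx <= n
      if (!any(ok)) next
      s <- tr$amp[r] * cos(2 * pi * tr$freq[r] * rel_t + tr$phase[r]) * win
      yt[idx[ok]] <- yt[idx[ok]] + s[ok]
      wsum[idx[ok]] <- wsum[idx[ok]] + win[ok]
    }
    y <- y + yt / pmax(wsum, 1)
  }
  y
}

#' Energy ratio between two waveforms in dB
#'
#' `10 * log10(sum(a^2) / sum(b^2))`. A zero-energy `b` yields `+Inf` with
#' a warning.
#'
#' @param a,b [waveform]s of equal length.
#' @return Ratio in dB.
#' @export
energy_ratio_db <- function(a, b) {
  stopifnot(inherits(a, "waveform"), inherits(b, "waveform"),
            length(a$samples) == length(b$samples))
  eb <- sum(b$samples^2)
  if (eb == 0) {
    warning("zero-energy denominator; returning +Inf")
    return(Inf)
  }
  10 * log10(sum(a$samples^2) / eb)
}

#' Separate a waveform into tonal and noise components
#'
#' @param w A [waveform].
#' @param cfg Tracking parameters from [partial_config()].
#' @return An object of class `decomposition`: a list with `tonal` and
#'   `noise` [waveform]s (equal length; their sum reconstructs the input
#'   exactly), the partial `tracks`, and `tonal_noise_ratio_db`.
#' @export
separate <- function(w, cfg = partial_config()) {
  tracks <- track_partials(w, cfg)
  n <- length(w$samples)
  tonal <- synthesize_partials(tracks, n, w$rate, cfg)
  noise <- w$samples - tonal
  tw <- waveform(tonal, w$rate)
  nw <- waveform(noise, w$rate)
  ratio <- if (sum(noise^2) == 0 && sum(tonal^2) == 0) 0 else
    suppressWarnings(energy_ratio_db(tw, nw))
  structure(list(tonal = tw, noise = nw, tracks = tracks,
                 tonal_noise_ratio_db = ratio),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d tracks, tonal/noise ratio %.2f dB\n",
              length(x$tracks), x$tonal_noise_ratio_db))
  invisible(x)
}
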