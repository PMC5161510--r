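#' Two-piece linear regression
#'
#' Fits two independent ordinary-least-squares lines split at the interior
#' breakpoint minimizing the total squared error (exhaustive search over
#' candidates with at least two points per piece). A constant series is a
#' perfect fit by definition (`slope1 = slope2 = 0`, `r2 = 1`).
#'
#' @param y Numeric response series (>= 4 points).
#' @param x Time stamps; defaults to `seq_along(y)`.
#' @return A list: `slope1`, `slope2`, `breakpoint` (the x value of the
#'   last point of the first piece), `r2` (on the joint model).
#' @export
two_piece_fit <- function(y, x = seq_along(y)) {
  stopifnot(length(y) >= 4, length(x) == length(y))
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  fit_piece <- function(ix) {
    xi <- x[ix]; yi <- y[ix]
    b <- stats::cov(xi, yi) / max(stats::var(xi), .Machine$double.eps)
    a <- mean(yi) - b * mean(xi)
    list(slope = b, sse = sum((yi - a - b * xi)^2))
  }
  if (sst == 0) {
    return(list(slope1 = 0, slope2 = 0, breakpoint = x[n %/% 2], r2 = 1))
  }
  best <- NULL
  for (i in 2:(n - 2)) {
    f1 <- fit_piece(1:i)
    f2 <- fit_piece((i + 1):n)
    sse <- f1$sse + f2$sse
    if (is.null(best) || sse < best$sse) {
      best <- list(slope1 = f1$slope, slope2 = f2$slope,
                   breakpoint = x[i], sse = sse)
    }
  }
  list(slope1 = best$slope1, slope2 = best$slope2,
       breakpoint = best$breakpoint, r2 = max(0, 1 - best$sse / sst))
}

# Autocorrelation pitch and pitch-strength estimate for one frame.
# Normalized autocorrelation peak in the candidate lag range; strength is
# the peak value in [0, 1].
frame_pitch <- function(x, rate, f_min = 60, f_max = 2000) {
  n <- length(x)
  x <- x - mean(x)
  e0 <- sum(x^2)
  if (e0 <= 0) return(c(pitch = 0, strength = 0))
  lmin <- max(2L, as.integer(floor(rate / f_max)))
  lmax <- min(n - 2L, as.integer(ceiling(rate / f_min)))
  if (lmax <= lmin) return(c(pitch = 0, strength = 0))
  ac <- vapply(lmin:lmax, function(l)
    sum(x[1:(n - l)] * x[(1 + l):n]) /
      sqrt(sum(x[1:(n - l)]^2) * sum(x[(1 + l):n]^2) + 1e-300),
    numeric(1))
  # periodic signals peak at every multiple of the period: take the
  # smallest *local maximum* within tolerance of the global maximum
  # (octave guard)
  la <- length(ac)
  is_pk <- c(FALSE, ac[2:(la - 1)] > ac[1:(la - 2)] &
               ac[2:(la - 1)] >= ac[3:la], FALSE)
  pk <- which(is_pk & ac >= 0.9 * max(ac) & ac > 0)
  if (!length(pk)) pk <- which.max(ac)
  j <- pk[1]
  lag <- lmin + j - 1L
  # parabolic refinement
  if (j > 1 && j < length(ac)) {
    a <- ac[j - 1]; b <- ac[j]; c <- ac[j + 1]
    den <- a - 2 * b + c
    if (abs(den) > 1e-12) lag <- lag + max(min(0.5 * (a - c) / den, 0.5), -0.5)
  }
  c(pitch = rate / lag, strength = max(0, min(1, max(ac))))
}

# Frame-wise descriptor series used by extract_features.
feature_frames <- function(w, d, win_s = 0.046) {
  rate <- w$rate
  N <- 2L * (as.integer(round(win_s * rate)) %/% 2L)
  hop <- N %/% 4L
  x <- w$samples
  n <- length(x)
  n_frames <- max(1L, (n - N) %/% hop + 1L)
  nfft <- next_pow2(N)
  win <- hann(N)
  freqs <- seq(0, rate / 2, length.out = nfft %/% 2 + 1)
  out <- data.frame(time = numeric(n_frames), amp = NA_real_,
                    loud_db = NA_real_, zcr = NA_real_, centroid = NA_real_,
                    peak_freq = NA_real_, pitch = NA_real_,
                    strength = NA_real_, noisiness = NA_real_)
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * hop + 1L
    idx <- i0:(i0 + N - 1L)
    seg <- x[idx]
    out$time[k] <- (i0 - 1 + N / 2) / rate
    a <- rms(seg)
    out$amp[k] <- a
    out$loud_db[k] <- db(max(a, 1e-10))
    out$zcr[k] <- sum(abs(diff(sign(seg))) > 0) / (N / rate)
    mag <- Mod(stats::fft(c(seg * win, numeric(nfft - N)))[seq_len(nfft %/% 2 + 1)])
    if (sum(mag) > 0) {
      out$centroid[k] <- sum(freqs * mag) / sum(mag)
      out$peak_freq[k] <- freqs[which.max(mag)]
    } else {
      out$centroid[k] <- 0; out$peak_freq[k] <- 0
    }
    fp <- frame_pitch(seg, rate)
    out$pitch[k] <- fp["pitch"]
    out$strength[k] <- fp["strength"]
    et <- sum(d$tonal$samples[idx]^2)
    en <- sum(d$noise$samples[idx]^2)
    # noise/harmonic ratio, regularized by 1% of frame energy so pure
    # noise or pure tone frames stay on a usable scale (~[0.01, 100])
    reg <- 0.01 * (et + en) + 1e-12
    out$noisiness[k] <- (en + reg) / (et + reg)
  }
  out
}

#' Extract the 13 summary features of a waveform
#'
#' Thirteen descriptors summarizing a sound's temporal and spectral
#' behaviour: counts and durations of active regions (frames within 40 dB
#' of the loudest frame); medians across active frames of noisiness
#' (noise/tonal energy ratio), zero-crossing rate, pitch strength, pitch
#' (gated at strength > 0.2), and loudness; the standard deviations of
#' pitch and spectral centroid; and, from two-piece linear fits to the
#' amplitude envelope and the main-spectral-peak series, the second-piece
#' slopes and the amplitude fit's goodness of fit.
#'
#' @param w A [waveform].
#' @param d A [separate()] decomposition of `w` (for noisiness); computed
#'   if omitted.
#' @param active_floor_db Frames quieter than the maximum by more than
#'   this are inactive (default 40 dB).
#' @return A named numeric vector of 13 features.
#' @export
extract_features <- function(w, d = NULL, active_floor_db = 40) {
  if (is.null(d)) d <- separate(w)
  fr <- feature_frames(w, d)
  act <- fr$loud_db > max(fr$loud_db) - active_floor_db
  regions <- sum(diff(c(FALSE, act)) == 1)
  hop_s <- if (nrow(fr) > 1) diff(fr$time[1:2]) else wave_duration(w)
  abs_dur <- sum(act) * hop_s
  rel_dur <- min(1, abs_dur / wave_duration(w))
  af <- fr[act, , drop = FALSE]
  voiced <- af$strength > 0.2
  med_pitch <- if (any(voiced)) stats::median(af$pitch[voiced]) else 0
  sd_pitch <- if (sum(voiced) > 1) stats::sd(af$pitch[voiced]) else 0
  amp_fit <- if (nrow(af) >= 4) two_piece_fit(af$amp / max(af$amp), af$time)
             else list(slope2 = 0, r2 = 1)
  pk_fit <- if (nrow(af) >= 4) two_piece_fit(af$peak_freq, af$time)
            else list(slope2 = 0)
  c(n_active_regions = regions,
    absolute_duration = abs_dur,
    relative_duration = rel_dur,
    median_noisiness = stats::median(af$noisiness),
    median_zcr = stats::median(af$zcr),
    median_pitch_strength = stats::median(af$strength),
    median_pitch = med_pitch,
    median_loudness = stats::median(af$loud_db),
    sd_pitch = sd_pitch,
    sd_spectral_centroid = if (nrow(af) > 1) stats::sd(af$centroid) else 0,
    amp_slope2 = amp_fit$slope2,
    specpeak_slope2 = pk_fit$slope2,
    amp_fit_r2 = amp_fit$r2)
}

#' Standardizer over a feature set
#'
#' Per-feature mean and standard deviation estimated over a stimulus set
#' (rows = sounds, columns = the 13 features). Fit it on the pooled set
#' under analysis so all sounds share one feature scaling.
#'
#' @param feature_matrix Numeric matrix or data.frame of feature vectors.
#' @return An object of class `standardizer` (lists `mean` and `sd`).
#' @export
feature_standardizer <- function(feature_matrix) {
  m <- as.matrix(feature_matrix)
  structure(list(mean = colMeans(m), sd = apply(m, 2, stats::sd)),
            class = "standardizer")
}

#' Euclidean distance between standardized feature vectors
#'
#' Features with degenerate (zero or non-finite) standard deviation in the
#' standardizer are dropped with a warning.
#'
#' @param a,b Feature vectors from [extract_features()].
#' @param z A [feature_standardizer()].
#' @return Non-negative distance; 0 iff the standardized vectors coincide.
#' @export
feature_distance <- function(a, b, z) {
  stopifnot(inherits(z, "standardizer"))
  ok <- is.finite(z$sd) & z$sd > 0
  if (!all(ok)) {
    warning("dropping degenerate features: ",
            paste(names(z$sd)[!ok], collapse = ", "))
  }
  za <- (a[ok] - z$mean[ok]) / z$sd[ok]
  zb <- (b[ok] - z$mean[ok]) / z$sd[ok]
  sqrt(sum((za - zb)^2))
}
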