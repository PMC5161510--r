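#' Quality presets for auditory sketches
#'
#' Three preset quality levels trade coefficient budget for fidelity. The
#' tonal path keeps `coeffs_per_second` cells of the auditory spectrogram
#' (full representation: 16000/s); the noise path uses an all-pole (LPC)
#' model of order `lpc_order` refit every `lpc_hop` seconds with 75%
#' frame overlap, so its own coefficient rate `lpc_order / lpc_hop`
#' matches the tonal budget.
#'
#' @return A named list of `sketch_params` objects for Q1, Q2, Q3, each
#'   with fields `quality`, `coeffs_per_second`, `lpc_order`, `lpc_hop`,
#'   `lpc_overlap`.
#' @examples
#' quality_presets()$Q2$coeffs_per_second  # 800
#' @export
quality_presets <- function() {
  mk <- function(q, cps, p, hop) {
    structure(list(quality = q, coeffs_per_second = cps, lpc_order = p,
                   lpc_hop = hop, lpc_overlap = 0.75),
              class = "sketch_params")
  }
  list(Q1 = mk("Q1", 160, 7, 0.044),
       Q2 = mk("Q2", 800, 16, 0.020),
       Q3 = mk("Q3", 4000, 36, 0.009))
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf("<sketch_params> %s: %d coeffs/s tonal; LPC order %d @ %g ms (%.0f/s)\n",
              x$quality, x$coeffs_per_second, x$lpc_order, x$lpc_hop * 1000,
              x$lpc_order / x$lpc_hop))
  invisible(x)
}

#' Sparsify an auditory spectrogram by maximum picking
#'
#' Within each non-overlapping one-second block of frames, the
#' `round(budget x block duration)` largest-magnitude cells are kept at
#' their original values and all other cells are zeroed. Ties are broken
#' deterministically by lower frame index, then lower channel index. A
#' budget of at least one cell per cell available returns the input
#' unchanged.
#'
#' @param s An `aud_spec` matrix.
#' @param coeffs_per_second Number of cells to keep per second.
#' @return A sparse `aud_spec` of the same shape and attributes.
#' @export
max_pick <- function(s, coeffs_per_second) {
  stopifnot(coeffs_per_second >= 1)
  frame_length <- attr(s, "frame_length")
  frames_per_block <- max(1L, as.integer(round(1 / frame_length)))
  n_frames <- nrow(s)
  out <- unclass(s)
  vals <- unclass(s)
  for (b0 in seq(1L, n_frames, by = frames_per_block)) {
    b1 <- min(b0 + frames_per_block - 1L, n_frames)
    block <- vals[b0:b1, , drop = FALSE]
    k <- as.integer(round(coeffs_per_second * nrow(block) * frame_length))
    if (k >= length(block)) next
    fr <- as.vector(row(block))
    ch <- as.vector(col(block))
    ord <- order(-as.vector(block), fr, ch)
    keep <- ord[seq_len(max(k, 0L))]
    z <- matrix(0, nrow(block), ncol(block))
    z[cbind(fr[keep], ch[keep])] <- block[cbind(fr[keep], ch[keep])]
    out[b0:b1, ] <- z
  }
  attributes(out) <- attributes(s)
  out
}

# Levinson-Durbin recursion: autocorrelation r[0..p] -> AR coefficients
# a[1..p] (prediction x[t] ~ sum a_i x[t-i]) and residual variance.
levinson <- function(r, p) {
  a <- numeric(p)
  e <- r[1]
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[1:(i - 1)] * r[i:2])
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[1:(i - 1)] <- a[1:(i - 1)] - k * a[(i - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) { e <- .Machine$double.eps; break }
  }
  list(a = a, var = e)
}

# Fit LPC to a (already windowed) frame by the autocorrelation method.
lpc_fit <- function(x, p) {
  n <- length(x)
  r <- vapply(0:p, function(l) sum(x[1:(n - l)] * x[(1 + l):n]), numeric(1))
  r[1] <- r[1] + 1e-9          # regularization
  levinson(r, p)
}

#' Sketch the noise component with frame-wise LPC
#'
#' Each analysis frame (length `4 x lpc_hop`, 75% overlap) is modelled by
#' an all-pole filter of order `lpc_order`; seeded white noise is passed
#' through the filter, scaled to the frame's RMS, and the frames are
#' overlap-added with squared-window normalization (incoherent frames add
#' in power, so the energy normalizer is `sqrt` of the window-square sum).
#'
#' @param noise A [waveform] (the noise component, at any rate).
#' @param params A `sketch_params` preset.
#' @param seed RNG seed for the white-noise excitation.
#' @return A [waveform] of the same length and rate.
#' @export
sketch_noise <- function(noise, params, seed = 0) {
  stopifnot(inherits(noise, "waveform"), inherits(params, "sketch_params"))
  n <- length(noise$samples)
  if (n == 0) stop("empty input")
  rate <- noise$rate
  hop <- max(1L, as.integer(round(params$lpc_hop * rate)))
  N <- as.integer(round(hop / (1 - params$lpc_overlap)))
  p <- params$lpc_order
  if (N < 2 * p) {
    stop(sprintf("LPC frame (%d samples) shorter than 2 x order (%d); use a larger hop or smaller order",
                 N, p))
  }
  if (n < N) {
    pad <- N - n
    noise <- waveform(c(noise$samples, numeric(pad)), rate)
  }
  x <- noise$samples
  win <- hann(N)
  n_frames <- max(1L, (length(x) - N) %/% hop + 1L)
  # independent excitation per frame: overlapping frames must be
  # incoherent for the squared-window overlap-add to preserve power
  excite <- matrix(with_seed(seed, stats::rnorm(n_frames * N)), nrow = N)
  y <- numeric(length(x))
  w2 <- numeric(length(x))
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * hop + 1L
    idx <- i0:(i0 + N - 1L)
    fr <- x[idx] * win
    target_rms <- rms(fr)
    if (target_rms > 0) {
      fit <- lpc_fit(fr, p)
      e <- stats::filter(excite[, k], fit$a, method = "recursive")
      e <- as.numeric(e) * win
      er <- rms(e)
      if (er > 0) e <- e * target_rms / er
      y[idx] <- y[idx] + e
    }
    w2[idx] <- w2[idx] + win^2
  }
  y <- y / sqrt(pmax(w2, 1e-8))
  waveform(y[seq_len(n)], rate)
}

#' Sketch the tonal component via the sparse auditory spectrogram
#'
#' Analysis, maximum-picking at the preset budget, and iterative inversion:
#' `invert(max_pick(spectrogram(tonal), coeffs_per_second))`.
#'
#' @param tonal A [waveform] at 8 kHz (the tonal component).
#' @param params A `sketch_params` preset.
#' @param seed Seed for the inversion.
#' @param n_iterations Inversion iterations (default 50).
#' @param cfg Auditory-model configuration.
#' @return A [waveform] at 8 kHz.
#' @export
sketch_tonal <- function(tonal, params, seed = 0, n_iterations = 50,
                         cfg = aud_config()) {
  stopifnot(inherits(params, "sketch_params"))
  if (all(tonal$samples == 0)) return(tonal)
  s <- auditory_spectrogram(tonal, cfg)
  sp <- max_pick(s, params$coeffs_per_second)
  # warm start from the tonal component itself: the projection pulls the
  # estimate onto the sparse target, and reconstruction fidelity tracks
  # how much the budget kept rather than the inversion's own floor
  y <- invert_auditory_spectrogram(sp, n_iterations = n_iterations,
                                   seed = seed, cfg = cfg, init = tonal)
  n <- length(tonal$samples)
  ys <- y$samples
  ys <- if (length(ys) >= n) ys[seq_len(n)] else c(ys, numeric(n - length(ys)))
  waveform(ys, tonal$rate)
}

#' Create an auditory sketch of a waveform
#'
#' Full pipeline: tonal/noise separation; sparse auditory-spectrogram
#' sketch of the tonal component (computed at 8 kHz, resampled back);
#' frame-wise LPC sketch of the noise component (at the input rate); and
#' recombination with the referent's tonal/noise energy ratio. The output
#' is scaled to the input's overall RMS.
#'
#' @param w A [waveform].
#' @param quality `"Q1"`, `"Q2"` or `"Q3"`, or a `sketch_params` object.
#' @param seed RNG seed (inversion and LPC excitation derive from it).
#' @param n_iterations Inversion iterations for the tonal path.
#' @param decomposition Optionally, a precomputed [separate()] result
#'   for `w` (saves recomputation when sketching at several qualities).
#' @return A [waveform] of the same length and rate as the input.
#' @export
make_sketch <- function(w, quality = "Q2", seed = 0, n_iterations = 50,
                        decomposition = NULL) {
  params <- if (inherits(quality, "sketch_params")) quality else {
    qp <- quality_presets()
    if (!quality %in% names(qp)) stop("unknown quality: ", quality)
    qp[[quality]]
  }
  d <- if (is.null(decomposition)) separate(w) else decomposition
  n <- length(w$samples)
  e_ton <- sum(d$tonal$samples^2)
  e_noi <- sum(d$noise$samples^2)
  fit_len <- function(x) {
    s <- x$samples
    s <- if (length(s) >= n) s[seq_len(n)] else c(s, numeric(n - length(s)))
    waveform(s, w$rate)
  }
  sk_t <- if (e_ton > 0) {
    t8 <- if (w$rate == 8000) d$tonal else resample(d$tonal, 8000)
    st <- sketch_tonal(t8, params, seed = seed, n_iterations = n_iterations)
    fit_len(if (w$rate == 8000) st else resample(st, w$rate))
  } else waveform(numeric(n), w$rate)
  sk_n <- if (e_noi > 0) fit_len(sketch_noise(d$noise, params, seed = seed + 1))
          else waveform(numeric(n), w$rate)
  # impose the referent's component energies (hence its energy ratio)
  e_skt <- sum(sk_t$samples^2)
  e_skn <- sum(sk_n$samples^2)
  ts <- if (e_skt > 0) sk_t$samples * sqrt(e_ton / e_skt) else sk_t$samples
  ns <- if (e_skn > 0) sk_n$samples * sqrt(e_noi / e_skn) else sk_n$samples
  out <- ts + ns
  r_in <- rms(w$samples)
  r_out <- rms(out)
  if (r_out > 0 && r_in > 0) out <- out * r_in / r_out
  structure(waveform(out, w$rate),
            sketch_components = list(tonal = waveform(ts, w$rate),
                                     noise = waveform(ns, w$rate),
                                     params = params))
}
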