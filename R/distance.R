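#' Dynamic-time-warping alignment cost
#'
#' Classic DTW with the symmetric step pattern \{(1,0), (0,1), (1,1)\},
#' local cost the Euclidean distance between frames, no warping window,
#' and no path-length normalization. The returned cost is the sum of local
#' costs along the optimal path.
#'
#' @param a,b Numeric matrices, frames x channels (equal channel counts).
#' @return The optimal alignment cost (>= 0; 0 for identical sequences).
#' @export
dtw_cost <- function(a, b) {
  a <- as.matrix(unclass(a)); b <- as.matrix(unclass(b))
  stopifnot(ncol(a) == ncol(b))
  n <- nrow(a); m <- nrow(b)
  # local cost matrix via |x - y|^2 = |x|^2 + |y|^2 - 2 x.y
  C <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0))
  D <- matrix(Inf, n, m)
  D[1, 1] <- C[1, 1]
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      if (i == 1 && j == 1) next
      up <- if (i > 1) D[i - 1, j] else Inf
      left <- if (j > 1) D[i, j - 1] else Inf
      diag <- if (i > 1 && j > 1) D[i - 1, j - 1] else Inf
      D[i, j] <- C[i, j] + min(up, left, diag)
    }
  }
  D[n, m]
}

# Package-local cache for the reference (noise vs tone) alignment cost.
.vocsketch_cache <- new.env(parent = emptyenv())

#' Auditory distance configuration
#'
#' @param common_duration_s All sounds are time-stretched to this duration
#'   before comparison (default 4.6 s), so alignment costs are on a common
#'   scale regardless of original durations.
#' @param rate Analysis rate, Hz (the auditory model's 8 kHz).
#' @param normalize If `TRUE`, costs are divided by the alignment cost
#'   between a seeded white noise and a 1-kHz pure tone of the common
#'   duration, so that pair defines a unit distance.
#' @param ref_seed Seed for the reference white noise.
#' @param level_dbfs All sounds (and the reference pair) are RMS-equalized
#'   to this level before analysis, mirroring the equal-loudness
#'   presentation of the stimuli; `NULL` disables equalization.
#' @return A configuration list.
#' @export
distance_config <- function(common_duration_s = 4.6, rate = 8000,
                            normalize = TRUE, ref_seed = 1891,
                            level_dbfs = -20) {
  list(common_duration_s = common_duration_s, rate = rate,
       normalize = normalize, ref_seed = ref_seed, level_dbfs = level_dbfs)
}

# Spectrogram of a waveform after level equalization + resampling +
# stretching to the common duration.
dist_spectrogram <- function(w, cfg) {
  if (!is.null(cfg$level_dbfs) && any(w$samples != 0)) {
    w <- equalize_level(w, cfg$level_dbfs)
  }
  if (w$rate != cfg$rate) w <- resample(w, cfg$rate)
  if (abs(wave_duration(w) - cfg$common_duration_s) * cfg$rate > 1) {
    w <- time_stretch(w, cfg$common_duration_s)
  }
  auditory_spectrogram(w, aud_config(rate = cfg$rate))
}

reference_cost <- function(cfg) {
  key <- sprintf("ref_%g_%g_%d_%s", cfg$common_duration_s, cfg$rate,
                 cfg$ref_seed, format(cfg$level_dbfs))
  if (!is.null(.vocsketch_cache[[key]])) return(.vocsketch_cache[[key]])
  n <- round(cfg$common_duration_s * cfg$rate)
  noise <- waveform(with_seed(cfg$ref_seed, stats::rnorm(n)) * 0.1, cfg$rate)
  tone <- waveform(0.1 * sqrt(2) * sin(2 * pi * 1000 * seq_len(n) / cfg$rate),
                   cfg$rate)
  cost <- dtw_cost(dist_spectrogram(noise, cfg), dist_spectrogram(tone, cfg))
  .vocsketch_cache[[key]] <- cost
  cost
}

#' Auditory distance between two waveforms
#'
#' Both sounds are time-stretched to a common duration (preserving spectral
#' content via the phase vocoder), analyzed into auditory spectrograms, and
#' aligned by dynamic time warping; the alignment cost is the distance. By
#' default the cost is expressed in units of the alignment cost between a
#' white noise and a 1-kHz tone of the same duration, so that pair is at
#' distance 1.
#'
#' @param a,b [waveform]s (any rate or duration).
#' @param cfg A [distance_config()].
#' @param spec_a,spec_b Optional precomputed spectrograms (from the same
#'   configuration) to avoid re-analysis in batch computations.
#' @return Non-negative distance; 0 for identical inputs; symmetric.
#' @export
auditory_distance <- function(a, b, cfg = distance_config(),
                              spec_a = NULL, spec_b = NULL) {
  sa <- if (is.null(spec_a)) dist_spectrogram(a, cfg) else spec_a
  sb <- if (is.null(spec_b)) dist_spectrogram(b, cfg) else spec_b
  cost <- dtw_cost(sa, sb)
  if (cfg$normalize) cost <- cost / reference_cost(cfg)
  cost
}
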