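test_that("quality presets store the published parameter triples", {
  qp <- quality_presets()
  expect_equal(qp$Q1$coeffs_per_second, 160)
  expect_equal(qp$Q1$lpc_order, 7)
  expect_equal(qp$Q1$lpc_hop, 0.044)
  expect_equal(qp$Q2$coeffs_per_second, 800)
  expect_equal(qp$Q2$lpc_order, 16)
  expect_equal(qp$Q2$lpc_hop, 0.020)
  expect_equal(qp$Q3$coeffs_per_second, 4000)
  expect_equal(qp$Q3$lpc_order, 36)
  expect_equal(qp$Q3$lpc_hop, 0.009)
  # Q2 is 5% of the full 16000/s representation
  expect_equal(qp$Q2$coeffs_per_second / 16000, 0.05)
  # LPC bookkeeping reproduces the per-second budgets
  expect_equal(qp$Q3$lpc_order / qp$Q3$lpc_hop, 4000)
  expect_equal(qp$Q2$lpc_order / qp$Q2$lpc_hop, 800)
  # fivefold budget steps split evenly: hop x ~sqrt(5), order / ~sqrt(5)
  expect_equal(qp$Q2$lpc_hop / qp$Q3$lpc_hop, sqrt(5), tolerance = 0.01)
  expect_equal(qp$Q1$lpc_hop / qp$Q2$lpc_hop, sqrt(5), tolerance = 0.02)
  expect_equal(qp$Q3$lpc_order / qp$Q2$lpc_order, sqrt(5), tolerance = 0.01)
})

test_that("max picking keeps exactly the largest cells per one-second block", {
  s <- auditory_spectrogram(tone_wave(440, 1))
  expect_equal(sum(max_pick(s, 160) != 0), 160)
  # identity when the budget covers everything
  expect_equal(unclass(max_pick(s, 16000)), unclass(s))
  # brute-force top-K oracle with the same deterministic tie-break
  v <- unclass(s)
  ord <- order(-as.vector(v), as.vector(row(v)), as.vector(col(v)))
  keep <- sort(ord[1:160])
  expect_setequal(which(as.vector(unclass(max_pick(s, 160))) != 0), keep)
  # kept cells retain their original values
  picked <- max_pick(s, 160)
  nz <- which(unclass(picked) != 0)
  expect_equal(unclass(picked)[nz], unclass(s)[nz])
})

test_that("budget accounting holds per second on longer signals", {
  # all-positive synthetic spectrogram so every retained cell is countable
  v <- matrix(with_seed(29, stats::runif(313 * 128, 0.01, 1)), 313, 128)
  s <- structure(v, class = c("aud_spec", "matrix"), frame_length = 0.008,
                 time_constant = 0.128,
                 channel_cfs = channel_center_frequencies(),
                 source_rate = 8000)
  picked <- max_pick(s, 800)
  duration <- nrow(v) * 0.008
  realized_rate <- sum(unclass(picked) != 0) / duration
  # within one coefficient/s of the preset budget, partial block pro-rated
  expect_lte(abs(realized_rate - 800), 1)
})

test_that("LPC noise sketch preserves spectral envelope and frame level", {
  z <- with_seed(4, stats::rnorm(16000))
  ar2 <- as.numeric(stats::filter(z, c(1.2, -0.6), method = "recursive"))
  wn <- waveform(ar2 * 0.1, 8000)
  sk <- sketch_noise(wn, quality_presets()$Q1, seed = 9)
  expect_length(sk$samples, 16000)
  in_lv <- band_levels_db(wn$samples, 8000)
  out_lv <- band_levels_db(sk$samples, 8000)
  expect_lt(max(abs(out_lv - in_lv)), 3)

  flat <- noise_wave(2, seed = 5)
  skf <- sketch_noise(flat, quality_presets()$Q2, seed = 9)
  lvf <- band_levels_db(skf$samples, 8000)
  expect_lt(max(abs(lvf - band_levels_db(flat$samples, 8000))), 3)

  # per-frame RMS tracks the input within 1 dB
  hop <- 800
  fr <- function(x) vapply(seq(1, length(x) - hop, by = hop),
                           function(i) sqrt(mean(x[i:(i + hop - 1)]^2)),
                           numeric(1))
  expect_lt(max(abs(20 * log10(fr(skf$samples) / fr(flat$samples)))), 1)

  tiny <- waveform(stats::rnorm(100), 8000)
  bad <- quality_presets()$Q3
  bad$lpc_hop <- 0.002  # 16-sample frames < 2 x order
  expect_error(sketch_noise(tiny, bad), "order")
})

test_that("tonal sketch keeps the tone and silence maps to silence", {
  w <- tone_wave(440, 1)
  sk <- sketch_tonal(w, quality_presets()$Q2, seed = 3, n_iterations = 20)
  expect_equal(fft_peak_hz(sk), 440, tolerance = 0.02)
  sil <- waveform(numeric(8000), 8000)
  expect_equal(sketch_tonal(sil, quality_presets()$Q1)$samples, numeric(8000))
})

test_that("a sketch preserves the referent's tonal/noise energy ratio", {
  t <- seq_len(12000) / 8000
  h <- sin(2 * pi * 220 * t) + 0.7 * sin(2 * pi * 440 * t)
  h <- h / sqrt(mean(h^2))
  z <- with_seed(8, stats::rnorm(12000)); z <- z / sqrt(mean(z^2))
  # +6 dB tonal/noise mixture
  mix <- waveform(0.2 * (h * 10^(3 / 20) + z), 8000)
  sk <- make_sketch(mix, "Q2", seed = 4, n_iterations = 15)
  cmp <- attr(sk, "sketch_components")
  d <- separate(mix)
  expect_equal(energy_ratio_db(cmp$tonal, cmp$noise),
               d$tonal_noise_ratio_db, tolerance = 0.1)
  expect_equal(length(sk$samples), length(mix$samples))

  # pure-tone referent: the noise path contributes < 10% of the energy
  tone <- tone_wave(330, 1.5)
  skt <- make_sketch(tone, "Q2", seed = 5, n_iterations = 15)
  cmp2 <- attr(skt, "sketch_components")
  expect_lt(sum(cmp2$noise$samples^2) / sum(skt$samples^2), 0.1)
})

test_that("auditory distance to the referent decreases with sketch quality", {
  tab <- corpus_distances()
  med <- tapply(tab$auditory_distance, tab$quality, stats::median)
  expect_lt(med["Q3"], med["Q2"])
  expect_lt(med["Q2"], med["Q1"])
})
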