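test_that("referent generators honour their profile contracts", {
  # impulsive: short, energy concentrated at the onset
  wi <- gen_referent(category_spec("impulsive", "noisy", seed = 2))
  expect_lte(wave_duration(wi), 0.5)
  e <- cumsum(wi$samples^2)
  expect_gt(e[round(0.1 * wi$rate)] / e[length(e)], 0.9)

  # stationary: frame-RMS coefficient of variation < 0.2
  ws <- gen_referent(category_spec("stationary", "noisy", seed = 3))
  fr <- vapply(seq(1, length(ws$samples) - 400, by = 400),
               function(i) sqrt(mean(ws$samples[i:(i + 399)]^2)), numeric(1))
  expect_lt(stats::sd(fr) / mean(fr), 0.2)

  # repeated at 4 bursts/s for 2 s: 8 active regions
  wr <- gen_referent(category_spec("repeated", "noisy", duration_s = 2,
                                   burst_rate_hz = 4, seed = 4))
  fv <- extract_features(wr)
  expect_equal(unname(fv["n_active_regions"]), 8)

  # tonal stationary referent: mostly tonal energy, clear pitch
  wt <- gen_referent(category_spec("stationary", "tonal", seed = 5))
  dt <- separate(wt)
  expect_gt(sum(dt$tonal$samples^2) / sum(wt$samples^2), 0.5)
  expect_gt(extract_features(wt, dt)["median_pitch_strength"], 0.5)

  # complex: many overlapping events by construction; deterministic
  wc <- gen_referent(category_spec("complex", "noisy", seed = 6))
  expect_identical(wc$samples,
                   gen_referent(category_spec("complex", "noisy", seed = 6))$samples)
  expect_error(category_spec("impulsive", "tonal", duration_s = 2), "0.5")
})

test_that("imitations preserve flagged features and are deterministic", {
  ref <- gen_referent(category_spec("repeated", "noisy", duration_s = 2,
                                    burst_rate_hz = 4, seed = 4))
  im <- gen_imitation(ref, seed = 6)
  expect_identical(im$samples, gen_imitation(ref, seed = 6)$samples)
  expect_equal(length(im$samples), length(ref$samples))
  # all-high fidelity on a repeated referent keeps burst count and rate
  expect_equal(unname(extract_features(im)["n_active_regions"]), 8)
})

test_that("an envelope-only imitation is farther from the referent than Q3", {
  ref <- gen_referent(category_spec("stationary", "tonal", seed = 15))
  cfg <- distance_config()
  sk3 <- make_sketch(ref, "Q3", seed = 7, n_iterations = 25)
  im <- gen_imitation(ref, fidelity = list(envelope = TRUE, pitch = FALSE,
                                           centroid = FALSE, jitter = 0.2),
                      seed = 8)
  spec_ref <- dist_spectrogram(ref, cfg)
  d_sketch <- auditory_distance(sk3, ref, cfg, spec_b = spec_ref)
  d_imit <- auditory_distance(im, ref, cfg, spec_b = spec_ref)
  expect_gt(d_imit, d_sketch)
})

test_that("corpus manifests reproduce the full-scale counts deterministically", {
  m <- gen_corpus(seed = 1)$manifest
  expect_equal(sum(m$role == "referent"), 32)
  expect_equal(sum(m$role == "imitation"), 320)
  expect_equal(sum(m$role == "sketch"), 96)
  expect_identical(m, gen_corpus(seed = 1)$manifest)

  small <- gen_corpus(default_categories()[1, ], seed = 1)$manifest
  expect_equal(nrow(small), 2 * (1 + 10 + 3))
})

test_that("simulated observers have the designed yes rates and ceiling", {
  tt <- build_trial_table(seed = 4)
  null <- simulate_observer(tt, observer_spec(dprime = 0, criterion = 0,
                                              seed = 5))
  p <- mean(null$yes)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 672))  # binomial CI

  perfect <- simulate_observer(tt, observer_spec(dprime = 10, criterion = 0,
                                                 seed = 6))
  res <- analyze_responses(tt, perfect)
  expect_true(all(abs(res$dprime - 2.9305) < 0.001))
})

test_that("cell-specific observer sensitivities are respected", {
  tt <- build_trial_table(seed = 8)
  dtab <- expand.grid(type_of_sound = unique(tt$type_of_sound),
                      profile = unique(tt$profile),
                      stringsAsFactors = FALSE)
  dtab$dprime <- ifelse(dtab$type_of_sound == "referent", 10, 0)
  obs <- observer_spec(dprime = dtab, criterion = 0, seed = 9)
  res <- analyze_responses(tt, simulate_observer(tt, obs))
  expect_true(all(res$dprime[res$type_of_sound == "referent"] > 2.9))
  expect_lt(mean(abs(res$dprime[res$type_of_sound != "referent"])), 0.8)
})

test_that("sketch quality ordering holds across the generated corpus", {
  # quality monotonicity in the forms that are robust to the known
  # temporal-resolution compromise (long LPC hops favour stationary
  # sounds): per-referent budget/distance correlations are uniformly
  # negative and strong, and the per-quality mean distances are strictly
  # ordered
  tab <- corpus_distances()
  per_ref <- tapply(seq_len(nrow(tab)), tab$referent, function(ix) {
    stats::cor(log(tab$auditory_distance[ix]), log(tab$coeffs_per_second[ix]))
  })
  expect_true(all(per_ref < 0))
  expect_lte(stats::median(per_ref), -0.8)
  mean_log <- tapply(log(tab$auditory_distance), tab$quality, mean)
  expect_lt(mean_log[["Q3"]], mean_log[["Q2"]])
  expect_lt(mean_log[["Q2"]], mean_log[["Q1"]])
})

test_that("categories within a profile are separable by auditory distance", {
  cfg <- distance_config()
  waves <- list()
  for (role in c("target", "distractor")) {
    for (ex in 1:2) {
      f0 <- if (role == "target") 330 else 520
      waves[[paste(role, ex)]] <- gen_referent(
        category_spec("repeated", "tonal", f0 = f0,
                      burst_rate_hz = if (role == "target") 4 else 2.5,
                      seed = 500 + 7 * ex + (role == "target")))
    }
  }
  specs <- lapply(waves, dist_spectrogram, cfg = cfg)
  dd <- function(i, j) auditory_distance(NULL, NULL, cfg,
                                         spec_a = specs[[i]],
                                         spec_b = specs[[j]])
  within <- c(dd("target 1", "target 2"), dd("distractor 1", "distractor 2"))
  between <- c(dd("target 1", "distractor 1"), dd("target 1", "distractor 2"),
               dd("target 2", "distractor 1"), dd("target 2", "distractor 2"))
  expect_gt(stats::median(between), stats::median(within))
})

test_that("mean recovered sensitivity tracks the generating observer", {
  # 672 twelve-trial cells per level via 12 trial tables of 56 cells each
  recover <- function(true_d, base_seed) {
    vals <- numeric(0)
    for (k in 1:12) {
      tt <- build_trial_table(seed = base_seed + k)
      obs <- observer_spec(dprime = true_d, criterion = 0,
                           seed = base_seed + 10 * k)
      res <- analyze_responses(tt, simulate_observer(tt, obs))
      vals <- c(vals, res$dprime)
    }
    mean(vals)
  }
  for (true_d in c(0, 0.5, 1, 1.5)) {
    expect_lt(abs(recover(true_d, 100 + round(10 * true_d)) - true_d), 0.15)
  }
  # near ceiling the corrected estimator shrinks but never exceeds 2.93
  expect_lte(recover(2.93, 77), 2.9305)
})
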