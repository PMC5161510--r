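#' Specification of a synthetic referent category
#'
#' Defines the generator parameters for a referent-like sound in one of
#' the four morphological profiles, either tonal (carried by a harmonic
#' complex) or noisy (carried by filtered noise):
#'
#' * `impulsive`: a single short event with a sharp onset and exponential
#'   decay (~0.4 s total, energy concentrated in the first tens of ms);
#' * `repeated`: a regular sequence of slow-onset bursts;
#' * `stationary`: a continuous sound whose statistics do not change over
#'   time (frame-RMS coefficient of variation < 0.2);
#' * `complex`: many overlapping micro-events with a drifting spectral
#'   centre.
#'
#' @param profile One of `"impulsive"`, `"repeated"`, `"stationary"`,
#'   `"complex"`.
#' @param tonality `"tonal"` or `"noisy"`.
#' @param f0 Fundamental (tonal) or filter centre (noisy), Hz.
#' @param duration_s Nominal duration, seconds.
#' @param burst_rate_hz Burst rate for the repeated profile.
#' @param decay_s Decay constant of the impulsive profile.
#' @param event_density Events per second for the complex profile.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @param rate Sampling rate, Hz.
#' @return An object of class `category_spec`.
#' @export
category_spec <- function(profile = c("impulsive", "repeated", "stationary",
                                      "complex"),
                          tonality = c("tonal", "noisy"),
                          f0 = 440, duration_s = NULL, burst_rate_hz = 4,
                          decay_s = 0.03, event_density = 12, seed = 0,
                          rate = 8000) {
  profile <- match.arg(profile)
  tonality <- match.arg(tonality)
  if (is.null(duration_s)) {
    duration_s <- if (profile == "impulsive") 0.4 else 1.5
  }
  if (profile == "impulsive" && duration_s > 0.5) {
    stop("impulsive referents must be <= 0.5 s")
  }
  structure(list(profile = profile, tonality = tonality, f0 = f0,
                 duration_s = duration_s, burst_rate_hz = burst_rate_hz,
                 decay_s = decay_s, event_density = event_density,
                 seed = seed, rate = rate),
            class = "category_spec")
}

# Tonal or noisy carrier of length n (unit RMS, before enveloping).
ref_carrier <- function(spec, n, seed_offset = 0) {
  rate <- spec$rate
  t <- seq_len(n) / rate
  if (spec$tonality == "tonal") {
    # harmonic complex with mild spectral tilt, partials below 3.5 kHz,
    # and a slow ~0.3% vibrato: rotating machinery is never perfectly
    # steady, and the wobble spreads energy across analysis channels
    nh <- max(1, floor(3500 / spec$f0))
    amps <- 1 / (seq_len(nh))^0.7
    ph <- with_seed(spec$seed + 101 + seed_offset,
                    stats::runif(nh, 0, 2 * pi))
    vib <- 1 + 0.003 * sin(2 * pi * 3.1 * t + (spec$seed %% 11))
    inst_phase <- 2 * pi * spec$f0 * cumsum(vib) / rate
    x <- rowSums(vapply(seq_len(nh), function(h)
      amps[h] * sin(h * inst_phase + ph[h]), numeric(n)))
  } else {
    # multi-resonance noise: mechanical sources have several formant-like
    # resonances over a tilted broadband floor, so the spectral envelope
    # is rich enough that all-pole model order genuinely matters
    z <- with_seed(spec$seed + 101 + seed_offset, stats::rnorm(n))
    res_f <- spec$f0 * c(1, 2.3, 4.1)
    res_f <- res_f[res_f < 0.45 * rate]
    res_r <- c(0.96, 0.93, 0.90)[seq_along(res_f)]
    x <- 0.15 * z                       # broadband floor
    for (j in seq_along(res_f)) {
      th <- 2 * pi * res_f[j] / rate
      x <- x + (0.8 / j) * as.numeric(
        stats::filter(z, c(2 * res_r[j] * cos(th), -res_r[j]^2),
                      method = "recursive"))
    }
    # gentle high-frequency tilt via a leaky differencer
    x <- x + 0.3 * c(0, diff(x))
  }
  x / max(rms(x), 1e-12)
}

#' Generate a synthetic referent sound
#'
#' @param spec A [category_spec()].
#' @return A [waveform]; deterministic given the spec (including its seed).
#' @export
gen_referent <- function(spec) {
  stopifnot(inherits(spec, "category_spec"))
  rate <- spec$rate
  n <- round(spec$duration_s * rate)
  t <- seq_len(n) / rate
  env <- switch(spec$profile,
    impulsive = {
      # 2-ms attack then exponential decay
      atk <- pmin(t / 0.002, 1)
      atk * exp(-t / spec$decay_s)
    },
    repeated = {
      period <- 1 / spec$burst_rate_hz
      burst_len <- 0.45 * period
      ph <- t %% period
      # slow onset: raised-cosine attack over 60% of the burst, fast decay
      e <- numeric(n)
      inb <- ph < burst_len
      u <- ph[inb] / burst_len
      e[inb] <- ifelse(u < 0.6, 0.5 - 0.5 * cos(pi * u / 0.6),
                       cos(0.5 * pi * (u - 0.6) / 0.4))
      e
    },
    stationary = {
      # constant level with a slow, small wobble
      wob <- 0.08 * sin(2 * pi * 1.3 * t + spec$seed %% 7)
      1 + wob
    },
    complex = {
      ne <- max(10, ceiling(spec$event_density * spec$duration_s))
      starts <- with_seed(spec$seed + 301,
                          stats::runif(ne, 0, spec$duration_s * 0.9))
      durs <- with_seed(spec$seed + 302, stats::runif(ne, 0.05, 0.25))
      amps <- with_seed(spec$seed + 303, stats::runif(ne, 0.4, 1))
      e <- numeric(n)
      for (j in seq_len(ne)) {
        i0 <- max(1L, round(starts[j] * rate))
        i1 <- min(n, round((starts[j] + durs[j]) * rate))
        seg <- seq(i0, i1)
        u <- (seg - i0) / max(i1 - i0, 1)
        e[seg] <- e[seg] + amps[j] * sin(pi * u)^2
      }
      e / max(e)
    })
  x <- ref_carrier(spec, n) * env
  if (spec$profile == "impulsive" && spec$tonality == "tonal") {
    # struck objects ring *and* click: add a short broadband impact
    # transient so the sketch budget binds across the whole spectrum
    click_n <- round(0.015 * rate)
    click <- with_seed(spec$seed + 401, stats::rnorm(click_n)) *
      exp(-seq_len(click_n) / (0.004 * rate))
    x[seq_len(click_n)] <- x[seq_len(click_n)] + 0.8 * click
  }
  if (spec$profile == "complex") {
    # drifting spectral centre: slow sweep of a resonant filter
    f_drift <- spec$f0 * 2^(seq(-0.5, 0.5, length.out = n))
    r <- 0.95
    y <- numeric(n)
    s1 <- 0; s2 <- 0
    th <- 2 * pi * f_drift / rate
    cth <- 2 * r * cos(th)
    for (i in seq_len(n)) {
      v <- x[i] + cth[i] * s1 - r^2 * s2
      y[i] <- v
      s2 <- s1; s1 <- v
    }
    x <- y * env / max(rms(y * env), 1e-12)
  }
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk * 0.7
  waveform(x, rate)
}

#' Generate an imitation-like degradation of a referent
#'
#' A feature-selective resynthesis, not a vocal-tract model: the referent's
#' amplitude envelope, pitch track and/or spectral-centroid trajectory are
#' measured, each either preserved (optionally jittered) or replaced by a
#' neutral "voice-like" default, and imposed on a new carrier — a pulse
#' train for tonal referents, filtered noise for noisy ones. This creates
#' stimuli whose overall acoustic distance to the referent is large even
#' when the preserved features are exact, the dissociation the imitation
#' analyses rely on.
#'
#' @param referent A [waveform].
#' @param fidelity List with logical `envelope`, `pitch`, `centroid` and
#'   numeric `jitter` (0 = exact preservation; 0.3 = strong degradation).
#' @param seed RNG seed.
#' @return A [waveform] of the same duration and rate.
#' @export
gen_imitation <- function(referent,
                          fidelity = list(envelope = TRUE, pitch = TRUE,
                                          centroid = TRUE, jitter = 0),
                          seed = 0) {
  stopifnot(inherits(referent, "waveform"))
  rate <- referent$rate
  n <- length(referent$samples)
  hop <- max(1L, round(0.005 * rate))
  starts <- seq(1L, max(1L, n - hop), by = hop)
  env <- vapply(starts, function(i)
    rms(referent$samples[i:min(i + hop - 1L, n)]), numeric(1))
  env_t <- (starts + hop / 2) / rate
  d <- separate(referent)
  voiced <- sum(d$tonal$samples^2) > 0.5 * sum(referent$samples^2)
  fr <- feature_frames(referent, d)
  jit <- function(v, amount, off) {
    if (amount <= 0) return(v)
    k <- max(3L, round(length(v) / 8))
    noise <- with_seed(seed + off, stats::rnorm(length(v)))
    smooth <- stats::filter(noise, rep(1 / k, k), sides = 2)
    smooth[is.na(smooth)] <- 0
    v * (1 + amount * as.numeric(smooth))
  }
  env_used <- if (isTRUE(fidelity$envelope)) {
    pmax(jit(env, fidelity$jitter, 11), 0)
  } else rep(mean(env), length(env))
  tt <- seq_len(n) / rate
  if (voiced) {
    pitch_track <- fr$pitch
    pitch_track[fr$strength < 0.2 | pitch_track <= 0] <- NA
    base <- if (all(is.na(pitch_track))) 120 else
      stats::median(pitch_track, na.rm = TRUE)
    pitch_track[is.na(pitch_track)] <- base
    p_used <- if (isTRUE(fidelity$pitch)) {
      pmax(jit(pitch_track, fidelity$jitter, 13), 40)
    } else rep(120, length(pitch_track))
    f_inst <- stats::approx(fr$time, p_used, xout = tt, rule = 2)$y
    phase <- 2 * pi * cumsum(f_inst) / rate
    # "glottal" pulse-like carrier: harmonically rich
    carrier <- 0.6 * sin(phase) + 0.3 * sin(2 * phase) + 0.15 * sin(3 * phase)
  } else {
    carrier <- with_seed(seed + 17, stats::rnorm(n))
  }
  cen_track <- if (isTRUE(fidelity$centroid)) {
    jit(fr$centroid, fidelity$jitter, 19)
  } else rep(500, nrow(fr))
  cen <- stats::approx(fr$time, pmax(cen_track, 80), xout = tt, rule = 2)$y
  cen <- pmin(cen, 0.45 * rate)
  # slowly varying one-pole resonator tracking the centroid target
  r <- 0.9
  cth <- 2 * r * cos(2 * pi * cen / rate)
  y <- numeric(n); s1 <- 0; s2 <- 0
  for (i in seq_len(n)) {
    v <- carrier[i] + cth[i] * s1 - r^2 * s2
    y[i] <- v
    s2 <- s1; s1 <- v
  }
  e_i <- stats::approx(env_t, env_used, xout = tt, rule = 2)$y
  # impose the envelope exactly: normalize local level first
  loc <- vapply(starts, function(i)
    rms(y[i:min(i + hop - 1L, n)]), numeric(1))
  loc_i <- stats::approx(env_t, pmax(loc, 1e-9), xout = tt, rule = 2)$y
  out <- y / loc_i * e_i
  pk <- max(abs(out))
  if (pk > 0) out <- out / pk * 0.7
  waveform(out, rate)
}

#' Default category set mirroring a two-family referent selection
#'
#' 16 categories: 2 families x 4 morphological profiles x (target +
#' distractor), with tonality assigned so both families mix tonal and
#' noisy sounds; target and distractor of a profile differ in generator
#' parameters but share the profile.
#'
#' @return A data.frame of category definitions.
#' @export
default_categories <- function() {
  base <- expand.grid(family = c("product", "interaction"),
                      profile = c("impulsive", "repeated", "stationary",
                                  "complex"),
                      role = c("target", "distractor"),
                      stringsAsFactors = FALSE)
  # product family is mostly tonal (machines), interactions mostly noisy
  base$tonality <- ifelse(base$family == "product",
                          ifelse(base$profile == "impulsive" &
                                   base$role == "target", "noisy", "tonal"),
                          ifelse(base$profile == "impulsive" &
                                   base$role == "distractor", "tonal",
                                 "noisy"))
  base$f0 <- ifelse(base$role == "target", 330, 520) +
    ifelse(base$family == "product", 0, 90)
  base$burst_rate_hz <- ifelse(base$role == "target", 4, 2.5)
  base$event_density <- ifelse(base$role == "target", 12, 20)
  base$category <- paste(base$family, base$profile, base$role, sep = "_")
  base
}

#' Generate a synthetic corpus manifest (and optionally its audio)
#'
#' For each category and exemplar, the corpus contains one referent,
#' `n_imitators` imitation variants and one sketch per quality. At the
#' full default scale (16 categories x 2 exemplars) this is 32 referents,
#' 320 imitations and 96 sketches.
#'
#' @param categories Category table as from [default_categories()] (or a
#'   subset of its rows).
#' @param n_exemplars Exemplars per category (default 2).
#' @param n_imitators Imitation variants per referent (default 10).
#' @param qualities Sketch qualities (default Q1, Q2, Q3).
#' @param seed Base RNG seed recorded per item.
#' @param audio If `TRUE`, synthesize every waveform (slow at full scale);
#'   if `FALSE` (default) return the manifest only.
#' @param out_dir If non-`NULL` and `audio` is `TRUE`, write WAVs here.
#' @return A list with `manifest` (data.frame: file, role, family,
#'   profile, category, tonality, variant, exemplar, seed) and, when
#'   `audio = TRUE`, `waves` (named list of [waveform]s).
#' @export
gen_corpus <- function(categories = default_categories(), n_exemplars = 2,
                       n_imitators = 10, qualities = c("Q1", "Q2", "Q3"),
                       seed = 0, audio = FALSE, out_dir = NULL) {
  rows <- list()
  for (ci in seq_len(nrow(categories))) {
    cat_row <- categories[ci, ]
    for (ex in seq_len(n_exemplars)) {
      item_seed <- seed + 1000 * ci + 100 * ex
      id <- sprintf("%s_ex%d", cat_row$category, ex)
      add <- function(role, variant, s) {
        data.frame(file = sprintf("%s_%s%s.wav", id, role,
                                  if (variant == "") "" else paste0("_", variant)),
                   role = role, family = cat_row$family,
                   profile = cat_row$profile, category = cat_row$category,
                   tonality = cat_row$tonality, variant = variant,
                   exemplar = ex, seed = s)
      }
      rows[[length(rows) + 1L]] <- add("referent", "", item_seed)
      for (im in seq_len(n_imitators)) {
        rows[[length(rows) + 1L]] <-
          add("imitation", sprintf("%02d", im), item_seed + im)
      }
      for (q in qualities) {
        rows[[length(rows) + 1L]] <- add("sketch", q, item_seed + 50)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  out <- list(manifest = manifest)
  if (audio) {
    waves <- list()
    for (ci in seq_len(nrow(categories))) {
      cat_row <- categories[ci, ]
      for (ex in seq_len(n_exemplars)) {
        item_seed <- seed + 1000 * ci + 100 * ex
        spec <- category_spec(profile = cat_row$profile,
                              tonality = cat_row$tonality,
                              f0 = cat_row$f0,
                              burst_rate_hz = cat_row$burst_rate_hz,
                              event_density = cat_row$event_density,
                              seed = item_seed)
        id <- sprintf("%s_ex%d", cat_row$category, ex)
        ref <- gen_referent(spec)
        waves[[sprintf("%s_referent", id)]] <- ref
        for (im in seq_len(n_imitators)) {
          jitter_lvl <- (im - 1) / max(n_imitators - 1, 1) * 0.3
          waves[[sprintf("%s_imitation_%02d", id, im)]] <-
            gen_imitation(ref, fidelity = list(envelope = TRUE, pitch = TRUE,
                                               centroid = TRUE,
                                               jitter = jitter_lvl),
                          seed = item_seed + im)
        }
        dref <- separate(ref)
        for (q in qualities) {
          waves[[sprintf("%s_sketch_%s", id, q)]] <-
            make_sketch(ref, q, seed = item_seed + 50, decomposition = dref)
        }
      }
    }
    out$waves <- waves
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (f in manifest$file) {
        key <- sub("\\.wav$", "", f)
        if (!is.null(waves[[key]])) write_wav(file.path(out_dir, f), waves[[key]])
      }
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' Simulated equal-variance Gaussian observer
#'
#' @param dprime True sensitivity: a single number, or a data.frame with
#'   columns `type_of_sound`, `profile`, `dprime` for cell-specific
#'   sensitivities.
#' @param criterion Criterion c as distance from the unbiased midpoint
#'   (positive = conservative, "no"-prone).
#' @param seed RNG seed.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(dprime = 1, criterion = 0, seed = 0) {
  structure(list(dprime = dprime, criterion = criterion, seed = seed),
            class = "observer_spec")
}

#' Simulate yes/no responses from a Gaussian observer
#'
#' Each target trial is answered "yes" with probability
#' `pnorm(d'/2 - c)` and each distractor trial with `pnorm(-d'/2 - c)`.
#'
#' @param trials A trial table from [build_trial_table()].
#' @param obs An [observer_spec()].
#' @return A data.frame with columns `trial` and logical `yes`.
#' @export
simulate_observer <- function(trials, obs = observer_spec()) {
  stopifnot(inherits(obs, "observer_spec"))
  d <- if (is.data.frame(obs$dprime)) {
    m <- merge(trials, obs$dprime, by = c("type_of_sound", "profile"),
               sort = FALSE)
    m <- m[order(m$trial), ]
    m$dprime
  } else rep(obs$dprime, nrow(trials))
  tr <- trials[order(trials$trial), ]
  p_yes <- ifelse(tr$category == "target",
                  stats::pnorm(d / 2 - obs$criterion),
                  stats::pnorm(-d / 2 - obs$criterion))
  yes <- with_seed(obs$seed, stats::runif(nrow(tr))) < p_yes
  data.frame(trial = tr$trial, yes = yes)
}
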