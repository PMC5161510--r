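# A seeded synthetic corpus of 12 referents (4 morphological profiles x
# tonal/noisy, plus a second exemplar per profile) with Q1/Q2/Q3 sketches
# and auditory distances to the referents. Computed once per test session
# and cached: several suites (sketch quality monotonicity, distance
# correlation) share it.

.corpus_cache <- new.env(parent = emptyenv())

corpus_specs <- function() {
  grid <- expand.grid(profile = c("impulsive", "repeated", "stationary",
                                  "complex"),
                      tonality = c("tonal", "noisy"),
                      stringsAsFactors = FALSE)
  # second exemplars: one more referent per profile at a different f0,
  # alternating tonality by profile
  grid <- rbind(grid,
                data.frame(profile = c("impulsive", "repeated", "stationary",
                                       "complex"),
                           tonality = c("noisy", "tonal", "noisy", "tonal")))
  # machine-like fundamentals / resonance centres: low enough that the
  # 90-3500 Hz band carries a dense set of partials
  lapply(seq_len(nrow(grid)), function(i) {
    category_spec(grid$profile[i], grid$tonality[i],
                  f0 = c(110, 180, 150)[1 + (i - 1) %% 3], seed = 40 + i)
  })
}

corpus_distances <- function() {
  if (!is.null(.corpus_cache$dist)) return(.corpus_cache$dist)
  specs <- corpus_specs()
  cfgd <- distance_config()
  budgets <- c(Q1 = 160, Q2 = 800, Q3 = 4000)
  rows <- list()
  sketches <- list()
  for (i in seq_along(specs)) {
    ref <- gen_referent(specs[[i]])
    d <- separate(ref)
    spec_ref <- dist_spectrogram(ref, cfgd)
    for (q in names(budgets)) {
      sk <- make_sketch(ref, q, seed = 60 + i, n_iterations = 40,
                        decomposition = d)
      rows[[length(rows) + 1L]] <- data.frame(
        referent = i, profile = specs[[i]]$profile,
        tonality = specs[[i]]$tonality, quality = q,
        coeffs_per_second = unname(budgets[q]),
        auditory_distance = auditory_distance(sk, ref, cfgd,
                                              spec_b = spec_ref))
      sketches[[sprintf("ref%d_%s", i, q)]] <- sk
    }
    sketches[[sprintf("ref%d_referent", i)]] <- ref
  }
  .corpus_cache$waves <- sketches
  .corpus_cache$dist <- do.call(rbind, rows)
  .corpus_cache$dist
}

# Imitation-like stimuli for the same referents (a faithful and a heavily
# jittered variant each), with auditory distances to their referents:
# together with the sketches these span the heterogeneous stimulus set over
# which the two distance models are compared.
corpus_imitation_distances <- function() {
  if (!is.null(.corpus_cache$imit)) return(.corpus_cache$imit)
  corpus_distances()  # ensure referents/waves are cached
  specs <- corpus_specs()
  cfgd <- distance_config()
  rows <- list()
  for (i in seq_along(specs)) {
    ref <- .corpus_cache$waves[[sprintf("ref%d_referent", i)]]
    spec_ref <- dist_spectrogram(ref, cfgd)
    for (j in 1:2) {
      im <- gen_imitation(ref, fidelity = list(envelope = TRUE, pitch = TRUE,
                                               centroid = TRUE,
                                               jitter = c(0, 0.3)[j]),
                          seed = 80 + 10 * i + j)
      key <- sprintf("ref%d_imit%d", i, j)
      .corpus_cache$waves[[key]] <- im
      rows[[length(rows) + 1L]] <- data.frame(
        referent = i, profile = specs[[i]]$profile,
        tonality = specs[[i]]$tonality, quality = sprintf("imit%d", j),
        coeffs_per_second = NA_real_,
        auditory_distance = auditory_distance(im, ref, cfgd,
                                              spec_b = spec_ref))
    }
  }
  .corpus_cache$imit <- do.call(rbind, rows)
  .corpus_cache$imit
}

# Correlation between log mean auditory distance per quality level and the
# log coefficient budget — the quality/distance summary statistic.
corpus_loglog_r <- function(tab) {
  mean_log <- tapply(log(tab$auditory_distance), tab$quality, mean)
  budgets <- tapply(log(tab$coeffs_per_second), tab$quality, unique)
  stats::cor(budgets, mean_log)
}

# Pairwise distances among the corpus referents under both distance
# models: the analog of comparing category exemplars to one another, which
# is where the two models share variance (stimulus-to-referent distances
# instead *dissociate* them by design for feature-faithful imitations).
corpus_pair_distances <- function() {
  if (!is.null(.corpus_cache$pairs)) return(.corpus_cache$pairs)
  corpus_distances()
  cfgd <- distance_config()
  n_ref <- length(corpus_specs())
  keys <- sprintf("ref%d_referent", seq_len(n_ref))
  specs <- lapply(keys, function(k)
    dist_spectrogram(.corpus_cache$waves[[k]], cfgd))
  feats <- t(vapply(keys, function(k)
    extract_features(.corpus_cache$waves[[k]]), numeric(13)))
  z <- feature_standardizer(feats)
  rows <- list()
  for (i in seq_len(n_ref - 1)) {
    for (j in (i + 1):n_ref) {
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j,
        auditory = auditory_distance(NULL, NULL, cfgd,
                                     spec_a = specs[[i]], spec_b = specs[[j]]),
        feature = feature_distance(feats[i, ], feats[j, ], z))
    }
  }
  .corpus_cache$pairs <- do.call(rbind, rows)
  .corpus_cache$pairs
}

# Feature distances stimulus -> referent over the pooled corpus (sketches
# and imitations; standardizer fit on all corpus sounds together).
corpus_feature_distances <- function() {
  if (!is.null(.corpus_cache$fdist)) return(.corpus_cache$fdist)
  dist_tab <- rbind(corpus_distances(), corpus_imitation_distances())
  waves <- .corpus_cache$waves
  feats <- t(vapply(names(waves), function(k) extract_features(waves[[k]]),
                    numeric(13)))
  z <- feature_standardizer(feats)
  fd <- vapply(seq_len(nrow(dist_tab)), function(r) {
    key_s <- sprintf("ref%d_%s", dist_tab$referent[r], dist_tab$quality[r])
    key_r <- sprintf("ref%d_referent", dist_tab$referent[r])
    feature_distance(feats[key_s, ], feats[key_r, ], z)
  }, numeric(1))
  .corpus_cache$fdist <- cbind(dist_tab, feature_distance = fd)
  .corpus_cache$fdist
}
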