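test_that("corrected d-prime reproduces its closed-form anchors", {
  expect_equal(dprime_yesno(6, 6, 0, 6), 2.93, tolerance = 0.01)
  expect_equal(dprime_yesno(3, 6, 3, 6), 0)
  # normal-quantile oracle on corrected rates 5.5/7 and 1.5/7
  expect_equal(dprime_yesno(5, 6, 1, 6),
               stats::qnorm(5.5 / 7) - stats::qnorm(1.5 / 7))
  expect_equal(round(dprime_yesno(5, 6, 1, 6), 2), 1.58)
})

test_that("d-prime is antisymmetric, monotone in hits, and bounded", {
  for (h in 0:6) for (f in 0:6) {
    expect_equal(dprime_yesno(h, 6, f, 6), -dprime_yesno(f, 6, h, 6))
  }
  d <- vapply(0:6, function(h) dprime_yesno(h, 6, 2, 6), numeric(1))
  expect_true(all(diff(d) > 0))
  all_d <- outer(0:6, 0:6, Vectorize(function(h, f) dprime_yesno(h, 6, f, 6)))
  expect_lte(max(abs(all_d)), 2.9305)
})

test_that("ln beta sign convention: liberal positive, matching the likelihood oracle", {
  expect_equal(ln_beta(5, 6, 1, 6), 0)       # symmetric criterion H = 1 - F
  expect_gt(ln_beta(6, 6, 4, 6), 0)          # yes-prone observer
  expect_lt(ln_beta(2, 6, 0, 6), 0)          # no-prone observer
  # numerical SDT oracle: |ln beta| is the Gaussian likelihood ratio at the
  # implied criterion, sign flipped relative to the textbook convention
  for (h in c(2, 4, 5, 6)) for (f in c(0, 1, 3)) {
    hh <- (h + 0.5) / 7; ff <- (f + 0.5) / 7
    d <- stats::qnorm(hh) - stats::qnorm(ff)
    crit <- -stats::qnorm(ff)                 # criterion re: noise mean
    textbook <- log(stats::dnorm(crit - d) / stats::dnorm(crit))
    expect_equal(abs(ln_beta(h, 6, f, 6)), abs(textbook), tolerance = 1e-10)
    if (hh + ff != 1) {
      expect_equal(sign(ln_beta(h, 6, f, 6)), sign(hh + ff - 1))
    }
  }
})

test_that("unbiased percent correct transforms d-prime through the normal CDF", {
  expect_equal(unbiased_pc(0), 50)
  expect_equal(unbiased_pc(2.93), 100 * stats::pnorm(1.465))
  expect_equal(round(unbiased_pc(2.93), 1), 92.9)
  d <- seq(-1, 3, by = 0.25)
  expect_true(all(diff(vapply(d, unbiased_pc, numeric(1))) > 0))
})

test_that("critical r thresholds match the t-distribution inversion", {
  expect_equal(pearson_critical_r(14, 0.05), 0.53, tolerance = 0.005)
  expect_equal(pearson_critical_r(14, 0.01), 0.66, tolerance = 0.005)
  expect_lt(pearson_critical_r(10000, 0.05), 0.03)
})

test_that("correlation and paired t wrappers match direct formulas", {
  x <- with_seed(5, stats::rnorm(10))
  y <- with_seed(6, stats::rnorm(10))
  ct <- correlate(x, y)
  r_direct <- sum(scale(x) * scale(y)) / 9
  expect_equal(ct$r, r_direct, tolerance = 1e-10)
  t_direct <- r_direct * sqrt(8 / (1 - r_direct^2))
  expect_equal(ct$p, 2 * stats::pt(-abs(t_direct), 8), tolerance = 1e-10)
  expect_equal(correlate(x, x)$r, 1)

  tt <- paired_ttest(x, y)
  dd <- x - y
  expect_equal(tt$t, mean(dd) / (stats::sd(dd) / sqrt(10)), tolerance = 1e-10)
  expect_equal(paired_ttest(x, x)$t, 0)
  expect_error(correlate(rep(1, 5), 1:5), "variance")
})

test_that("the trial table realizes the designed cell structure", {
  tt <- build_trial_table(seed = 3)
  expect_equal(nrow(tt), 672)
  counts <- table(tt$profile, tt$type_of_sound)
  expect_true(all(counts == 12))
  split6 <- table(tt$profile, tt$type_of_sound, tt$category)
  expect_true(all(split6 == 6))
  # each exemplar x repetition triple carries offsets {0, -5, -10}
  key <- interaction(tt$type_of_sound, tt$profile, tt$category, tt$exemplar)
  offs <- tapply(tt$level_offset_db, key, function(v) sort(v))
  expect_true(all(vapply(offs, identical, logical(1), c(-10, -5, 0))))
  # five blocks; referents always last
  expect_equal(sort(unique(tt$block)), 1:5)
  expect_true(all(tt$block_name[tt$block == 5] == "referent"))
  expect_true(all(tt$type_of_sound[tt$block_name == "imitations"] %in%
                    sprintf("imitation_%02d", 1:10)))
  # deterministic given the seed
  expect_identical(tt, build_trial_table(seed = 3))
  expect_false(identical(tt$type_of_sound, build_trial_table(seed = 4)$type_of_sound))
})

test_that("response scoring matches a hand-tallied fixture", {
  tt <- build_trial_table(seed = 2)
  cell <- tt[tt$type_of_sound == "referent" & tt$profile == "impulsive", ]
  resp <- data.frame(trial = tt$trial, yes = FALSE)
  # say yes to 5 of 6 targets and 1 of 6 distractors in that cell
  yes_trials <- c(cell$trial[cell$category == "target"][1:5],
                  cell$trial[cell$category == "distractor"][1])
  resp$yes[resp$trial %in% yes_trials] <- TRUE
  res <- analyze_responses(tt, resp)
  row <- res[res$type_of_sound == "referent" & res$profile == "impulsive", ]
  expect_equal(row$n_hit, 5)
  expect_equal(row$n_fa, 1)
  expect_equal(row$dprime, dprime_yesno(5, 6, 1, 6))
  # all-"no" cells: d' = 0 is not expected; hit = fa = 0 gives d' = 0
  other <- res[res$type_of_sound == "referent" & res$profile == "complex", ]
  expect_equal(other$dprime, 0)

  # missing responses are flagged, not dropped
  resp2 <- resp[-(1:5), ]
  res2 <- analyze_responses(tt, resp2)
  expect_equal(sum(res2$n_missing), 5)
})

test_that("an all-yes responder shows no sensitivity and no likelihood bias", {
  tt <- build_trial_table(seed = 9)
  res <- analyze_responses(tt, data.frame(trial = tt$trial, yes = TRUE))
  expect_true(all(res$dprime == 0))
  # with equal hit and false-alarm rates the likelihood ratio is 1, so the
  # bias statistic is exactly 0 even at this extreme criterion
  expect_true(all(res$ln_beta == 0))
  # a yes-prone observer with some sensitivity does show a liberal bias
  obs <- observer_spec(dprime = 1, criterion = -0.8, seed = 3)
  res2 <- analyze_responses(tt, simulate_observer(tt, obs))
  expect_gt(mean(res2$ln_beta), 0)
})
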