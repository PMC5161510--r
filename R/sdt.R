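#' Yes/no sensitivity with the log-linear correction
#'
#' Equal-variance Gaussian d-prime for a yes/no task, with the log-linear
#' correction for extreme counts: 0.5 is added to the hit and false-alarm
#' counts and 1 to each trial count, so perfect and null scores stay
#' finite. With 6 signal and 6 noise trials, perfect discrimination maps
#' to d' = 2 * qnorm(6.5/7) = 2.93.
#'
#' @param n_hit,n_signal Hits and signal (target) trial count.
#' @param n_fa,n_noise False alarms and noise (distractor) trial count.
#' @return The corrected sensitivity index d'.
#' @examples
#' dprime_yesno(6, 6, 0, 6)  # 2.93
#' @export
dprime_yesno <- function(n_hit, n_signal, n_fa, n_noise) {
  stopifnot(n_signal >= 1, n_noise >= 1,
            n_hit >= 0, n_hit <= n_signal, n_fa >= 0, n_fa <= n_noise)
  h <- (n_hit + 0.5) / (n_signal + 1)
  f <- (n_fa + 0.5) / (n_noise + 1)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Response bias ln(beta), signed so that liberal = positive
#'
#' The magnitude is the Gaussian log-likelihood ratio at the observer's
#' criterion, `|z(H)^2 - z(F)^2| / 2` on log-linear-corrected rates. The
#' sign convention is: positive when the observer is biased toward "yes"
#' (criterion below the midpoint, i.e. H + F > 1), negative when biased
#' toward "no". Note this is the negative of the textbook likelihood-ratio
#' sign, which is negative for liberal criteria.
#'
#' @inheritParams dprime_yesno
#' @return Signed ln(beta); 0 for a symmetric criterion.
#' @export
ln_beta <- function(n_hit, n_signal, n_fa, n_noise) {
  h <- (n_hit + 0.5) / (n_signal + 1)
  f <- (n_fa + 0.5) / (n_noise + 1)
  zh <- stats::qnorm(h)
  zf <- stats::qnorm(f)
  sign(zh + zf) * abs(zh^2 - zf^2) / 2
}

#' Unbiased percent correct implied by a d'
#'
#' The percent correct an observer with sensitivity d' would reach under a
#' symmetric (no-bias) criterion, where false alarms = 1 - hit rate:
#' `100 * pnorm(d' / 2)`.
#'
#' @param dprime Sensitivity index (finite).
#' @return Percent correct in (0, 100); strictly increasing in d'.
#' @export
unbiased_pc <- function(dprime) {
  stopifnot(is.finite(dprime))
  100 * stats::pnorm(dprime / 2)
}

#' Two-tailed critical value of the Pearson correlation
#'
#' Inverts the t distribution with n - 2 degrees of freedom:
#' `r = t / sqrt(n - 2 + t^2)`. With n = 14, alpha = .05 gives r = 0.53
#' and alpha = .01 gives r = 0.66.
#'
#' @param n Number of data points (>= 3).
#' @param alpha Two-tailed significance level.
#' @return The critical |r|.
#' @export
pearson_critical_r <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  t <- stats::qt(1 - alpha / 2, df = n - 2)
  t / sqrt(n - 2 + t^2)
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A list with `r`, `df` and two-tailed `p`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input; correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Paired t test
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return A list with `t`, `df`, two-tailed `p`, and the mean difference.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    # degenerate case: identical pairwise differences
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = n - 1, p = if (t == 0) 1 else 0,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Experiment design for the yes/no identification task
#'
#' One participant hears 14 types of sound (the referent, ten imitators'
#' imitations, and sketches Q1/Q2/Q3) in each of 4 morphological profiles.
#' Each (profile, type) cell has 12 trials: 2 target + 2 distractor
#' exemplars, each repeated 3 times at level offsets 0, -5 and -10 dB from
#' baseline. Trials are organized in five blocks — imitations, the three
#' sketch qualities in order Q1, Q2, Q3, and the referents always last —
#' with order randomized within block. Total: 12 x 4 x 14 = 672 trials.
#'
#' @param family `"product"` or `"interaction"` (label only).
#' @param n_imitators Number of imitators (default 10).
#' @param order `"imitations_first"` or `"sketches_first"`.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(family = c("product", "interaction"),
                              n_imitators = 10,
                              order = c("imitations_first", "sketches_first")) {
  structure(list(family = match.arg(family), n_imitators = n_imitators,
                 order = match.arg(order),
                 profiles = c("impulsive", "repeated", "stationary", "complex"),
                 qualities = c("Q1", "Q2", "Q3"),
                 level_offsets = c(0, -5, -10)),
            class = "experiment_design")
}

#' Build the randomized trial table
#'
#' @param design An [experiment_design()].
#' @param seed RNG seed for within-block shuffling.
#' @return A data.frame with one row per trial: `trial` (presentation
#'   index), `block`, `block_name`, `type_of_sound`, `profile`, `category`
#'   (target/distractor), `exemplar`, `repetition`, `level_offset_db`.
#' @export
build_trial_table <- function(design = experiment_design(), seed = 1) {
  imit <- sprintf("imitation_%02d", seq_len(design$n_imitators))
  block_types <- if (design$order == "imitations_first") {
    c(list(imit), as.list(design$qualities), list("referent"))
  } else {
    c(as.list(design$qualities), list(imit), list("referent"))
  }
  block_names <- vapply(block_types, function(ts)
    if (length(ts) > 1) "imitations" else ts[1], character(1))
  rows <- list()
  for (b in seq_along(block_types)) {
    cell <- expand.grid(type_of_sound = block_types[[b]],
                        profile = design$profiles,
                        category = c("target", "distractor"),
                        exemplar = 1:2,
                        repetition = 1:3,
                        stringsAsFactors = FALSE)
    # the three repetitions of an exemplar get the three level offsets
    cell$level_offset_db <- design$level_offsets[cell$repetition]
    cell$block <- b
    cell$block_name <- block_names[b]
    rows[[b]] <- cell[with_seed(seed + b, sample.int(nrow(cell))), ]
  }
  out <- do.call(rbind, rows)
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("trial", "block", "block_name", "type_of_sound", "profile",
          "category", "exemplar", "repetition", "level_offset_db")]
}

#' Score yes/no responses into signal-detection results per cell
#'
#' Tallies hits (yes on target trials) and false alarms (yes on distractor
#' trials) per (type_of_sound, profile) cell — per participant if the
#' response table has a `participant` column — and derives d', ln(beta)
#' and the unbiased percent correct. Cells with missing responses are
#' flagged via `n_missing`, not dropped.
#'
#' @param trials A trial table from [build_trial_table()].
#' @param responses A data.frame with columns `trial`, logical/0-1 `yes`,
#'   and optionally `participant`.
#' @return A data.frame with one row per cell: counts, `dprime`,
#'   `ln_beta`, `upc`, `n_missing`.
#' @export
analyze_responses <- function(trials, responses) {
  stopifnot(all(c("trial", "yes") %in% names(responses)))
  if (!"participant" %in% names(responses)) responses$participant <- 1L
  # merge per participant against the full trial table so that trials
  # without a response stay visible (as NA) in that participant's cells
  m <- do.call(rbind, lapply(split(responses, responses$participant),
    function(rp) {
      mm <- merge(trials, rp[, c("trial", "yes")], by = "trial", all.x = TRUE)
      mm$participant <- rp$participant[1]
      mm
    }))
  key <- interaction(m$participant, m$type_of_sound, m$profile, drop = TRUE)
  cells <- split(m, key)
  out <- do.call(rbind, lapply(cells, function(cc) {
    tgt <- cc$category == "target"
    miss <- is.na(cc$yes)
    n_signal <- sum(tgt & !miss)
    n_noise <- sum(!tgt & !miss)
    n_hit <- sum(cc$yes[tgt & !miss])
    n_fa <- sum(cc$yes[!tgt & !miss])
    d <- if (n_signal >= 1 && n_noise >= 1)
      dprime_yesno(n_hit, n_signal, n_fa, n_noise) else NA_real_
    data.frame(participant = cc$participant[1],
               type_of_sound = cc$type_of_sound[1],
               profile = cc$profile[1],
               n_hit = n_hit, n_signal = n_signal,
               n_fa = n_fa, n_noise = n_noise,
               dprime = d,
               ln_beta = if (is.na(d)) NA_real_ else
                 ln_beta(n_hit, n_signal, n_fa, n_noise),
               upc = if (is.na(d)) NA_real_ else unbiased_pc(d),
               n_missing = sum(miss))
  }))
  rownames(out) <- NULL
  out
}
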