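#' Analysis parameters
#'
#' Shared constants of the behavioural analyses: the bin side of the
#' (nu_L, nu_R) plane (1 Hz), the snapshot window before sure-target onset
#' (50 ms), the minimum per-bin trial count below which conditional maps
#' are masked (30), the search range for the decision-time histogram dip
#' (100-1500 ms), the bootstrap sample count (10000) and the relative
#' value of the sure reward (0.8).
#'
#' @param bin_hz,snapshot_ms,min_count,dt_range,B,w_S see above
#' @param dt_bin decision-time histogram bin (ms)
#' @return an object of class `analysis_params`
#' @export
analysis_params <- function(bin_hz = 1, snapshot_ms = 50, min_count = 30,
                            dt_range = c(100, 1500), B = 10000, w_S = 0.8,
                            dt_bin = 10) {
  stopifnot(bin_hz > 0, snapshot_ms > 0, min_count > 0, B > 0, w_S >= 0,
            dt_bin > 0, length(dt_range) == 2, dt_range[1] < dt_range[2])
  structure(list(bin_hz = bin_hz, snapshot_ms = snapshot_ms,
                 min_count = min_count, dt_range = dt_range, B = B,
                 w_S = w_S, dt_bin = dt_bin), class = "analysis_params")
}

wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

#' Psychometric table
#'
#' Per condition (lambda, dlambda, duration): the probability of a correct
#' final choice on forced-choice trials, the probability of a correct
#' final choice on free-choice trials in which the sure target was shown
#' but waived, and the probability of choosing the sure target, with
#' Wilson 95% intervals and trial counts.  Undecided trials are excluded
#' from the correctness denominators but counted separately.
#'
#' @param trials a [run_ensemble()] table containing both forced- and
#'   free-choice trials
#' @return data frame of class `psychometric_table`
#' @export
psychometrics <- function(trials) {
  key <- interaction(trials$lambda, trials$dlambda, trials$duration,
                     drop = TRUE)
  out <- lapply(split(trials, key), function(d) {
    forced <- d[!d$free_choice, ]
    free <- d[d$free_choice, ]
    dec_f <- forced[forced$final_choice %in% c("L", "R"), ]
    waiv <- free[free$final_choice %in% c("L", "R"), ]
    n_s <- sum(free$final_choice == "S")
    ci_f <- wilson_ci(sum(dec_f$final_correct), nrow(dec_f))
    ci_w <- wilson_ci(sum(waiv$final_correct), nrow(waiv))
    ci_s <- wilson_ci(n_s, nrow(free))
    data.frame(lambda = d$lambda[1], dlambda = d$dlambda[1],
               duration = d$duration[1],
               p_correct_forced = mean(dec_f$final_correct),
               p_correct_forced_lo = ci_f[1], p_correct_forced_hi = ci_f[2],
               n_forced = nrow(dec_f),
               p_correct_waived = mean(waiv$final_correct),
               p_correct_waived_lo = ci_w[1], p_correct_waived_hi = ci_w[2],
               n_waived = nrow(waiv),
               p_sure = if (nrow(free)) n_s / nrow(free) else NA_real_,
               p_sure_lo = ci_s[1], p_sure_hi = ci_s[2],
               n_free = nrow(free),
               undecided_forced = if (nrow(forced))
                 mean(forced$final_choice == "undecided") else NA_real_,
               undecided_free = if (nrow(free))
                 mean(free$final_choice == "undecided") else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$lambda, out$duration, out$dlambda), ]
  class(out) <- c("psychometric_table", "data.frame")
  out
}

#' Conditional sure-choice map
#'
#' Probability of an eventual sure choice given the state of the decision
#' pools just before the sure target appears: free-choice trials are binned
#' by their (nu_L, nu_R) snapshot in square bins of side `bin_hz`, and the
#' fraction of trials per bin ending in a sure choice is reported.  Bins
#' with fewer than `min_count` trials are masked (`NA`).  By default all
#' stimulus conditions are pooled; pass a subset of `trials` for
#' per-condition maps.
#'
#' @param trials free-choice trials from [run_ensemble()]
#' @param params an [analysis_params()]
#' @return data frame `(nu_L, nu_R, n, p_sure, masked)` of class
#'   `sure_map`
#' @export
conditional_sure_map <- function(trials, params = analysis_params()) {
  d <- trials[trials$free_choice, ]
  if (!nrow(d)) stop("no free-choice trials")
  bl <- floor(d$nu_L / params$bin_hz)
  br <- floor(d$nu_R / params$bin_hz)
  key <- paste(bl, br)
  agg <- lapply(split(seq_len(nrow(d)), key), function(i) {
    n <- length(i)
    data.frame(nu_L = (bl[i[1]] + 0.5) * params$bin_hz,
               nu_R = (br[i[1]] + 0.5) * params$bin_hz, n = n,
               p_sure = sum(d$final_choice[i] == "S") / n)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out$masked <- out$n < params$min_count
  out$p_sure[out$masked] <- NA_real_
  class(out) <- c("sure_map", "data.frame")
  out
}

#' Projections of the sure-choice probability
#'
#' `1 - P(S)` binned along the absolute rate difference `|nu_L - nu_R|`
#' and along the summed rate `nu_L + nu_R` of the snapshot.  Both
#' projections are expected to rise sigmoidally in this model: not only the
#' difference but also the total activity of the decision pools is
#' informative about the upcoming sure choice.  The deviation from
#' monotonicity is summarised by the residual of an isotonic fit.
#'
#' @param trials free-choice trials
#' @param bin bin width (Hz)
#' @return list of two data frames `diff` and `sum` (columns `x`,
#'   `one_minus_p_sure`, `n`), each with attribute `isotonic_residual`
#'   (RMS residual of the isotonic regression, as a fraction of the range)
#' @export
sure_probability_projections <- function(trials, bin = 2) {
  d <- trials[trials$free_choice, ]
  if (!nrow(d)) stop("no free-choice trials")
  proj <- function(x) {
    b <- floor(x / bin)
    agg <- lapply(split(seq_along(x), b), function(i)
      data.frame(x = (b[i[1]] + 0.5) * bin,
                 one_minus_p_sure = mean(d$final_choice[i] != "S"),
                 n = length(i)))
    out <- do.call(rbind, agg)
    out <- out[order(out$x), ]
    rownames(out) <- NULL
    iso <- stats::isoreg(out$x, out$one_minus_p_sure)
    res <- sqrt(stats::weighted.mean((iso$yf - out$one_minus_p_sure)^2,
                                     out$n))
    rng <- diff(range(out$one_minus_p_sure))
    attr(out, "isotonic_residual") <- if (rng > 0) res / rng else 0
    out
  }
  list(diff = proj(abs(d$nu_L - d$nu_R)), sum = proj(d$nu_L + d$nu_R))
}

#' Split decision times at the histogram dip
#'
#' Locates the minimum of the decision-time histogram (bin width
#' `dt_bin`, counts smoothed by a 3-bin moving average) inside
#' `dt_range` and partitions the decided trials into a fast and a slow
#' group at that point.  A minimum sitting on the boundary of the search
#' range indicates a unimodal distribution and is flagged (`interior_dip =
#' FALSE`), as in the bistable regime where the bimodality disappears.
#'
#' @param trials trials with decision times
#' @param params an [analysis_params()]
#' @return list `(split_ms, interior_dip, fast, slow, histogram)`
#' @export
dt_split <- function(trials, params = analysis_params()) {
  d <- trials[!is.na(trials$dt), ]
  if (!nrow(d)) stop("no decided trials")
  breaks <- seq(0, max(d$dt) + params$dt_bin, by = params$dt_bin)
  h <- graphics::hist(d$dt, breaks = breaks, plot = FALSE)
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
  cnt[is.na(cnt)] <- h$counts[is.na(cnt)]
  mid <- h$mids
  inside <- which(mid >= params$dt_range[1] & mid <= params$dt_range[2])
  if (!length(inside)) stop("no histogram bins inside the search range")
  k <- inside[which.min(cnt[inside])]
  split <- mid[k]
  # a genuine dip has substantial mass on both sides of the minimum
  rise <- cnt[k] + max(1, 0.1 * max(cnt))
  interior <- k > 1 && k < length(cnt) &&
    any(cnt[seq_len(k - 1)] > rise) &&
    any(cnt[(k + 1):length(cnt)] > rise)
  list(split_ms = split, interior_dip = interior,
       fast = d[d$dt <= split, ], slow = d[d$dt > split, ],
       histogram = data.frame(mid = mid, count = h$counts,
                              smoothed = cnt))
}

#' Bootstrap comparison of error counts in fast and slow trials
#'
#' Resamples each group with replacement `B` times, counting error trials
#' (early choice incorrect) per resample, and compares the two bootstrap
#' distributions of error counts with a two-sample t-test.
#'
#' @param fast,slow trial subsets (e.g. from [dt_split()])
#' @param B bootstrap samples
#' @param seed RNG seed
#' @return list `(fast_counts, slow_counts, t_test)`
#' @export
bootstrap_error_counts <- function(fast, slow, B = 10000, seed = 1) {
  stopifnot(nrow(fast) > 0, nrow(slow) > 0)
  set.seed(seed)
  boot <- function(d) {
    err <- !d$correct
    err <- err[!is.na(err)]
    vapply(seq_len(B), function(i)
      sum(sample(err, length(err), replace = TRUE)), numeric(1))
  }
  fc <- boot(fast); sc <- boot(slow)
  list(fast_counts = fc, slow_counts = sc,
       t_test = stats::t.test(fc, sc))
}

#' X-pattern of sure choices from simulated trials
#'
#' Probability of a sure choice as a function of the evidence `dlambda`,
#' conditioned on the early outcome (correct vs error): the model predicts
#' opposite monotonic trends, decreasing with evidence on early-correct
#' trials and increasing on early-error trials.
#'
#' @param trials free-choice trials
#' @return data frame `(dlambda, outcome, p_sure, lo, hi, n)`
#' @export
xpattern_simulated <- function(trials) {
  d <- trials[trials$free_choice & !is.na(trials$correct), ]
  out <- lapply(split(d, list(d$dlambda, d$correct), drop = TRUE),
                function(g) {
    k <- sum(g$final_choice == "S")
    ci <- wilson_ci(k, nrow(g))
    data.frame(dlambda = g$dlambda[1],
               outcome = if (g$correct[1]) "correct" else "error",
               p_sure = k / nrow(g), lo = ci[1], hi = ci[2], n = nrow(g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$outcome, out$dlambda), ]
}

#' X-pattern from the reduced probabilistic model
#'
#' Conditional sure-choice probabilities computed from behavioural
#' quantities alone, assuming only that presenting the sure target does
#' not change the overall probability of a correct decision.  With
#' P(C) the probability of an (early) correct decision, P(S) the sure
#' probability and P(C|S-bar) the accuracy when the sure target was shown
#' but waived:
#' \deqn{P(S|C) = [P(C) - P(C|\bar S) + P(S) P(C|\bar S)] / P(C)}
#' \deqn{P(S|E) = 1 - [1 - P(C|\bar S)] [1 - P(S)] / [1 - P(C)]}
#' These satisfy the law of total probability
#' `P(S|C) P(C) + P(S|E) P(E) = P(S)` exactly.
#'
#' @param p_correct,p_sure,p_correct_waived numeric vectors in `[0, 1]`
#' @return data frame `(p_sure_correct, p_sure_error)`; entries where a
#'   conditioning probability vanishes are `NA`
#' @export
xpattern_probabilistic <- function(p_correct, p_sure, p_correct_waived) {
  stopifnot(all(p_correct >= 0 & p_correct <= 1, na.rm = TRUE),
            all(p_sure >= 0 & p_sure <= 1, na.rm = TRUE),
            all(p_correct_waived >= 0 & p_correct_waived <= 1, na.rm = TRUE))
  psc <- (p_correct - p_correct_waived + p_sure * p_correct_waived) /
    p_correct
  psc[p_correct == 0] <- NA_real_
  pse <- 1 - (1 - p_correct_waived) * (1 - p_sure) / (1 - p_correct)
  pse[p_correct == 1] <- NA_real_
  data.frame(p_sure_correct = psc, p_sure_error = pse)
}

#' Mean reward amount
#'
#' Expected reward per trial with a correct choice worth 1, an error 0 and
#' the sure choice `w_S`: `P(correct) + P(S) * w_S`.  The per-trial
#' variant sums the realised choice values over a trial table.
#'
#' @param p_correct,p_sure probabilities (per condition or overall);
#'   `p_correct` is the unconditional probability of a correct final
#'   choice (not conditioned on waiving)
#' @param w_S relative value of the sure reward
#' @return numeric mean reward (arbitrary units, correct = 1)
#' @export
reward_amount <- function(p_correct, p_sure, w_S = 0.8) {
  p_correct + p_sure * w_S
}

#' @rdname reward_amount
#' @param trials a trial table; reward counts final choices (correct
#'   direction 1, error 0, sure `w_S`, undecided 0)
#' @export
reward_per_trial <- function(trials, w_S = 0.8) {
  v <- ifelse(trials$final_choice == "S", w_S,
              ifelse(is.na(trials$final_correct), 0,
                     as.numeric(trials$final_correct)))
  mean(v)
}

#' Snapshot rate distributions
#'
#' Normalised 2-D histograms (bins of `bin_hz`) of the (nu_L, nu_R)
#' snapshot, grouped by condition and optionally by early outcome, with
#' the across-diagonal asymmetry summarised per group: the mean signed
#' distance to the diagonal and the mean absolute rate difference.
#'
#' @param trials trial table
#' @param by grouping columns
#' @param params an [analysis_params()]
#' @return list `(histograms, summary)`: long-format counts per group and
#'   a per-group summary data frame
#' @export
rate_distributions <- function(trials, by = c("dlambda", "duration"),
                               params = analysis_params()) {
  key <- interaction(trials[by], drop = TRUE)
  hists <- lapply(split(trials, key), function(g) {
    bl <- floor(g$nu_L / params$bin_hz)
    br <- floor(g$nu_R / params$bin_hz)
    tab <- as.data.frame(table(paste(bl, br)), stringsAsFactors = FALSE)
    xy <- do.call(rbind, strsplit(tab$Var1, " "))
    out <- data.frame(nu_L = (as.numeric(xy[, 1]) + 0.5) * params$bin_hz,
                      nu_R = (as.numeric(xy[, 2]) + 0.5) * params$bin_hz,
                      p = tab$Freq / nrow(g))
    for (b in by) out[[b]] <- g[[b]][1]
    out
  })
  summ <- lapply(split(trials, key), function(g) {
    out <- data.frame(n = nrow(g),
                      mean_signed_diff = mean(g$nu_L - g$nu_R),
                      mean_abs_diff = mean(abs(g$nu_L - g$nu_R)))
    for (b in by) out[[b]] <- g[[b]][1]
    out
  })
  list(histograms = do.call(rbind, hists), summary = do.call(rbind, summ))
}
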