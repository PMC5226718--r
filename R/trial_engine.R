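#' Decision-rule parameters
#'
#' Threshold rule used to read out choices from population rates: a
#' decision is registered at the first time a decision pool's rate crosses
#' `theta` and stays at or above it for the subsequent `sustain`
#' milliseconds.  Population rates are estimated in a sliding (trailing)
#' window.  The default threshold of 28 Hz is calibrated for the
#' multistable operating point (`lambda` = 50 Hz) so that fewer than 5% of
#' trials are undecided at the go cue; the bistable preset (`lambda` = 15
#' Hz) uses 24 Hz by the same criterion.
#'
#' @param theta decision threshold (Hz)
#' @param sustain required supra-threshold duration after the crossing (ms)
#' @param window rate-estimation window (ms)
#' @param step rate-estimation step (ms)
#' @return an object of class `decision_params`
#' @export
decision_params <- function(theta = 28, sustain = 50, window = 50,
                            step = 5) {
  stopifnot(theta > 0, sustain > 0, window >= step, step > 0)
  structure(list(theta = theta, sustain = sustain, window = window,
                 step = step), class = "decision_params")
}

#' Population firing-rate trace
#'
#' Sliding-window estimate of a pool's population rate: the spike count of
#' the pool in the trailing window `(t - window, t]`, divided by the window
#' length and the pool size.  The trailing (causal) alignment means the
#' estimate at time `t` uses only spikes up to `t`.
#'
#' @param spikes a [simulate_trial()] record
#' @param pool pool name (`"L"`, `"R"`, `"S"`, `"nonspecific"`,
#'   `"inhibitory"`) or index
#' @param window,step window length and sampling step (ms)
#' @param t_end trace end time (ms); defaults to the protocol's trial end
#'   or the last spike time
#' @return data frame `(time_ms, rate)` with the window metadata attached
#' @export
pool_rate <- function(spikes, pool, window = 50, step = 5, t_end = NULL) {
  stopifnot(window >= step)
  if (is.character(pool)) pool <- match(pool, POOLS)
  sizes <- attr(spikes, "pool_sizes")
  if (is.na(pool) || pool < 1 || pool > length(sizes))
    stop("unknown pool")
  if (sizes[pool] == 0) stop("pool is empty")
  if (is.null(t_end)) {
    pr <- attr(spikes, "protocol")
    t_end <- if (!is.null(pr)) pr$trial_end else max(spikes$time_ms, 0)
  }
  st <- sort(spikes$time_ms[spike_pools(spikes) == pool])
  tt <- seq(step, t_end, by = step)
  n_hi <- findInterval(tt, st)
  n_lo <- findInterval(tt - window, st)
  r <- (n_hi - n_lo) / (sizes[pool] * window * 1e-3)
  structure(data.frame(time_ms = tt, rate = r),
            window = window, step = step, pool = POOLS[pool])
}

#' Rate traces of the three selective pools
#'
#' @inheritParams pool_rate
#' @return data frame `(time_ms, L, R, S)` with window metadata
#' @export
rate_traces <- function(spikes, window = 50, step = 5, t_end = NULL) {
  tr <- lapply(1:3, function(p) pool_rate(spikes, p, window, step, t_end))
  structure(data.frame(time_ms = tr[[1]]$time_ms, L = tr[[1]]$rate,
                       R = tr[[2]]$rate, S = tr[[3]]$rate),
            window = window, step = step)
}

# First sustained threshold crossing of one rate vector.  Returns the
# crossing time or NA.  `tt` sample times; eligibility window [from, until].
first_sustained_crossing <- function(tt, rate, theta, sustain, step,
                                     from, until) {
  idx <- which(rate >= theta & tt >= from & tt <= until)
  for (i in idx) {
    j <- which(tt >= tt[i] & tt <= min(tt[i] + sustain, until))
    if (all(rate[j] >= theta)) return(tt[i])
  }
  NA_real_
}

#' Detect a decision from rate traces
#'
#' Applies the threshold rule of [decision_params()] to the given decision
#' pools: the winner is the pool with the earliest time at which its rate
#' reaches `theta` and stays at or above it for the subsequent `sustain`
#' ms (evaluated on the available samples up to `until`).  The decision
#' time is reported relative to `dt_origin` (normally the motion onset).
#'
#' @param traces a [rate_traces()] data frame
#' @param params a [decision_params()]
#' @param from_time earliest eligible crossing time (ms)
#' @param until latest eligible time, normally the go cue (ms)
#' @param pools candidate pool columns
#' @param dt_origin time decision times are measured from (ms)
#' @return list `(winner, t_cross, dt)`; winner `"undecided"` and NAs when
#'   no pool satisfies the rule
#' @export
detect_decision <- function(traces, params = decision_params(),
                            from_time = 0, until = Inf,
                            pools = c("L", "R"), dt_origin = from_time) {
  tt <- traces$time_ms
  cross <- vapply(pools, function(p)
    first_sustained_crossing(tt, traces[[p]], params$theta, params$sustain,
                             attr(traces, "step"), from_time, until),
    numeric(1))
  if (all(is.na(cross)))
    return(list(winner = "undecided", t_cross = NA_real_, dt = NA_real_))
  w <- which.min(cross)
  list(winner = pools[w], t_cross = unname(cross[w]),
       dt = unname(cross[w]) - dt_origin)
}

#' Detect a change of mind
#'
#' A change of mind is registered when the pool dominating at the go cue
#' (largest mean rate over the `window` ms preceding it) differs from the
#' pool that first satisfied the threshold rule.
#'
#' @param traces a [rate_traces()] data frame
#' @param decision a [detect_decision()] result with a winner
#' @param go_cue go-cue time (ms)
#' @param pools pools competing at the go cue
#' @param window averaging window before the go cue (ms)
#' @return logical flag, plus the dominant pool as attribute `dominant`
#' @export
detect_change_of_mind <- function(traces, decision, go_cue,
                                  pools = c("L", "R"), window = 50) {
  stopifnot(decision$winner != "undecided")
  sel <- traces$time_ms > go_cue - window & traces$time_ms <= go_cue
  m <- vapply(pools, function(p) mean(traces[[p]][sel]), numeric(1))
  dom <- pools[which.max(m)]
  structure(dom != decision$winner, dominant = dom)
}

#' Classify one trial
#'
#' Reduces a spike record to the trial-level outcome: the early choice
#' (decision state before sure-target onset), the final choice (first pool
#' -- including S on free-choice trials, from its onset -- to satisfy the
#' threshold rule before the go cue), the decision time from motion onset,
#' the (nu_L, nu_R) snapshot averaged over the 50 ms preceding sure-target
#' onset (computed at the equivalent time on forced-choice trials so the
#' distributions are comparable), the change-of-mind flag and correctness.
#' With positive evidence (`dlambda > 0`) pool L receives the stronger
#' input, so L is the correct direction; at `dlambda = 0` the correct label
#' is the conventional L.  If the threshold rule selects no early winner,
#' the early choice falls back to the pool dominating the snapshot, so that
#' every trial carries an early correct/error label.
#'
#' @param spikes a [simulate_trial()] record
#' @param protocol the trial's protocol (defaults to the one attached to
#'   `spikes`)
#' @param params a [decision_params()]
#' @return one-row data frame (a `TrialResult`)
#' @export
classify_trial <- function(spikes, protocol = attr(spikes, "protocol"),
                           params = decision_params()) {
  stopifnot(!is.null(protocol))
  tr <- rate_traces(spikes, params$window, params$step,
                    t_end = protocol$trial_end)
  sizes <- attr(spikes, "pool_sizes")
  pid <- spike_pools(spikes)
  snap_win <- c(protocol$sure_onset - 50, protocol$sure_onset)
  snap <- vapply(1:3, function(p)
    sum(pid == p & spikes$time_ms > snap_win[1] &
          spikes$time_ms <= snap_win[2]) / (sizes[p] * 50e-3), numeric(1))
  # mean pool-S rate from trial start to the go cue (saccade signal excluded)
  s_rate <- sum(pid == 3 & spikes$time_ms <= protocol$go_cue) /
    (sizes[3] * protocol$go_cue * 1e-3)

  early <- detect_decision(tr, params, from_time = protocol$motion_onset,
                           until = protocol$sure_onset, pools = c("L", "R"),
                           dt_origin = protocol$motion_onset)
  early_rule <- early$winner
  early_choice <- early$winner
  if (early_choice == "undecided")
    early_choice <- if (snap[1] > snap[2]) "L" else if (snap[2] > snap[1])
      "R" else "undecided"

  pools_final <- c("L", "R", if (protocol$free_choice) "S")
  cand <- lapply(pools_final, function(p) {
    from <- if (p == "S") protocol$sure_onset else protocol$motion_onset
    detect_decision(tr, params, from_time = from, until = protocol$go_cue,
                    pools = p, dt_origin = protocol$motion_onset)
  })
  tc <- vapply(cand, function(d) ifelse(is.na(d$t_cross), Inf, d$t_cross),
               numeric(1))
  if (all(!is.finite(tc))) {
    final_choice <- "undecided"; dtime <- NA_real_; com <- NA
  } else {
    k <- which.min(tc)
    final_choice <- pools_final[k]
    dtime <- cand[[k]]$dt
    # change of mind in the direction-decision sense: the dominant
    # *direction* pool at the go cue differs from the threshold winner.
    # An eventual opt-out (pool S taking over) is not a change of mind.
    com <- if (final_choice %in% c("L", "R"))
      as.logical(detect_change_of_mind(tr, cand[[k]], protocol$go_cue,
                                       pools = c("L", "R"),
                                       window = params$window))
    else FALSE
  }
  data.frame(lambda = protocol$lambda, dlambda = protocol$dlambda,
             duration = protocol$duration,
             free_choice = protocol$free_choice,
             seed = attr(spikes, "seed") %||% NA_integer_,
             early_choice = early_choice, early_rule = early_rule,
             final_choice = final_choice, dt = dtime,
             nu_L = snap[1], nu_R = snap[2], nu_S = snap[3],
             s_rate = s_rate,
             change_of_mind = com,
             correct = if (early_choice == "undecided") NA else
               early_choice == "L",
             final_correct = if (final_choice %in% c("L", "R"))
               final_choice == "L" else NA,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an ensemble of trials
#'
#' Simulates `n_trials` spiking trials for every row of the condition
#' grid and classifies each one.  Trial `i` of the whole ensemble uses seed
#' `base_seed + i - 1`, so ensembles are reproducible and any trial can be
#' re-simulated in isolation.  Failures of single trials are recorded (with
#' their seed) and skipped.
#'
#' @param network a [build_network()] object
#' @param conditions data frame with columns `lambda`, `dlambda`,
#'   `duration`, `free_choice`
#' @param n_trials trials per condition
#' @param base_seed first seed
#' @param params a [decision_params()]
#' @param dt integration step (ms)
#' @param file optional CSV path; results are appended as they are produced
#' @param verbose print progress
#' @param ... passed to [assemble_protocol()]
#' @return data frame of class `trial_set`, one row per trial
#' @export
run_ensemble <- function(network, conditions, n_trials = 50, base_seed = 1,
                         params = decision_params(), dt = 0.05,
                         file = NULL, verbose = FALSE, ...) {
  stopifnot(all(c("lambda", "dlambda", "duration", "free_choice") %in%
                  names(conditions)))
  rows <- list()
  idx <- 0
  for (ci in seq_len(nrow(conditions))) {
    cc <- conditions[ci, ]
    pr <- assemble_protocol(duration = cc$duration, lambda = cc$lambda,
                            dlambda = cc$dlambda,
                            free_choice = cc$free_choice, ...)
    for (k in seq_len(n_trials)) {
      idx <- idx + 1
      seed <- base_seed + idx - 1
      res <- tryCatch({
        sp <- simulate_trial(network, pr, seed = seed, dt = dt)
        classify_trial(sp, pr, params)
      }, error = function(e) {
        warning("trial with seed ", seed, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- res
      if (!is.null(file))
        utils::write.table(res, file, append = file.exists(file),
                           col.names = !file.exists(file), sep = ",",
                           row.names = FALSE)
    }
    if (verbose)
      message(sprintf("condition %d/%d done (lambda=%g dlambda=%g dur=%g %s)",
                      ci, nrow(conditions), cc$lambda, cc$dlambda,
                      cc$duration,
                      if (cc$free_choice) "free" else "forced"))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trial_set", "data.frame")
  out
}

#' Calibrate the decision threshold
#'
#' Chooses the largest threshold from `grid` for which the undecided
#' fraction of a pilot ensemble stays below `max_undecided` (the criterion
#' used to set the reference thresholds: 28 Hz in the multistable regime,
#' 24 Hz in the bistable one).  If no candidate passes, the threshold with
#' the lowest undecided fraction is returned.
#'
#' @param network a [build_network()] object
#' @param conditions condition grid (see [run_ensemble()])
#' @param n_trials pilot trials per condition
#' @param grid candidate thresholds (Hz)
#' @param max_undecided tolerated undecided fraction at the go cue
#' @param ... passed to [run_ensemble()]
#' @return chosen threshold (Hz) with the pilot undecided fractions as
#'   attribute `undecided`
#' @export
calibrate_threshold <- function(network, conditions, n_trials = 20,
                                grid = seq(20, 36, by = 2),
                                max_undecided = 0.05, ...) {
  und <- vapply(grid, function(th) {
    ts <- run_ensemble(network, conditions, n_trials,
                       params = decision_params(theta = th), ...)
    mean(ts$final_choice == "undecided")
  }, numeric(1))
  ok <- which(und < max_undecided)
  th <- if (length(ok)) grid[max(ok)] else grid[which.min(und)]
  structure(th, undecided = stats::setNames(und, grid))
}
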