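test_that("pool rate estimator recovers a known rate and smooths with wider windows", {
  sp <- fake_spike_record(list(L = regular_train(4, 10, 2000, jitter = 50)))
  tr <- pool_rate(sp, "L", window = 50, step = 5, t_end = 2000)
  mid <- tr$rate[tr$time_ms > 200]
  expect_equal(mean(mid), 10, tolerance = 0.05)
  expect_true(all(tr$rate >= 0))
  tr100 <- pool_rate(sp, "L", window = 100, step = 5, t_end = 2000)
  expect_equal(mean(tr100$rate[tr100$time_ms > 200]), 10, tolerance = 0.05)
  expect_lte(stats::var(tr100$rate[tr100$time_ms > 200]),
             stats::var(mid) + 1e-12)
  # no spikes -> all-zero trace
  empty <- fake_spike_record(list(L = data.frame(neuron = integer(),
                                                 time_ms = numeric())))
  expect_true(all(pool_rate(empty, "L", t_end = 500)$rate == 0))
  expect_error(pool_rate(sp, "L", window = 2, step = 5))
})

test_that("decision detection applies the threshold-plus-sustain rule", {
  tt <- seq(5, 2500, by = 5)
  flat <- fake_traces(tt, L = rep(10, length(tt)), R = rep(10, length(tt)))
  d0 <- detect_decision(flat, decision_params(theta = 28), from_time = 1000,
                        until = 2400)
  expect_equal(d0$winner, "undecided")
  step_up <- fake_traces(tt, L = ifelse(tt >= 1800, 30, 10),
                         R = rep(10, length(tt)))
  d1 <- detect_decision(step_up, decision_params(theta = 28),
                        from_time = 1000, until = 2400, dt_origin = 1000)
  expect_equal(d1$winner, "L")
  expect_equal(d1$dt, 800)
  # a 40 ms excursion above threshold does not satisfy the 50 ms sustain
  blip <- fake_traces(tt, L = ifelse(tt >= 1800 & tt < 1840, 30, 10),
                      R = rep(10, length(tt)))
  d2 <- detect_decision(blip, decision_params(theta = 28), from_time = 1000,
                        until = 2400)
  expect_equal(d2$winner, "undecided")
})

test_that("change of mind is the go-cue dominance differing from the threshold winner", {
  tt <- seq(5, 2500, by = 5)
  # L crosses first, R dominates at the go cue
  tr <- fake_traces(tt, L = ifelse(tt >= 1200 & tt < 1800, 30, 5),
                    R = ifelse(tt >= 1900, 35, 5))
  dec <- detect_decision(tr, decision_params(theta = 28), from_time = 1000,
                         until = 2400)
  expect_equal(dec$winner, "L")
  expect_true(as.logical(detect_change_of_mind(tr, dec, go_cue = 2400)))
  # winner stays dominant -> no change of mind
  tr2 <- fake_traces(tt, L = ifelse(tt >= 1200, 30, 5),
                     R = rep(5, length(tt)))
  dec2 <- detect_decision(tr2, decision_params(theta = 28),
                          from_time = 1000, until = 2400)
  expect_false(as.logical(detect_change_of_mind(tr2, dec2, go_cue = 2400)))
})

test_that("trial classification: forced trials never choose S; snapshots are taken before sure onset", {
  pr <- assemble_protocol(duration = 300, lambda = 50, dlambda = 7,
                          free_choice = FALSE)
  # R pool firing at 30 Hz from motion onset on; S silent; L at 4 Hz
  mk <- function(pool, rate, from, to)
    within(regular_train(4, rate, to - from), time_ms <- time_ms + from)
  sp <- fake_spike_record(list(
    L = mk("L", 4, 0, pr$trial_end),
    R = mk("R", 30, pr$motion_onset + 100, pr$trial_end)),
    protocol = pr)
  res <- classify_trial(sp, pr, decision_params(theta = 20))
  expect_equal(res$final_choice, "R")
  expect_false(res$final_correct)
  expect_false(res$correct)       # early choice R, dlambda > 0 makes L correct
  expect_gt(res$nu_R, 20)
  expect_lt(res$nu_L, 10)
  expect_false(res$change_of_mind)
})

test_that("ensembles are reproducible from the base seed and carry per-trial seeds", {
  net <- build_network(network_spec(N = 100))
  conds <- data.frame(lambda = 50, dlambda = 14, duration = 100,
                      free_choice = c(TRUE, FALSE))
  args <- list(net, conds, n_trials = 3, base_seed = 42,
               spontaneous_duration = 100, target_duration = 200,
               post_sure = 300)
  a <- do.call(run_ensemble, args)
  b <- do.call(run_ensemble, args)
  expect_identical(a, b)
  expect_equal(a$seed, 42:47)
  expect_equal(nrow(a), 6)
  expect_true(all(a$final_choice[!a$free_choice] != "S"))
})
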