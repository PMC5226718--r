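# Constructed fixtures for the trial engine and analysis tests.

# A spike record built by hand: `spikes` is a list of data.frames with
# columns neuron (within-pool index) and time_ms, one per pool name.
fake_spike_record <- function(spikes, pool_sizes = c(4, 4, 4, 8, 5),
                              protocol = NULL) {
  start <- cumsum(c(0, pool_sizes))
  rows <- lapply(names(spikes), function(p) {
    i <- match(p, c("L", "R", "S", "nonspecific", "inhibitory"))
    d <- spikes[[p]]
    data.frame(neuron = start[i] + d$neuron, time_ms = d$time_ms)
  })
  sp <- do.call(rbind, rows)
  sp <- sp[order(sp$time_ms), ]
  attr(sp, "pool_sizes") <- pool_sizes
  attr(sp, "pool_id") <- rep.int(seq_along(pool_sizes), pool_sizes)
  attr(sp, "protocol") <- protocol
  class(sp) <- c("spike_record", "data.frame")
  sp
}

# Regular spike train at `rate` Hz for each of `n` neurons over [0, t_end).
regular_train <- function(n, rate, t_end, jitter = 0) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- seq(1000 / rate, t_end, by = 1000 / rate)
    data.frame(neuron = i, time_ms = tt + jitter * (i - 1) / n)
  }))
}

# A synthetic rate-traces object (bypassing spike records).
fake_traces <- function(time_ms, L, R, S = rep(2, length(time_ms)),
                        step = 5) {
  structure(data.frame(time_ms = time_ms, L = L, R = R, S = S),
            window = 50, step = step)
}

# A synthetic trial table with the columns the analysis functions use.
fake_trials <- function(n, dlambda = 0, duration = 500, lambda = 50,
                        free_choice = TRUE, final_choice = "L",
                        early_choice = final_choice, dt = NA_real_,
                        nu_L = 5, nu_R = 5) {
  data.frame(lambda = lambda, dlambda = dlambda, duration = duration,
             free_choice = free_choice, seed = seq_len(n),
             early_choice = early_choice, early_rule = early_choice,
             final_choice = final_choice, dt = dt,
             nu_L = nu_L, nu_R = nu_R, nu_S = 2, s_rate = 2,
             change_of_mind = FALSE,
             correct = ifelse(early_choice == "undecided", NA,
                              early_choice == "L"),
             final_correct = ifelse(final_choice %in% c("L", "R"),
                                    final_choice == "L", NA))
}
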