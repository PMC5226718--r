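test_that("network construction derives the pool structure and rejects degenerate fractions", {
  spec <- network_spec(N = 1000, f = 0.2)
  expect_equal(unname(spec$pools), c(160, 160, 160, 320, 200))
  small <- network_spec(N = 100)
  expect_equal(unname(small$pools), c(16, 16, 16, 32, 20))
  expect_error(network_spec(f = 0), "fraction")
  expect_error(network_spec(N = 1003), "integer")
  W <- structured_weights(spec)
  expect_equal(diag(W)[1:3], rep(1.5, 3), ignore_attr = TRUE)
  expect_equal(W["nonspecific", "L"], 0.878, ignore_attr = TRUE)
  expect_equal(W["inhibitory", "L"], 1, ignore_attr = TRUE)
  expect_equal(W["L", "nonspecific"], 1, ignore_attr = TRUE)
})

test_that("reduced networks scale recurrent conductances to preserve the operating point", {
  net <- build_network(network_spec(N = 200), nmda_efficacy = 1)
  # per-connection conductance x number of excitatory neurons is preserved
  expect_equal(net$class_params$g_nmda[1] * net$spec$N_E, 0.327 * 800)
  expect_equal(net$class_params$g_gaba[1] * net$spec$N_I, 1.287 * 200)
  # external conductance is not size-dependent
  expect_equal(net$class_params$g_ampa_ext[1], 2.08)
})

test_that("NMDA voltage gate follows the magnesium-block form", {
  expect_equal(nmda_voltage_gate(0, mg = 0), 1)
  expect_gt(nmda_voltage_gate(200), 0.9999)
  expect_equal(nmda_voltage_gate(-70, mg = 1),
               1 / (1 + exp(-0.062 * -70) / 3.57))
  expect_true(all(diff(nmda_voltage_gate(seq(-90, 0))) > 0))
})

test_that("a quiescent network at the leak reversal stays put, and threshold triggers spike + reset", {
  syn0 <- synapse_params(g_ampa_ext_exc = 0, g_ampa_ext_inh = 0,
                         g_ampa_rec_exc = 0, g_ampa_rec_inh = 0,
                         g_nmda_exc = 0, g_nmda_inh = 0,
                         g_gaba_exc = 0, g_gaba_inh = 0)
  net <- build_network(network_spec(N = 100), syn = syn0)
  st <- lif_init_state(net)
  res <- lif_step(net, st, rep(0, 5), n_steps = 1)
  expect_equal(res$state$V, st$V)          # equilibrium at V_L
  expect_equal(nrow(res$spikes), 0)
  # place one neuron at threshold: it must fire once and reset
  st$V[1] <- -49.9
  res2 <- lif_step(net, st, rep(0, 5), n_steps = 2)
  expect_equal(res2$spikes$neuron, 1)
  expect_equal(res2$state$V[1], -55)
})

test_that("trials are deterministic given the seed and respect the refractory period", {
  net <- build_network(network_spec(N = 100))
  pr <- assemble_protocol(duration = 100, lambda = 50, dlambda = 0,
                          spontaneous_duration = 100,
                          target_duration = 200, post_sure = 300)
  a <- simulate_trial(net, pr, seed = 5)
  b <- simulate_trial(net, pr, seed = 5)
  expect_identical(a$neuron, b$neuron)
  expect_identical(a$time_ms, b$time_ms)
  c <- simulate_trial(net, pr, seed = 6)
  expect_false(identical(a$time_ms, c$time_ms))
  # no neuron fires within its refractory period
  rp <- ifelse(net$pool_id <= 4, 2, 1)
  for (n in unique(a$neuron)) {
    isi <- diff(a$time_ms[a$neuron == n])
    if (length(isi)) expect_gte(min(isi), rp[n])
  }
})

test_that("NMDA gating stays saturating (s <= 1) under strong drive", {
  net <- build_network(network_spec(N = 100))
  res <- lif_step(net, lif_init_state(net), rep(8000, 5), n_steps = 4000)
  expect_true(all(res$state$s_nmda <= 1))
  expect_true(all(res$state$s_nmda >= 0))
  expect_true(all(res$state$s_ampa_ext >= 0))
})

test_that("halving the integration step changes firing rates by < 5%", {
  # with recurrence the network state itself fluctuates slowly (and seeds
  # cannot be paired across step sizes), so integration accuracy is
  # measured where neurons are independent: external drive only
  syn0 <- synapse_params(g_ampa_rec_exc = 0, g_ampa_rec_inh = 0,
                         g_nmda_exc = 0, g_nmda_inh = 0,
                         g_gaba_exc = 0, g_gaba_inh = 0)
  net <- build_network(network_spec(N = 200), syn = syn0)
  rate_at <- function(dt) {
    set.seed(17)
    res <- lif_step(net, lif_init_state(net),
                    matrix(2400, 4000 / dt, 5), dt = dt,
                    n_steps = 4000 / dt)
    sum(res$spikes$time_ms > 500) / (net$spec$N * 3.5)
  }
  r1 <- rate_at(0.05)
  r2 <- rate_at(0.025)
  expect_lt(abs(r1 - r2) / r2, 0.05)
})

test_that("background-only pool rates agree with the mean-field spontaneous state within 1.5 Hz", {
  net <- build_network()
  set.seed(29)
  res <- lif_step(net, lif_init_state(net), matrix(2400, 2000 / 0.05, 5),
                  n_steps = 2000 / 0.05)
  sp <- res$spikes
  pools <- net$pool_id[sp$neuron]
  keep <- sp$time_ms > 500
  rates <- vapply(1:5, function(p)
    sum(keep & pools == p) / (net$pool_sizes[p] * 1.5), numeric(1))
  fp <- solve_fixed_point(mf_params(), lambda = 0)
  expect_true(all(abs(rates - fp$nu) < 1.5))
})

test_that("exchange symmetry: at zero evidence L and R win equally often", {
  net <- build_network(network_spec(N = 200))
  pr <- assemble_protocol(duration = 200, lambda = 50, dlambda = 0,
                          spontaneous_duration = 200, target_duration = 300,
                          post_sure = 400, free_choice = FALSE)
  wins <- vapply(1:100, function(s) {
    sp <- simulate_trial(net, pr, seed = 1000 + s)
    r <- classify_trial(sp, pr, decision_params(theta = 24))
    r$early_choice
  }, character(1))
  k <- sum(wins == "L")
  n <- sum(wins %in% c("L", "R"))
  expect_gt(n, 50)
  expect_gt(stats::binom.test(k, n, 0.5)$p.value, 0.001)
})

test_that("spike records round-trip through the plain-text format", {
  net <- build_network(network_spec(N = 100))
  pr <- assemble_protocol(duration = 100, lambda = 50,
                          spontaneous_duration = 100, target_duration = 100,
                          post_sure = 200)
  sp <- simulate_trial(net, pr, seed = 3)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  write_spike_record(sp, f)
  back <- read_spike_record(f)
  expect_equal(back$neuron, sp$neuron)
  expect_equal(back$time_ms, sp$time_ms)
  expect_equal(attr(back, "pool_sizes"), attr(sp, "pool_sizes"))
})
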