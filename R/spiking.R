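#' NMDA voltage gate
#'
#' Magnesium-block factor of the NMDA conductance,
#' `1 / (1 + mg * exp(-0.062 V) / 3.57)`, approaching 1 at depolarised
#' potentials or zero magnesium.
#'
#' @param V membrane potential (mV)
#' @param mg magnesium concentration (mM)
#' @return gating factor in `(0, 1]`
#' @export
nmda_voltage_gate <- function(V, mg = 1) {
  1 / (1 + mg * exp(-0.062 * V) / 3.57)
}

#' Build a spiking network
#'
#' Assembles the five-population conductance-based LIF network: pool
#' membership (neurons ordered L, R, S, nonspecific, inhibitory), the
#' structured weight matrix, the per-class neuron and synapse parameters
#' (with recurrent conductances size-scaled for reduced networks, see
#' [network_spec()]) and independent aggregated external Poisson drive per
#' neuron.
#'
#' `nmda_efficacy` scales the NMDA conductances of the spiking network
#' relative to the values used by the mean-field reduction.  The
#' reduction's saturation function overestimates the event-driven average
#' NMDA activation by a few percent, and finite-size noise preferentially
#' boosts the noise-driven inhibitory population, so a network simulated
#' with the literal kinetics realises a systematically weaker attractor
#' landscape than its own reduction -- in particular the decision-memory
#' state needed to hold a choice through the delay does not persist.  The
#' default factor 1.10 is calibrated so that the simulated delay-period
#' memory rate matches the reduction's decision-memory attractor while the
#' spontaneous state stays at its reference level; set it to 1 for the
#' uncorrected kinetics.  See the methods vignette for the calibration.
#'
#' @param spec a [network_spec()]
#' @param neuron a [neuron_params()]
#' @param syn a [synapse_params()]
#' @param nmda_efficacy NMDA conductance factor reconciling the spiking
#'   network with its mean-field reduction
#' @return an object of class `lif_network`
#' @examples
#' net <- build_network(network_spec(N = 100))
#' net$spec$pools    # 16 16 16 32 20
#' @export
build_network <- function(spec = network_spec(), neuron = neuron_params(),
                          syn = synapse_params(), nmda_efficacy = 1.10) {
  stopifnot(nmda_efficacy > 0)
  ssyn <- scaled_conductances(spec, syn)
  ssyn$g_nmda_exc <- ssyn$g_nmda_exc * nmda_efficacy
  ssyn$g_nmda_inh <- ssyn$g_nmda_inh * nmda_efficacy
  cls <- list(
    Cm = c(neuron$Cm_exc, neuron$Cm_inh),
    gL = c(neuron$g_L_exc, neuron$g_L_inh),
    tau_rp = c(neuron$tau_rp_exc, neuron$tau_rp_inh),
    g_ampa_ext = c(ssyn$g_ampa_ext_exc, ssyn$g_ampa_ext_inh),
    g_ampa_rec = c(ssyn$g_ampa_rec_exc, ssyn$g_ampa_rec_inh),
    g_nmda = c(ssyn$g_nmda_exc, ssyn$g_nmda_inh),
    g_gaba = c(ssyn$g_gaba_exc, ssyn$g_gaba_inh),
    V_L = neuron$V_L, V_E = ssyn$V_E, V_I = ssyn$V_I,
    V_thr = neuron$V_thr, V_reset = neuron$V_reset,
    tau_ampa = ssyn$tau_ampa, tau_gaba = ssyn$tau_gaba,
    tau_nmda_rise = ssyn$tau_nmda_rise, tau_nmda_decay = ssyn$tau_nmda_decay,
    alpha = ssyn$alpha, mg = ssyn$mg)
  pool_id <- rep.int(seq_along(spec$pools), spec$pools)
  structure(list(spec = spec, neuron = neuron, syn = syn,
                 nmda_efficacy = nmda_efficacy, class_params = cls,
                 W = structured_weights(spec),
                 pool_sizes = as.integer(spec$pools),
                 pool_id = pool_id),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat("Conductance-based LIF network\n")
  print(x$spec)
  invisible(x)
}

#' Initial network state
#'
#' All membrane potentials at the leak reversal, all gating variables zero,
#' no refractory history.
#'
#' @param network a [build_network()] object
#' @return an object of class `lif_state`
#' @export
lif_init_state <- function(network) {
  N <- network$spec$N
  structure(list(V = rep(network$class_params$V_L, N),
                 s_ampa_ext = numeric(N), s_ampa_rec = numeric(N),
                 s_nmda = numeric(N), x_nmda = numeric(N),
                 s_gaba = numeric(N), t_last_spike = rep(-1e9, N), t = 0),
            class = "lif_state")
}

#' Advance the network state
#'
#' Integrates the membrane and gating equations by forward Euler (gating
#' decays are applied exactly) for `n_steps` steps of size `dt`, drawing
#' external Poisson input at the given per-pool total rates.  Spikes are
#' emitted when a non-refractory neuron reaches threshold; the neuron is
#' reset and held for its refractory period.
#'
#' @param network a [build_network()] object
#' @param state a [lif_init_state()] state (or the state returned by a
#'   previous call)
#' @param ext_rates numeric matrix `n_steps x 5` of total external rates
#'   (Hz per neuron, background included), or a length-5 vector recycled
#'   over steps
#' @param dt integration step (ms)
#' @param n_steps number of steps
#' @param record_spikes collect emitted spikes?
#' @return list with `state` (class `lif_state`) and `spikes` (data frame
#'   `neuron`, `time_ms`)
#' @export
lif_step <- function(network, state, ext_rates, dt = 0.05, n_steps = 1,
                     record_spikes = TRUE) {
  stopifnot(inherits(network, "lif_network"), inherits(state, "lif_state"),
            dt > 0)
  if (is.null(dim(ext_rates)))
    ext_rates <- matrix(rep(ext_rates, each = n_steps), n_steps, 5)
  stopifnot(ncol(ext_rates) == 5, nrow(ext_rates) == n_steps,
            all(ext_rates >= 0))
  res <- .cpp_lif_run(network$pool_sizes, network$W, network$class_params,
                      ext_rates, dt, state$t, unclass(state), record_spikes)
  st <- res$state
  class(st) <- "lif_state"
  list(state = st,
       spikes = data.frame(neuron = res$spike_neuron,
                           time_ms = res$spike_time))
}

#' Simulate one trial
#'
#' Runs the spiking network through a full stimulation protocol from the
#' initial state, with the external drive of each pool equal to the
#' aggregated background (`N_ext * nu_ext_source` Hz) plus the protocol's
#' extra rate.  Deterministic for a given seed.
#'
#' @param network a [build_network()] object
#' @param protocol a [assemble_protocol()] object
#' @param seed integer seed for the trial's random stream
#' @param dt integration step (ms)
#' @return an object of class `spike_record`: data frame `(neuron,
#'   time_ms)` with the network, protocol, dt and seed attached as
#'   attributes
#' @export
simulate_trial <- function(network, protocol, seed = 1, dt = 0.05) {
  stopifnot(inherits(network, "lif_network"),
            inherits(protocol, "stim_protocol"))
  n_steps <- ceiling(protocol$trial_end / dt)
  tt <- (seq_len(n_steps) - 1) * dt
  bg <- network$spec$N_ext * network$spec$nu_ext_source
  ext <- protocol_rates(protocol, tt) + bg
  set.seed(as.integer(seed))
  res <- lif_step(network, lif_init_state(network), ext, dt = dt,
                  n_steps = n_steps, record_spikes = TRUE)
  sp <- res$spikes
  attr(sp, "pool_sizes") <- network$pool_sizes
  attr(sp, "pool_id") <- network$pool_id
  attr(sp, "protocol") <- protocol
  attr(sp, "dt") <- dt
  attr(sp, "seed") <- seed
  class(sp) <- c("spike_record", "data.frame")
  sp
}

#' Pool membership of a spike record
#'
#' @param spikes a [simulate_trial()] record
#' @return integer vector: pool index (1-5) of each spike
#' @export
spike_pools <- function(spikes) {
  attr(spikes, "pool_id")[spikes$neuron]
}

#' Write / read a spike record as plain text
#'
#' Two-column whitespace table `(neuron, time_ms)` with a `# pools:` header
#' carrying the pool sizes.
#'
#' @param spikes a `spike_record`
#' @param file path
#' @return `read_spike_record` returns a `spike_record` (without protocol
#'   metadata)
#' @export
write_spike_record <- function(spikes, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# pools:",
                   paste(attr(spikes, "pool_sizes"), collapse = " ")), con)
  utils::write.table(spikes[c("neuron", "time_ms")], con,
                     row.names = FALSE, quote = FALSE)
}

#' @rdname write_spike_record
#' @export
read_spike_record <- function(file) {
  hdr <- readLines(file, n = 1)
  sizes <- as.integer(strsplit(sub("# pools: *", "", hdr), " ")[[1]])
  sp <- utils::read.table(file, header = TRUE, comment.char = "#")
  attr(sp, "pool_sizes") <- sizes
  attr(sp, "pool_id") <- rep.int(seq_along(sizes), sizes)
  class(sp) <- c("spike_record", "data.frame")
  sp
}
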