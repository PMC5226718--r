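#' Neuron parameters of the conductance-based LIF model
#'
#' Membrane and threshold parameters for the two cell classes (excitatory
#' and inhibitory).  Defaults are the reference parameter set of the model:
#' capacitances 0.5 / 0.2 nF, leak conductances 25 / 20 nS (membrane time
#' constants 20 / 10 ms), leak reversal -70 mV, threshold -50 mV, reset
#' -55 mV, refractory periods 2 / 1 ms.  The leak conductance is not an
#' independently reported value for this parameter set; the defaults are the
#' standard values of the model family this network belongs to, and the
#' mean-field spontaneous and sure-choice attractor rates serve as the
#' operational check of the choice (see the package vignette).
#'
#' @param Cm_exc,Cm_inh membrane capacitance (nF)
#' @param g_L_exc,g_L_inh leak conductance (nS)
#' @param V_L leak reversal potential (mV)
#' @param V_thr spike threshold (mV)
#' @param V_reset post-spike reset potential (mV)
#' @param tau_rp_exc,tau_rp_inh absolute refractory period (ms)
#' @return an object of class `neuron_params` (named list)
#' @export
neuron_params <- function(Cm_exc = 0.5, Cm_inh = 0.2,
                          g_L_exc = 25, g_L_inh = 20,
                          V_L = -70, V_thr = -50, V_reset = -55,
                          tau_rp_exc = 2, tau_rp_inh = 1) {
  p <- list(Cm_exc = Cm_exc, Cm_inh = Cm_inh, g_L_exc = g_L_exc,
            g_L_inh = g_L_inh, V_L = V_L, V_thr = V_thr, V_reset = V_reset,
            tau_rp_exc = tau_rp_exc, tau_rp_inh = tau_rp_inh)
  stopifnot(V_reset < V_thr, Cm_exc > 0, Cm_inh > 0, g_L_exc > 0,
            g_L_inh > 0, tau_rp_exc > 0, tau_rp_inh > 0)
  structure(p, class = "neuron_params")
}

#' Synapse parameters
#'
#' Conductances (nS, per connection), kinetic time constants (ms), reversal
#' potentials (mV), the NMDA saturation rate `alpha` (1/ms) and the
#' extracellular magnesium concentration (mM) entering the NMDA voltage
#' gate.  AMPA and GABA gating variables jump on a presynaptic spike and
#' decay exponentially; NMDA gating rises through an intermediate variable
#' with time constant `tau_nmda_rise` and saturates below one.
#'
#' @param g_ampa_ext_exc,g_ampa_ext_inh external AMPA conductance (nS)
#' @param g_ampa_rec_exc,g_ampa_rec_inh recurrent AMPA conductance (nS)
#' @param g_nmda_exc,g_nmda_inh NMDA conductance (nS)
#' @param g_gaba_exc,g_gaba_inh GABA conductance (nS)
#' @param tau_ampa,tau_gaba,tau_nmda_rise,tau_nmda_decay time constants (ms)
#' @param alpha NMDA saturation rate (1/ms)
#' @param V_E,V_I excitatory / inhibitory reversal potential (mV)
#' @param mg magnesium concentration (mM)
#' @return an object of class `synapse_params`
#' @export
synapse_params <- function(g_ampa_ext_exc = 2.08, g_ampa_ext_inh = 1.62,
                           g_ampa_rec_exc = 0.104, g_ampa_rec_inh = 0.081,
                           g_nmda_exc = 0.327, g_nmda_inh = 0.258,
                           g_gaba_exc = 1.287, g_gaba_inh = 1.002,
                           tau_ampa = 2, tau_gaba = 10,
                           tau_nmda_rise = 2, tau_nmda_decay = 100,
                           alpha = 0.5, V_E = 0, V_I = -70, mg = 1) {
  p <- list(g_ampa_ext_exc = g_ampa_ext_exc, g_ampa_ext_inh = g_ampa_ext_inh,
            g_ampa_rec_exc = g_ampa_rec_exc, g_ampa_rec_inh = g_ampa_rec_inh,
            g_nmda_exc = g_nmda_exc, g_nmda_inh = g_nmda_inh,
            g_gaba_exc = g_gaba_exc, g_gaba_inh = g_gaba_inh,
            tau_ampa = tau_ampa, tau_gaba = tau_gaba,
            tau_nmda_rise = tau_nmda_rise, tau_nmda_decay = tau_nmda_decay,
            alpha = alpha, V_E = V_E, V_I = V_I, mg = mg)
  g <- unlist(p[grep("^g_", names(p))])
  tt <- unlist(p[grep("^tau", names(p))])
  stopifnot(all(g >= 0), all(tt > 0), V_I < V_E, mg >= 0)
  structure(p, class = "synapse_params")
}

#' Network specification
#'
#' Population sizes and structured connectivity of the five-population
#' network: three selective excitatory pools (L, R and S, a fraction `f` of
#' the excitatory neurons each), one nonspecific excitatory pool and one
#' inhibitory pool.  Connectivity is all-to-all without autapses or
#' synaptic delays.  Within-pool excitatory connections of a selective pool
#' are potentiated (`w_plus`); excitatory connections from any other
#' excitatory pool onto a selective pool are depressed (`w_minus`); all
#' remaining weights are 1.
#'
#' Reduced-size networks (`N < reference_N`) are supported for fast tests:
#' with `scale_recurrent = TRUE` (default) the recurrent conductances are
#' multiplied by `reference_N / N` when a network is built, so the mean
#' recurrent drive per neuron -- and hence the mean-field operating point --
#' is preserved while finite-size fluctuations grow.
#'
#' @param N total number of neurons; excitatory count is `0.8 * N`
#' @param f fraction of excitatory neurons per selective pool
#' @param w_plus,w_minus potentiated / depressed relative synaptic weight
#' @param N_ext number of external Poisson sources per neuron
#' @param nu_ext_source background rate per external source (Hz)
#' @param reference_N network size at which the synapse conductances are
#'   calibrated
#' @param scale_recurrent scale recurrent conductances by `reference_N / N`
#' @return an object of class `network_spec`
#' @examples
#' spec <- network_spec()              # N = 1000: pools 160/160/160/320/200
#' small <- network_spec(N = 100)     # test preset: pools 16/16/16/32/20
#' @export
network_spec <- function(N = 1000, f = 0.2, w_plus = 1.5, w_minus = 0.878,
                         N_ext = 800, nu_ext_source = 3,
                         reference_N = 1000, scale_recurrent = TRUE) {
  if (f <= 0 || f > 1 / 3)
    stop("selective-pool fraction f must be in (0, 1/3]")
  N_E <- 0.8 * N
  N_I <- 0.2 * N
  n_sel <- f * N_E
  if (any(c(N_E, N_I, n_sel) != round(c(N_E, N_I, n_sel))))
    stop("N and f must give integer pool sizes (0.8*N, 0.2*N, f*0.8*N)")
  pools <- c(L = n_sel, R = n_sel, S = n_sel,
             nonspecific = N_E - 3 * n_sel, inhibitory = N_I)
  if (any(pools <= 0)) stop("inconsistent pool sizes: ", toString(pools))
  structure(list(N = N, N_E = N_E, N_I = N_I, f = f, pools = pools,
                 w_plus = w_plus, w_minus = w_minus, N_ext = N_ext,
                 nu_ext_source = nu_ext_source, reference_N = reference_N,
                 scale_recurrent = scale_recurrent),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Five-population attractor network, N =", x$N, "\n")
  cat("  pools:", paste(names(x$pools), x$pools, sep = "=", collapse = ", "), "\n")
  cat("  w+ =", x$w_plus, " w- =", x$w_minus,
      " external:", x$N_ext, "sources x", x$nu_ext_source, "Hz\n")
  invisible(x)
}

# Recurrent conductances after size scaling (nS). Internal.
scaled_conductances <- function(spec, syn) {
  s_e <- if (spec$scale_recurrent) (0.8 * spec$reference_N) / spec$N_E else 1
  s_i <- if (spec$scale_recurrent) (0.2 * spec$reference_N) / spec$N_I else 1
  syn$g_ampa_rec_exc <- syn$g_ampa_rec_exc * s_e
  syn$g_ampa_rec_inh <- syn$g_ampa_rec_inh * s_e
  syn$g_nmda_exc <- syn$g_nmda_exc * s_e
  syn$g_nmda_inh <- syn$g_nmda_inh * s_e
  syn$g_gaba_exc <- syn$g_gaba_exc * s_i
  syn$g_gaba_inh <- syn$g_gaba_inh * s_i
  syn
}

#' Structured weight matrix between pools
#'
#' Returns the 5 x 5 matrix of relative synaptic weights, rows indexing the
#' source pool and columns the target pool (order L, R, S, nonspecific,
#' inhibitory).  Inhibitory-source weights are 1 onto every target.
#'
#' @param spec a [network_spec()]
#' @return numeric matrix with dimnames
#' @export
structured_weights <- function(spec) {
  nm <- c("L", "R", "S", "nonspecific", "inhibitory")
  W <- matrix(1, 5, 5, dimnames = list(source = nm, target = nm))
  for (x in 1:3) {
    W[1:4, x] <- spec$w_minus
    W[x, x] <- spec$w_plus
  }
  W
}

#' Flat mean-field parameter list
#'
#' Collects neuron, synapse and network parameters into the single list the
#' mean-field routines consume.  Times are converted to seconds; rates stay
#' in Hz, potentials in mV, conductances in nS.  Size scaling of a reduced
#' network is folded into the conductances so that the mean-field reduction
#' of a scaled network coincides with that of the reference network.
#'
#' @param spec a [network_spec()]
#' @param neuron a [neuron_params()]
#' @param syn a [synapse_params()]
#' @return a plain named list of class `mf_params`
#' @export
mf_params <- function(spec = network_spec(), neuron = neuron_params(),
                      syn = synapse_params()) {
  syn <- scaled_conductances(spec, syn)
  p <- list(
    gm_exc = neuron$g_L_exc, gm_inh = neuron$g_L_inh,
    Cm_exc = neuron$Cm_exc, Cm_inh = neuron$Cm_inh,
    V_L = neuron$V_L, V_thr = neuron$V_thr, V_reset = neuron$V_reset,
    V_E = syn$V_E, V_I = syn$V_I,
    tau_rp_exc = neuron$tau_rp_exc * 1e-3,
    tau_rp_inh = neuron$tau_rp_inh * 1e-3,
    g_ampa_ext_exc = syn$g_ampa_ext_exc, g_ampa_ext_inh = syn$g_ampa_ext_inh,
    g_ampa_rec_exc = syn$g_ampa_rec_exc, g_ampa_rec_inh = syn$g_ampa_rec_inh,
    g_nmda_exc = syn$g_nmda_exc, g_nmda_inh = syn$g_nmda_inh,
    g_gaba_exc = syn$g_gaba_exc, g_gaba_inh = syn$g_gaba_inh,
    tau_ampa = syn$tau_ampa * 1e-3, tau_gaba = syn$tau_gaba * 1e-3,
    tau_nmda_rise = syn$tau_nmda_rise * 1e-3,
    tau_nmda_decay = syn$tau_nmda_decay * 1e-3,
    alpha = syn$alpha * 1e3, mg = syn$mg,
    N_E = spec$N_E, N_I = spec$N_I,
    N_ext = spec$N_ext, nu_ext_source = spec$nu_ext_source,
    f = spec$f, w_plus = spec$w_plus, w_minus = spec$w_minus)
  structure(p, class = "mf_params")
}
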