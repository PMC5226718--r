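#' Motion-stimulus input rates
#'
#' Evidence-dependent extra external rate delivered during the motion
#' period: pool L receives `lambda + dlambda`, pool R receives
#' `lambda - dlambda` and pool S receives nothing.  `dlambda > 0` therefore
#' makes L the correct choice.
#'
#' @param pool `"L"`, `"R"` or `"S"`
#' @param lambda mean stimulus rate common to both decision pools (Hz)
#' @param dlambda evidence-dependent rate difference (Hz)
#' @return added external rate (Hz)
#' @export
motion_input <- function(pool, lambda, dlambda) {
  if (lambda - dlambda < 0)
    stop("lambda - dlambda = ", lambda - dlambda,
         " Hz: pool R cannot receive a negative rate")
  if (lambda < 0 || dlambda < 0) stop("lambda and dlambda must be >= 0")
  vapply(pool, function(p)
    switch(p, L = lambda + dlambda, R = lambda - dlambda, S = 0,
           stop("pool must be one of L, R, S")), numeric(1))
}

#' Target-onset input transient
#'
#' Visual targets elicit a strong transient response that adapts: the input
#' rate is the sum of two exponential decays on top of an asymptote,
#' nonincreasing in time.  Direction targets decay to zero; the sure target
#' uses a sustained asymptote of 5 Hz.
#'
#' @param t_since_onset time since target onset (ms), `>= 0`
#' @param asymptote sustained rate as `t -> Inf` (Hz)
#' @param A_fast,tau_fast fast component amplitude (Hz) and time constant (ms)
#' @param A_slow,tau_slow slow component amplitude (Hz) and time constant (ms)
#' @return input rate (Hz)
#' @export
target_transient <- function(t_since_onset, asymptote = 0,
                             A_fast = 200, tau_fast = 80,
                             A_slow = 100, tau_slow = 450) {
  stopifnot(all(t_since_onset >= 0))
  asymptote + A_fast * exp(-t_since_onset / tau_fast) +
    A_slow * exp(-t_since_onset / tau_slow)
}

#' Assemble the stimulation protocol of one trial
#'
#' Builds the piecewise time course of the per-pool external input for the
#' delayed three-option task.  The timeline is: a spontaneous period
#' (background only), a target transient to pools L and R, the motion
#' stimulus (`lambda + dlambda` to L, `lambda - dlambda` to R), a delay
#' with background only, and -- on free-choice trials -- a sure-target
#' transient to pool S starting 500 ms after motion offset and sustained
#' (asymptote 5 Hz) to the end of the trial.  A saccade-related signal of
#' 80 Hz is delivered to L, R and S during the final 100 ms; its onset is
#' the go cue.  On forced-choice trials pool S receives only the background
#' throughout.  Phases are half-open intervals `[onset, offset)`.
#'
#' @param duration motion-stimulus duration (ms); the reference conditions
#'   use 100, 200, 300 or 500 ms
#' @param lambda,dlambda motion input rates (Hz); see [motion_input()]
#' @param free_choice logical: present the sure target?
#' @param spontaneous_duration,target_duration first two phases (ms)
#' @param delay_to_sure gap between motion offset and sure-target onset (ms)
#' @param post_sure time from sure-target onset to trial end (ms)
#' @param sure_asymptote sustained sure-target input (Hz)
#' @param sure_peak_scale factor on the sure-target transient amplitudes
#'   relative to the direction-target transient (the sustained asymptote is
#'   not scaled); the value of the opt-out stake is reflected in this input
#' @param saccade_rate,saccade_duration end-of-trial signal (Hz, ms)
#' @param target_peak_fast,target_tau_fast,target_peak_slow,target_tau_slow
#'   transient shape, see [target_transient()]
#' @return an object of class `stim_protocol`
#' @examples
#' pr <- assemble_protocol(duration = 500, lambda = 50, dlambda = 7)
#' pr$sure_onset   # 2000 ms: 1000 ms after motion onset
#' @export
assemble_protocol <- function(duration = 500, lambda = 50, dlambda = 0,
                              free_choice = TRUE,
                              spontaneous_duration = 500,
                              target_duration = 500,
                              delay_to_sure = 500, post_sure = 1000,
                              sure_asymptote = 5, sure_peak_scale = 1,
                              saccade_rate = 80, saccade_duration = 100,
                              target_peak_fast = 200, target_tau_fast = 80,
                              target_peak_slow = 100, target_tau_slow = 450) {
  motion_input("L", lambda, dlambda)  # validates rates
  stopifnot(duration > 0, spontaneous_duration >= 0, target_duration > 0,
            delay_to_sure >= 0, post_sure > saccade_duration)
  target_onset <- spontaneous_duration
  motion_onset <- target_onset + target_duration
  motion_offset <- motion_onset + duration
  sure_onset <- motion_offset + delay_to_sure
  trial_end <- sure_onset + post_sure
  go_cue <- trial_end - saccade_duration
  structure(list(
    duration = duration, lambda = lambda, dlambda = dlambda,
    free_choice = free_choice,
    target_onset = target_onset, target_duration = target_duration,
    motion_onset = motion_onset, motion_offset = motion_offset,
    sure_onset = sure_onset, trial_end = trial_end, go_cue = go_cue,
    saccade_rate = saccade_rate, saccade_duration = saccade_duration,
    sure_asymptote = sure_asymptote, sure_peak_scale = sure_peak_scale,
    target_peak_fast = target_peak_fast, target_tau_fast = target_tau_fast,
    target_peak_slow = target_peak_slow, target_tau_slow = target_tau_slow),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(paste0("Stimulation protocol (%s choice): lambda = %g, ",
                     "dlambda = %g, duration = %g ms\n"),
              if (x$free_choice) "free" else "forced", x$lambda, x$dlambda,
              x$duration))
  cat(sprintf("  targets %g | motion %g-%g | sure %s | go cue %g | end %g ms\n",
              x$target_onset, x$motion_onset, x$motion_offset,
              if (x$free_choice) sprintf("%g", x$sure_onset) else "-",
              x$go_cue, x$trial_end))
  invisible(x)
}

#' Per-pool extra input rates of a protocol
#'
#' Evaluates the protocol's extra external rate (Hz, on top of the
#' background) for the five pools at the requested times.
#'
#' @param protocol a [assemble_protocol()] object
#' @param times_ms vector of times from trial start (ms)
#' @return matrix `length(times_ms) x 5` (columns L, R, S, nonspecific,
#'   inhibitory)
#' @export
protocol_rates <- function(protocol, times_ms) {
  p <- protocol
  n <- length(times_ms)
  out <- matrix(0, n, 5,
                dimnames = list(NULL, POOLS))
  tgt <- times_ms >= p$target_onset &
    times_ms < p$target_onset + p$target_duration
  tr <- target_transient(pmax(times_ms - p$target_onset, 0), 0,
                         p$target_peak_fast, p$target_tau_fast,
                         p$target_peak_slow, p$target_tau_slow)
  out[tgt, "L"] <- tr[tgt]
  out[tgt, "R"] <- tr[tgt]
  mot <- times_ms >= p$motion_onset & times_ms < p$motion_offset
  out[mot, "L"] <- out[mot, "L"] + p$lambda + p$dlambda
  out[mot, "R"] <- out[mot, "R"] + p$lambda - p$dlambda
  if (p$free_choice) {
    sur <- times_ms >= p$sure_onset & times_ms < p$trial_end
    st <- target_transient(pmax(times_ms - p$sure_onset, 0),
                           p$sure_asymptote,
                           p$sure_peak_scale * p$target_peak_fast,
                           p$target_tau_fast,
                           p$sure_peak_scale * p$target_peak_slow,
                           p$target_tau_slow)
    out[sur, "S"] <- st[sur]
  }
  sac <- times_ms >= p$go_cue & times_ms < p$trial_end
  out[sac, c("L", "R", "S")] <- out[sac, c("L", "R", "S")] + p$saccade_rate
  out
}

#' Tabulate a protocol for inspection or export
#'
#' @param protocol a [assemble_protocol()] object
#' @param step sampling step (ms)
#' @return data frame `(time_ms, rate_L, rate_R, rate_S, rate_nonspecific,
#'   rate_inhibitory)` of extra input rates (Hz above background)
#' @export
protocol_table <- function(protocol, step = 5) {
  tt <- seq(0, protocol$trial_end - step, by = step)
  r <- protocol_rates(protocol, tt)
  data.frame(time_ms = tt, rate_L = r[, 1], rate_R = r[, 2], rate_S = r[, 3],
             rate_nonspecific = r[, 4], rate_inhibitory = r[, 5])
}
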