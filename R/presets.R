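#' Named simulation presets
#'
#' Ready-made configurations at several scales:
#' \describe{
#'   \item{smoke}{N = 200 network, a 2-condition grid, 5 trials: exercises
#'     every code path in seconds.}
#'   \item{bistable}{N = 1000, lambda = 15 Hz, threshold 24 Hz: the regime
#'     with only the two decision attractors (unimodal decision times).}
#'   \item{multistable}{N = 1000, lambda = 50 Hz, threshold 28 Hz: the
#'     reference operating point where the mixed non-decision attractor
#'     coexists with the decision attractors.}
#'   \item{psychometrics}{full-scale grid (four durations, four evidence
#'     levels, free and forced) at the multistable operating point; with
#'     `n_trials = 1000` this is the reference-scale behavioural
#'     experiment.}
#' }
#' Each preset is a list with `network_args`, `conditions`, `theta` and
#' `n_trials`.
#'
#' @param name preset name; omit to list available presets
#' @return a preset list, or the preset names
#' @examples
#' fixture_presets()
#' p <- fixture_presets("smoke")
#' @export
fixture_presets <- function(name = NULL) {
  grid <- function(lambda, dlambdas, durations, free = c(TRUE, FALSE))
    expand.grid(lambda = lambda, dlambda = dlambdas, duration = durations,
                free_choice = free)
  presets <- list(
    smoke = list(
      network_args = list(N = 200),
      conditions = grid(50, c(0, 14), 300, free = c(TRUE, FALSE)),
      theta = 28, n_trials = 5),
    bistable = list(
      network_args = list(N = 1000),
      conditions = grid(15, c(0, 3, 7, 14), c(100, 200, 300, 500)),
      theta = 24, n_trials = 200),
    multistable = list(
      network_args = list(N = 1000),
      conditions = grid(50, c(0, 7, 14, 28), c(100, 200, 300, 500)),
      theta = 28, n_trials = 200),
    psychometrics = list(
      network_args = list(N = 1000),
      conditions = grid(50, c(0, 7, 14, 28), c(100, 200, 300, 500)),
      theta = 28, n_trials = 1000))
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  presets[[name]]
}

#' Run a preset end to end
#'
#' Builds the preset's network and runs its condition grid.
#'
#' @param preset a name accepted by [fixture_presets()]
#' @param n_trials override the preset's trial count
#' @param base_seed first seed
#' @param ... passed to [run_ensemble()]
#' @return a `trial_set`
#' @export
run_preset <- function(preset, n_trials = NULL, base_seed = 1, ...) {
  p <- fixture_presets(preset)
  net <- build_network(do.call(network_spec, p$network_args))
  run_ensemble(net, p$conditions, n_trials %||% p$n_trials, base_seed,
               params = decision_params(theta = p$theta), ...)
}
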