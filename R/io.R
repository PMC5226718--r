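#' Write or read a trial table
#'
#' Plain CSV with all trial-level fields; the reader restores the
#' `trial_set` class.
#'
#' @param trials a [run_ensemble()] table
#' @param file path
#' @export
write_trials <- function(trials, file) {
  utils::write.csv(trials, file, row.names = FALSE)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(out) <- c("trial_set", "data.frame")
  out
}

profile_sections <- c("network", "neuron", "synapse", "decision")

#' Read or write a configuration profile
#'
#' A profile is a YAML file with sections `network`, `neuron`, `synapse`
#' and `decision`, whose keys are the arguments of [network_spec()],
#' [neuron_params()], [synapse_params()] and [decision_params()].  Unknown
#' sections or keys are rejected.  Missing keys take the reference
#' defaults, so an empty profile reproduces the reference parameter set.
#'
#' @param file path to a YAML profile
#' @return list with components `network`, `neuron`, `synapse`, `decision`
#'   (constructed parameter objects)
#' @export
read_profile <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y)) y <- list()
  extra <- setdiff(names(y), profile_sections)
  if (length(extra)) stop("unknown profile section(s): ", toString(extra))
  build <- function(section, ctor) {
    args <- y[[section]] %||% list()
    # YAML 1.1 parses a bare `N` key as boolean; map it back
    names(args)[names(args) == "FALSE"] <- "N"
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop("unknown key(s) in profile section '", section, "': ",
           toString(bad))
    do.call(ctor, args)
  }
  list(network = build("network", network_spec),
       neuron = build("neuron", neuron_params),
       synapse = build("synapse", synapse_params),
       decision = build("decision", decision_params))
}

#' @rdname read_profile
#' @param profile a list as returned by [read_profile()]
#' @export
write_profile <- function(profile, file) {
  yaml::write_yaml(lapply(profile, unclass), file)
}
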