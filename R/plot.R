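#' Plot selective-pool rate traces of a trial
#'
#' @param spikes a [simulate_trial()] record
#' @param window,step rate-estimation window and step (ms)
#' @param ... passed to [graphics::plot()]
#' @return the traces, invisibly
#' @export
plot_rate_traces <- function(spikes, window = 50, step = 5, ...) {
  tr <- rate_traces(spikes, window, step)
  pr <- attr(spikes, "protocol")
  graphics::plot(tr$time_ms, tr$L, type = "l", col = "blue",
                 xlab = "time (ms)", ylab = "population rate (Hz)",
                 ylim = range(0, tr$L, tr$R, tr$S), ...)
  graphics::lines(tr$time_ms, tr$R, col = "darkorange")
  graphics::lines(tr$time_ms, tr$S, col = "darkgreen")
  if (!is.null(pr))
    graphics::abline(v = c(pr$motion_onset, pr$motion_offset,
                           pr$sure_onset, pr$go_cue), lty = 3,
                     col = "grey50")
  graphics::legend("topleft", c("L", "R", "S"), lty = 1, bty = "n",
                   col = c("blue", "darkorange", "darkgreen"))
  invisible(tr)
}

#' Plot a bifurcation diagram
#'
#' Rates of pools L and R of every attractor as a function of the common
#' stimulus rate.
#'
#' @param scan a [bifurcation_scan()] result
#' @param ... passed to [graphics::plot()]
#' @export
plot_bifurcation <- function(scan, ...) {
  graphics::plot(scan$lambda, scan$nu_L, pch = 16, cex = 0.5,
                 xlab = expression(lambda ~ "(Hz)"),
                 ylab = expression(nu[L] * "," ~ nu[R] ~ "(Hz)"), ...)
  graphics::points(scan$lambda, scan$nu_R, pch = 1, cex = 0.5)
  for (tr in attr(scan, "transitions"))
    graphics::abline(v = tr - 0.5, lty = 3, col = "grey50")
  invisible(scan)
}

#' Plot a conditional sure-choice map
#'
#' @param map a [conditional_sure_map()] result
#' @param ... passed to [graphics::image()]
#' @export
plot_sure_map <- function(map, ...) {
  xl <- sort(unique(map$nu_L)); yl <- sort(unique(map$nu_R))
  z <- matrix(NA_real_, length(xl), length(yl))
  z[cbind(match(map$nu_L, xl), match(map$nu_R, yl))] <- map$p_sure
  graphics::image(xl, yl, z, xlab = expression(nu[L] ~ "(Hz)"),
                  ylab = expression(nu[R] ~ "(Hz)"), ...)
  invisible(map)
}
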