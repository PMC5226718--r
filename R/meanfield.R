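#' @useDynLib wagernet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

POOLS <- c("L", "R", "S", "nonspecific", "inhibitory")

#' Effective NMDA activation
#'
#' Average fraction of open NMDA channels of a presynaptic neuron firing as
#' a Poisson process at rate `nu`, accounting for saturation of the gating
#' variable.  Evaluated as an alternating series over spike-interaction
#' orders, truncated at `nmax` terms with early stopping once a term falls
#' below 1e-12.  Strictly increasing in `nu`, zero at zero rate and
#' saturating below one.
#'
#' @param nu firing rate(s), Hz
#' @param params an [mf_params()] list
#' @param nmax maximum series order
#' @return numeric vector of activations in `[0, 1)`
#' @export
psi_nmda <- function(nu, params = mf_params(), nmax = 64) {
  stopifnot(all(nu >= 0))
  .cpp_psi(as.numeric(nu), params, as.integer(nmax))
}

#' Population transfer function
#'
#' Stationary firing rate of a population of LIF neurons receiving Gaussian
#' current fluctuations: the inverse of the refractory period plus the mean
#' first-passage time from reset to threshold, with integration bounds
#' corrected for the finite synaptic (AMPA) time constant.  Evaluated by
#' 96-point Gauss-Legendre quadrature of the scaled-erfc integrand.
#'
#' @param mu mean membrane potential (mV)
#' @param sigma fluctuation magnitude (mV), must be positive
#' @param tau_x effective membrane time constant (s)
#' @param tau_rp refractory period (s)
#' @param params an [mf_params()] list (supplies `tau_ampa`, threshold and
#'   reset)
#' @return firing rate (Hz); never exceeds `1 / tau_rp`
#' @export
mf_transfer <- function(mu, sigma, tau_x, tau_rp, params = mf_params()) {
  stopifnot(all(sigma > 0), all(tau_x > 0), all(tau_rp > 0))
  n <- max(length(mu), length(sigma), length(tau_x), length(tau_rp))
  .cpp_phi(rep_len(as.numeric(mu), n), rep_len(as.numeric(sigma), n),
           rep_len(as.numeric(tau_x), n), rep_len(as.numeric(tau_rp), n),
           params$tau_ampa, params$V_thr, params$V_reset)
}

#' Recurrent synaptic drives
#'
#' Population-fraction- and weight-summed presynaptic activity entering
#' each of the five populations: AMPA and GABA drives are weighted rate
#' sums, the NMDA drive weights the saturating activation [psi_nmda()].
#'
#' @param nu rate vector, Hz, ordered L, R, S, nonspecific, inhibitory
#' @param params an [mf_params()] list
#' @return list with components `ampa`, `nmda`, `gaba`, each length 5
#' @export
mf_drives <- function(nu, params = mf_params()) {
  stopifnot(length(nu) == 5, all(nu >= 0))
  f <- .cpp_mf_fields(as.numeric(nu), ext_rates_mf(params), params)
  list(ampa = stats::setNames(f$n_ampa, POOLS),
       nmda = stats::setNames(f$n_nmda, POOLS),
       gaba = stats::setNames(f$n_gaba, POOLS))
}

# Total external rate (Hz) per population for a stationary input condition.
ext_rates_mf <- function(params, lambda = 0, dlambda = 0, lambda_S = 0) {
  if (lambda - dlambda < 0)
    stop("lambda - dlambda is negative: pool R would receive a negative rate")
  base <- params$N_ext * params$nu_ext_source
  c(base + lambda + dlambda, base + lambda - dlambda, base + lambda_S,
    base, base)
}

#' Self-consistent input statistics
#'
#' Mean `mu` and fluctuation `sigma` of the effective membrane potential,
#' effective time constant, total conductance factor and mean potential of
#' each population, iterated to self-consistency at fixed rates (the mean
#' potential feeds back on the linearised NMDA conductance and on `mu`
#' itself).  In the leak-only limit (no input at all) `mu` equals the leak
#' reversal and the conductance factor is 1.
#'
#' @param nu rate vector, Hz, ordered L, R, S, nonspecific, inhibitory
#' @param params an [mf_params()] list
#' @param lambda,dlambda,lambda_S stationary stimulus rates (Hz): pools L
#'   and R receive `lambda + dlambda` and `lambda - dlambda`, pool S
#'   receives `lambda_S`, all on top of the background
#' @return list with `mu`, `sigma` (mV), `tau` (s), `S_x`, `V_mean` (mV)
#' @export
mu_sigma <- function(nu, params = mf_params(), lambda = 0, dlambda = 0,
                     lambda_S = 0) {
  stopifnot(length(nu) == 5, all(nu >= 0))
  f <- .cpp_mf_fields(as.numeric(nu),
                      ext_rates_mf(params, lambda, dlambda, lambda_S), params)
  lapply(f[c("mu", "sigma", "tau", "S_x", "V_mean")],
         function(v) stats::setNames(v, POOLS))
}

#' Classify a converged mean-field state
#'
#' Labels a rate vector as `spontaneous` (all selective pools below
#' `low`), `decision_L` / `decision_R` / `decision_S` (one selective pool
#' above `high`, the others below `low`), `mixed` (L and R both at
#' intermediate rate, within `mixed_gap` of each other) or `other`.
#'
#' @param nu rate vector (length >= 3, order L, R, S, ...)
#' @param low,high,mixed_range,mixed_gap classification thresholds (Hz)
#' @return character label
#' @export
classify_attractor <- function(nu, low = 10, high = 20,
                               mixed_range = c(10, 40), mixed_gap = 2) {
  L <- nu[1]; R <- nu[2]; S <- nu[3]
  sel <- c(L, R, S)
  if (all(sel < low)) return("spontaneous")
  for (i in 1:3) if (sel[i] > high && all(sel[-i] < low))
    return(c("decision_L", "decision_R", "decision_S")[i])
  if (L >= mixed_range[1] && L <= mixed_range[2] &&
      R >= mixed_range[1] && R <= mixed_range[2] &&
      abs(L - R) < mixed_gap && S < low) return("mixed")
  "other"
}

#' Solve the mean-field self-consistency equations
#'
#' Integrates the rate relaxation dynamics `tau_x dnu/dt = -nu + phi(mu,
#' sigma)` for the five populations by forward Euler (default step 0.1 ms)
#' until the largest per-step rate change falls below `tol`, starting from
#' `init`.  At every step the input statistics are recomputed
#' self-consistently from the current rates.  Fixed points of this flow are
#' solutions of the self-consistency equations; convergence under the flow
#' is the operational notion of stability used throughout.
#'
#' @param params an [mf_params()] list
#' @param lambda,dlambda,lambda_S stationary stimulus rates (Hz)
#' @param init initial rate vector (Hz, length 5); defaults to a
#'   near-spontaneous state
#' @param dt Euler step (s)
#' @param tol convergence threshold on the per-step rate change (Hz)
#' @param max_steps step budget; non-convergence within it is flagged (the
#'   flow may be on a limit cycle or a slow manifold), never silently
#'   returned as a fixed point
#' @return an object of class `mf_fixed_point`: rates `nu`, `classification`,
#'   `converged`, self-consistency `residual`, and the input statistics
#' @examples
#' p <- mf_params()
#' fp <- solve_fixed_point(p, lambda = 0)   # spontaneous state, ~2.5 Hz
#' @export
solve_fixed_point <- function(params = mf_params(), lambda = 0, dlambda = 0,
                              lambda_S = 0, init = c(3, 3, 3, 3, 9),
                              dt = 1e-4, tol = 1e-6, max_steps = 1e6) {
  stopifnot(length(init) == 5, all(init >= 0), dt > 0)
  ext <- ext_rates_mf(params, lambda, dlambda, lambda_S)
  sol <- .cpp_mf_solve(as.numeric(init), ext, params, dt, tol, max_steps)
  if (!sol$converged)
    warning("mean-field flow did not converge within ", max_steps,
            " steps (possible limit cycle); state returned with converged = FALSE")
  structure(list(
    nu = stats::setNames(sol$nu, POOLS),
    classification = classify_attractor(sol$nu),
    converged = sol$converged, steps = sol$steps, residual = sol$residual,
    mu = stats::setNames(sol$mu, POOLS),
    sigma = stats::setNames(sol$sigma, POOLS),
    tau = stats::setNames(sol$tau, POOLS),
    S_x = stats::setNames(sol$S_x, POOLS),
    V_mean = stats::setNames(sol$V_mean, POOLS),
    lambda = lambda, dlambda = dlambda, lambda_S = lambda_S,
    init = init), class = "mf_fixed_point")
}

#' @export
print.mf_fixed_point <- function(x, ...) {
  cat(sprintf("Mean-field fixed point (%s)%s\n", x$classification,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$nu, 3))
  cat(sprintf("  residual %.2e Hz after %d steps\n", x$residual, x$steps))
  invisible(x)
}

# Default seeds (nu_L, nu_R) for attractor enumeration.
default_init_grid <- function() {
  rbind(c(1, 1), c(3, 3), c(15, 15), c(25, 25), c(35, 35),
        c(30, 1), c(1, 30), c(45, 3), c(3, 45), c(20, 5), c(5, 20))
}

# External rates for a named trial epoch.  "stimulus": lambda on L/R;
# "delay": background only; "sure": sure-target input (its asymptotic rate)
# on S only.
condition_rates <- function(condition, lambda, dlambda, sure_rate = 5) {
  switch(condition,
         stimulus = c(lambda = lambda, dlambda = dlambda, lambda_S = 0),
         delay = c(lambda = 0, dlambda = 0, lambda_S = 0),
         sure = c(lambda = 0, dlambda = 0, lambda_S = sure_rate),
         stop("unknown condition: ", condition))
}

#' Enumerate attractors of the mean-field dynamics
#'
#' Relaxes the mean-field flow from a grid of initial conditions in the
#' (nu_L, nu_R) plane (plus S-dominant seeds under the sure-target
#' condition), deduplicates converged states (two states are the same
#' attractor when all five rates agree within `dedup_tol`) and classifies
#' them.  Symmetric (nu_L = nu_R) states found from symmetric seeds are
#' additionally probed with an antisymmetric rate perturbation of size
#' `probe`: under an exactly symmetric flow, roundoff alone may fail to
#' reveal that the diagonal state is unstable to L-R symmetry breaking, so
#' states that do not return from the probe are marked unstable and
#' dropped (kept with `stable = FALSE` when `keep_unstable = TRUE`).
#'
#' @param params an [mf_params()] list
#' @param lambda,dlambda stimulus rates (Hz)
#' @param condition `"stimulus"`, `"delay"` or `"sure"`
#' @param init_grid optional matrix of (nu_L, nu_R) seeds
#' @param dedup_tol rate tolerance identifying two converged states (Hz)
#' @param probe antisymmetric perturbation used for the stability check (Hz)
#' @param sure_rate asymptotic sure-target input rate (Hz)
#' @param keep_unstable keep probe-unstable states in the table
#' @param ... passed to [solve_fixed_point()]
#' @return an object of class `attractor_landscape`: a data frame with one
#'   row per attractor (rates, classification, stability) plus metadata
#' @export
enumerate_attractors <- function(params = mf_params(), lambda = 0,
                                 dlambda = 0,
                                 condition = c("stimulus", "delay", "sure"),
                                 init_grid = NULL, dedup_tol = 0.1,
                                 probe = 0.1, sure_rate = 5,
                                 keep_unstable = FALSE, ...) {
  condition <- match.arg(condition)
  cr <- condition_rates(condition, lambda, dlambda, sure_rate)
  if (is.null(init_grid)) init_grid <- default_init_grid()
  seeds <- lapply(seq_len(nrow(init_grid)), function(i)
    c(init_grid[i, 1], init_grid[i, 2], 2, 3, 9))
  if (condition == "sure")
    seeds <- c(seeds, list(c(2, 2, 30, 3, 9), c(1, 1, 40, 3, 9)))
  found <- list()
  for (s in seeds) {
    fp <- solve_fixed_point(params, cr["lambda"], cr["dlambda"],
                            cr["lambda_S"], init = s, ...)
    if (!fp$converged) next
    dup <- any(vapply(found, function(g) max(abs(g$nu - fp$nu)) < dedup_tol,
                      logical(1)))
    if (!dup) found[[length(found) + 1]] <- fp
  }
  stable <- vapply(found, function(fp) {
    if (abs(fp$nu[1] - fp$nu[2]) > dedup_tol) return(TRUE)
    pert <- fp$nu + c(probe, -min(probe, fp$nu[2]), 0, 0, 0)
    fp2 <- solve_fixed_point(params, cr["lambda"], cr["dlambda"],
                             cr["lambda_S"], init = pmax(pert, 0), ...)
    fp2$converged && max(abs(fp2$nu - fp$nu)) < 5 * dedup_tol
  }, logical(1))
  if (!keep_unstable) found <- found[stable]
  if (!keep_unstable) stable <- stable[stable]
  tab <- do.call(rbind, lapply(found, function(fp)
    data.frame(class = fp$classification, nu_L = fp$nu[1], nu_R = fp$nu[2],
               nu_S = fp$nu[3], nu_ns = fp$nu[4], nu_I = fp$nu[5],
               residual = fp$residual, row.names = NULL)))
  if (is.null(tab))
    tab <- data.frame(class = character(), nu_L = numeric(),
                      nu_R = numeric(), nu_S = numeric(), nu_ns = numeric(),
                      nu_I = numeric(), residual = numeric())
  tab$stable <- stable
  structure(list(attractors = tab, condition = condition, lambda = lambda,
                 dlambda = dlambda, sure_rate = sure_rate, params = params,
                 fixed_points = found),
            class = "attractor_landscape")
}

#' @export
print.attractor_landscape <- function(x, ...) {
  cat(sprintf("Attractor landscape: %s condition, lambda = %g, dlambda = %g\n",
              x$condition, x$lambda, x$dlambda))
  print(x$attractors, digits = 4)
  invisible(x)
}

#' Bifurcation scan over the common stimulus rate
#'
#' Runs [enumerate_attractors()] for each value of `lambda_grid` (with
#' `dlambda = 0` by default) and returns a tidy table of all attractors
#' found, one row per (lambda, attractor).  Bifurcation points are reported
#' as the grid values where the set of attractor classes changes.
#'
#' @param params an [mf_params()] list
#' @param lambda_grid vector of stimulus rates (Hz); step of 1 Hz or finer
#'   recommended
#' @param dlambda evidence rate difference (Hz)
#' @param condition trial epoch, see [enumerate_attractors()]
#' @param verbose print progress
#' @param ... passed to [enumerate_attractors()]
#' @return a data frame of class `bifurcation_scan` with attributes
#'   `transitions` (lambda values where the attractor-set composition
#'   changes) and `classes_by_lambda`
#' @export
bifurcation_scan <- function(params = mf_params(), lambda_grid = 0:70,
                             dlambda = 0, condition = "stimulus",
                             verbose = FALSE, ...) {
  rows <- list()
  comp <- character(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    ls <- enumerate_attractors(params, lambda = lam, dlambda = dlambda,
                               condition = condition, ...)
    a <- ls$attractors
    comp[i] <- paste(sort(unique(a$class)), collapse = "+")
    if (nrow(a) > 0) rows[[length(rows) + 1]] <- cbind(lambda = lam, a)
    if (verbose) message("lambda = ", lam, ": ", comp[i])
  }
  out <- do.call(rbind, rows)
  trans <- lambda_grid[which(comp[-1] != comp[-length(comp)]) + 1]
  structure(out, transitions = trans,
            classes_by_lambda = stats::setNames(comp, lambda_grid),
            class = c("bifurcation_scan", "data.frame"))
}

#' Basin boundary by bisection
#'
#' Finds the boundary of an attractor's basin in the (nu_L, nu_R) plane.
#' For each of `n_rays` directions from the attractor, the initial rates of
#' pools L and R are varied along the ray while the remaining pools start
#' at their rates in the attractor; the boundary between initial points
#' converging to the attractor and initial points converging elsewhere is
#' bisected to `precision`.  Rays that stay inside one basin over the whole
#' probed range contribute no boundary point and are recorded as such.
#'
#' @param landscape an [enumerate_attractors()] result
#' @param attractor row index of the attractor in `landscape$attractors`
#' @param n_rays number of ray directions
#' @param precision bisection precision (Hz)
#' @param r_max maximum probed radius along a ray (Hz)
#' @param ... passed to [solve_fixed_point()]
#' @return data frame `(ray, angle, nu_L, nu_R, found)`
#' @export
basin_boundary <- function(landscape, attractor = 1, n_rays = 16,
                           precision = 0.1, r_max = 60, ...) {
  stopifnot(inherits(landscape, "attractor_landscape"),
            attractor >= 1, attractor <= nrow(landscape$attractors))
  fp <- landscape$fixed_points[[attractor]]
  cr <- condition_rates(landscape$condition, landscape$lambda,
                        landscape$dlambda, landscape$sure_rate)
  p <- landscape$params
  in_basin <- function(nuL, nuR) {
    init <- fp$nu; init[1] <- nuL; init[2] <- nuR
    g <- solve_fixed_point(p, cr["lambda"], cr["dlambda"], cr["lambda_S"],
                           init = pmax(init, 0), ...)
    g$converged && max(abs(g$nu - fp$nu)) < 0.5
  }
  angles <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  res <- lapply(seq_along(angles), function(k) {
    th <- angles[k]
    dir <- c(cos(th), sin(th))
    # clip the ray to the nonnegative quadrant
    r_hi <- r_max
    for (d in 1:2) if (dir[d] < 0) r_hi <- min(r_hi, -fp$nu[d] / dir[d])
    if (r_hi <= precision)
      return(data.frame(ray = k, angle = th, nu_L = NA_real_,
                        nu_R = NA_real_, found = FALSE))
    lo <- 0; hi <- r_hi
    if (in_basin(fp$nu[1] + hi * dir[1], fp$nu[2] + hi * dir[2]))
      return(data.frame(ray = k, angle = th, nu_L = NA_real_,
                        nu_R = NA_real_, found = FALSE))
    while (hi - lo > precision) {
      mid <- (lo + hi) / 2
      if (in_basin(fp$nu[1] + mid * dir[1], fp$nu[2] + mid * dir[2]))
        lo <- mid else hi <- mid
    }
    data.frame(ray = k, angle = th, nu_L = fp$nu[1] + (lo + hi) / 2 * dir[1],
               nu_R = fp$nu[2] + (lo + hi) / 2 * dir[2], found = TRUE)
  })
  do.call(rbind, res)
}
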