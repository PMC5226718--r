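# Independent transcriptions of the mean-field quantities, used as oracles.
# Written directly from the self-consistency equations in plain R; they
# share no code with the package's solver.

oracle_psi <- function(nu, tau_rise = 0.002, tau_decay = 0.1, alpha = 500,
                       nmax = 200) {
  tau_nmda <- alpha * tau_rise * tau_decay
  q <- nu * tau_nmda
  s <- 0
  for (n in 1:nmax) {
    k <- 0:n
    a <- tau_rise * (1 + q)
    Tn <- sum((-1)^k * choose(n, k) * a / (a + k * tau_decay))
    term <- (-alpha * tau_rise)^n * Tn / factorial(n + 1)
    s <- s + term
    if (is.finite(term) && abs(term) < 1e-16) break
  }
  q / (1 + q) * (1 + s / (1 + q))
}

# Transfer function by adaptive quadrature (stats::integrate) on the
# scaled-erfc integrand, with pracma's erfcx.
oracle_phi <- function(mu, sigma, tau_x, tau_rp, tau_ampa = 0.002,
                       V_thr = -50, V_reset = -55) {
  k <- tau_ampa / tau_x
  a <- (V_thr - mu) / sigma * (1 + 0.5 * k) + 1.03 * sqrt(k) - 0.5 * k
  b <- (V_reset - mu) / sigma
  if (a > 12) return(0)
  I <- stats::integrate(function(u) pracma::erfcx(-u), b, a,
                        rel.tol = 1e-12)$value
  1 / (tau_rp + tau_x * sqrt(pi) * I)
}

# Full independent evaluation of mu, sigma for all five populations at
# fixed rates (iterating the mean-potential feedback to convergence).
oracle_fields <- function(nu, nu_ext) {
  r <- c(0.2, 0.2, 0.2, 0.4)
  W <- matrix(1, 4, 4)
  for (x in 1:3) { W[, x] <- 0.878; W[x, x] <- 1.5 }
  psis <- vapply(nu[1:4], oracle_psi, numeric(1))
  nA <- c(as.vector(t(W) %*% (r * nu[1:4])), sum(r * nu[1:4]))
  nN <- c(as.vector(t(W) %*% (r * psis)), sum(r * psis))
  nG <- rep(nu[5], 5)
  gm <- c(rep(25, 4), 20); Cm <- c(rep(0.5, 4), 0.2)
  gae <- c(rep(2.08, 4), 1.62); gar <- c(rep(0.104, 4), 0.081)
  gn <- c(rep(0.327, 4), 0.258); gg <- c(rep(1.287, 4), 1.002)
  tau_m <- Cm / gm
  Text <- gae * 0.002 / gm
  TA <- gar * 800 * 0.002 / gm
  TI <- gg * 200 * 0.01 / gm
  Vx <- rep(-55, 5); mu <- rep(-70, 5); taux <- tau_m; sig2 <- rep(1, 5)
  for (it in 1:500) {
    J <- 1 + exp(-0.062 * Vx) / 3.57
    rho1 <- gn * 800 / (gm * J)
    rho2 <- 0.062 * gn * 800 * Vx * (J - 1) / (gm * J^2)
    Sx <- 1 + Text * nu_ext + TA * nA + (rho1 + rho2) * nN + TI * nG
    mu_new <- (rho2 * nN * Vx + TI * nG * (-70) + (-70)) / Sx
    taux <- Cm / (gm * Sx)
    sig2 <- gae^2 * Vx^2 * nu_ext * 0.002^2 * taux / (gm^2 * tau_m^2)
    Vx_new <- mu_new - 5 * nu * taux
    d <- max(abs(Vx_new - Vx) + abs(mu_new - mu))
    Vx <- Vx_new; mu <- mu_new
    if (d < 1e-12) break
  }
  list(mu = mu, sigma = sqrt(sig2), tau = taux, S_x = Sx)
}
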