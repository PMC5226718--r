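p_ref <- mf_params()

test_that("NMDA activation psi is zero at rest, saturating, increasing, and matches the series oracle", {
  expect_equal(psi_nmda(0, p_ref), 0)
  grid <- seq(0, 100, by = 2)
  v <- psi_nmda(grid, p_ref)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 1))
  for (nu in c(1, 3, 10, 25, 60))
    expect_equal(psi_nmda(nu, p_ref), oracle_psi(nu), tolerance = 1e-10)
})

test_that("transfer function: subthreshold silence, refractory ceiling, quadrature agrees with adaptive oracle", {
  expect_lt(mf_transfer(-100, 1, 0.02, 0.002, p_ref), 1e-6)
  grid <- expand.grid(mu = c(-58, -54, -52, -50.5, -49, -46),
                      sigma = c(0.8, 2, 5),
                      tau_x = c(0.004, 0.01, 0.02))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- mf_transfer(g$mu, g$sigma, g$tau_x, 0.002, p_ref)
    want <- oracle_phi(g$mu, g$sigma, g$tau_x, 0.002)
    expect_lt(abs(got - want) / max(want, 1e-9), 1e-6)
    expect_lt(got, 1 / 0.002)
  }
})

test_that("synaptic drives are weighted population sums", {
  z <- mf_drives(rep(0, 5), p_ref)
  expect_equal(unname(unlist(z)), rep(0, 15))
  nu <- c(3, 5, 2, 4, 9)
  d <- mf_drives(nu, p_ref)
  # independent direct summation
  r <- c(0.2, 0.2, 0.2, 0.4)
  W <- matrix(1, 4, 4); for (x in 1:3) { W[, x] <- 0.878; W[x, x] <- 1.5 }
  expect_equal(unname(d$ampa[1:4]), as.vector(t(W) %*% (r * nu[1:4])))
  expect_equal(unname(d$ampa[5]), sum(r * nu[1:4]))
  expect_equal(unname(d$gaba), rep(nu[5], 5))
  psis <- vapply(nu[1:4], oracle_psi, numeric(1))
  expect_equal(unname(d$nmda[1:4]), as.vector(t(W) %*% (r * psis)),
               tolerance = 1e-9)
})

test_that("input statistics: leak-only limit and agreement with an independent transcription", {
  # no external drive, no activity: total conductance 1, mu at leak reversal
  p0 <- mf_params(network_spec(nu_ext_source = 0))
  f0 <- mu_sigma(rep(0, 5), p0)
  expect_equal(unname(f0$mu), rep(-70, 5))
  expect_equal(unname(f0$S_x), rep(1, 5))
  expect_true(all(f0$sigma < 1e-10))   # sigma is proportional to sqrt(nu_ext)
  # spontaneous-like rates against the oracle transcription
  nu <- c(2.5, 2.5, 2.5, 2.4, 8.3)
  f <- mu_sigma(nu, p_ref)
  o <- oracle_fields(nu, rep(2400, 5))
  expect_equal(unname(f$mu), o$mu, tolerance = 1e-8)
  expect_equal(unname(f$sigma), o$sigma, tolerance = 1e-8)
  expect_equal(unname(f$tau), o$tau, tolerance = 1e-8)
})

test_that("fixed points: spontaneous state, residual self-consistency, mirror symmetry", {
  fp <- solve_fixed_point(p_ref, lambda = 0)
  expect_true(fp$converged)
  expect_equal(fp$classification, "spontaneous")
  expect_true(all(fp$nu[c("L", "R")] > 1.5 & fp$nu[c("L", "R")] < 4))
  expect_lt(fp$residual, 1e-3)
  # every population simultaneously satisfies nu = phi(mu, sigma)
  trp <- c(rep(p_ref$tau_rp_exc, 4), p_ref$tau_rp_inh)
  phi <- mf_transfer(fp$mu, fp$sigma, fp$tau, trp, p_ref)
  expect_equal(unname(phi), unname(fp$nu), tolerance = 1e-3)
  # mirrored initial conditions give mirrored fixed points at dlambda = 0
  a <- solve_fixed_point(p_ref, lambda = 50, init = c(40, 5, 2, 3, 9))
  b <- solve_fixed_point(p_ref, lambda = 50, init = c(5, 40, 2, 3, 9))
  expect_equal(unname(a$nu[c(1, 2)]), unname(b$nu[c(2, 1)]), tolerance = 1e-4)
  expect_equal(a$classification, "decision_L")
  expect_equal(b$classification, "decision_R")
})

test_that("sure-target condition has an opt-out attractor with both decision pools suppressed", {
  fp <- solve_fixed_point(p_ref, lambda = 0, lambda_S = 5,
                          init = c(2, 2, 30, 3, 9))
  expect_equal(fp$classification, "decision_S")
  expect_equal(unname(fp$nu["L"]), unname(fp$nu["R"]), tolerance = 1e-6)
  expect_lt(fp$nu["L"], 4)
  expect_gt(fp$nu["S"], 20)
})

test_that("attractor enumeration recovers the regime structure", {
  # multistable operating point: two decision attractors plus the mixed state
  ls50 <- enumerate_attractors(p_ref, lambda = 50)
  expect_setequal(ls50$attractors$class,
                  c("decision_L", "decision_R", "mixed"))
  expect_equal(nrow(ls50$attractors), 3)
  # bistable regime: only the two decision attractors
  ls15 <- enumerate_attractors(p_ref, lambda = 15)
  expect_setequal(ls15$attractors$class, c("decision_L", "decision_R"))
  expect_equal(nrow(ls15$attractors), 2)
  # delay epoch: resting state plus two decision-memory attractors
  ls0 <- enumerate_attractors(p_ref, lambda = 0, condition = "delay")
  expect_setequal(ls0$attractors$class,
                  c("spontaneous", "decision_L", "decision_R"))
})

test_that("basin boundaries are mirror-symmetric at zero evidence and verified by two-sided probes", {
  ls <- enumerate_attractors(p_ref, lambda = 50)
  iL <- which(ls$attractors$class == "decision_L")
  iR <- which(ls$attractors$class == "decision_R")
  bL <- basin_boundary(ls, iL, n_rays = 8, r_max = 30)
  bR <- basin_boundary(ls, iR, n_rays = 8, r_max = 30)
  found_L <- bL[bL$found, ]
  expect_gt(nrow(found_L), 2)
  # mirror: for each L-boundary point there is an R-boundary point at the
  # reflected position (rays are laid out symmetrically about the diagonal)
  refl <- found_L[, c("nu_R", "nu_L")]
  bRf <- bR[bR$found, c("nu_L", "nu_R")]
  for (i in seq_len(nrow(refl))) {
    dmin <- min(sqrt((bRf$nu_L - refl$nu_R[i])^2 +
                       (bRf$nu_R - refl$nu_L[i])^2))
    expect_lt(dmin, 0.5)
  }
  # two-sided probe across the first boundary point's ray
  fp <- ls$fixed_points[[iL]]
  b1 <- found_L[1, ]
  dir <- c(b1$nu_L - fp$nu[1], b1$nu_R - fp$nu[2])
  dir <- dir / sqrt(sum(dir^2))
  probe <- function(d) {
    init <- fp$nu
    init[1] <- b1$nu_L + d * dir[1]; init[2] <- b1$nu_R + d * dir[2]
    g <- solve_fixed_point(p_ref, lambda = 50, init = pmax(init, 0))
    max(abs(g$nu - fp$nu)) < 0.5
  }
  expect_true(probe(-0.15))
  expect_false(probe(+0.15))
})
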