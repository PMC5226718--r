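test_that("psychometric table: degenerate and symmetric cases", {
  tr <- rbind(fake_trials(50, final_choice = "L", free_choice = FALSE),
              fake_trials(50, final_choice = "L", free_choice = TRUE))
  ps <- psychometrics(tr)
  expect_equal(ps$p_correct_forced, 1)
  expect_equal(ps$p_sure, 0)
  # balanced outcomes give chance-level accuracy
  tr2 <- rbind(fake_trials(100, final_choice = rep(c("L", "R"), 50),
                           free_choice = FALSE),
               fake_trials(100, final_choice = rep(c("L", "R"), 50)))
  ps2 <- psychometrics(tr2)
  expect_equal(ps2$p_correct_forced, 0.5)
  expect_true(ps2$p_correct_forced_lo < 0.5 & ps2$p_correct_forced_hi > 0.5)
})

test_that("conditional sure-choice map reproduces a constructed rule and masks sparse bins", {
  set.seed(1)
  n <- 4000
  nu_L <- runif(n, 0, 20); nu_R <- runif(n, 0, 20)
  choice <- ifelse(pmax(nu_L, nu_R) < 10, "S", "L")
  tr <- fake_trials(n, final_choice = choice, nu_L = nu_L, nu_R = nu_R)
  m <- conditional_sure_map(tr, analysis_params(min_count = 5))
  inside <- !m$masked & pmax(m$nu_L, m$nu_R) < 9.5
  outside <- !m$masked & pmax(m$nu_L, m$nu_R) > 10.5
  expect_true(all(m$p_sure[inside] == 1))
  expect_true(all(m$p_sure[outside] == 0))
  # a bin with fewer than 30 trials is masked under the default threshold
  tr29 <- fake_trials(29, final_choice = "S", nu_L = 3.2, nu_R = 3.7)
  m29 <- conditional_sure_map(tr29)
  expect_true(all(m29$masked))
  expect_true(all(is.na(m29$p_sure)))
})

test_that("sure-probability projections are flat for constant rules and monotone for threshold rules", {
  set.seed(2)
  n <- 3000
  nu_L <- runif(n, 0, 25); nu_R <- runif(n, 0, 25)
  all_s <- fake_trials(n, final_choice = "S", nu_L = nu_L, nu_R = nu_R)
  pj <- sure_probability_projections(all_s)
  expect_true(all(pj$diff$one_minus_p_sure == 0))
  expect_true(all(pj$sum$one_minus_p_sure == 0))
  # rule depending only on |nu_L - nu_R|: difference projection is monotone
  choice <- ifelse(abs(nu_L - nu_R) < 8, "S", "L")
  tr <- fake_trials(n, final_choice = choice, nu_L = nu_L, nu_R = nu_R)
  pj2 <- sure_probability_projections(tr)
  expect_lt(attr(pj2$diff, "isotonic_residual"), 0.05)
})

test_that("decision-time split finds an interior dip between two modes and flags unimodal histograms", {
  set.seed(3)
  dts <- c(rnorm(400, 250, 60), rnorm(300, 900, 150))
  tr <- fake_trials(700, dt = pmax(dts, 30))
  sp <- dt_split(tr)
  expect_true(sp$interior_dip)
  expect_gt(sp$split_ms, 400)
  expect_lt(sp$split_ms, 800)
  expect_equal(nrow(sp$fast) + nrow(sp$slow), 700)
  expect_true(all(sp$fast$dt <= sp$split_ms), all(sp$slow$dt > sp$split_ms))
  # unimodal: minimum pinned to the search-range boundary, flagged
  uni <- fake_trials(600, dt = pmax(rnorm(600, 260, 70), 30))
  expect_false(dt_split(uni)$interior_dip)
})

test_that("bootstrap error-count comparison: null case is calm, constructed effect is detected", {
  set.seed(4)
  same <- fake_trials(300, early_choice = rep(c("L", "R"), c(240, 60)))
  b0 <- bootstrap_error_counts(same, same, B = 2000, seed = 9)
  expect_gt(b0$t_test$p.value, 1e-6)  # identical populations
  expect_lt(abs(mean(b0$fast_counts) - mean(b0$slow_counts)), 5)
  fast <- fake_trials(500, early_choice = rep(c("L", "R"), c(450, 50)))
  slow <- fake_trials(500, early_choice = rep(c("L", "R"), c(400, 100)))
  b1 <- bootstrap_error_counts(fast, slow, B = 2000, seed = 9)
  expect_lt(b1$t_test$p.value, 1e-100)
  expect_gt(mean(b1$slow_counts), mean(b1$fast_counts))
  # reproducible given the seed
  b2 <- bootstrap_error_counts(fast, slow, B = 2000, seed = 9)
  expect_identical(b1$fast_counts, b2$fast_counts)
})

test_that("probabilistic X-pattern obeys its algebraic identities", {
  # no sure choices and unchanged accuracy: both conditionals vanish
  z <- xpattern_probabilistic(0.8, 0, 0.8)
  expect_equal(z$p_sure_correct, 0)
  expect_equal(z$p_sure_error, 0)
  # outcome-independent opting out: P(S|C) = P(S) = P(S|E)
  id <- xpattern_probabilistic(0.7, 0.3, 0.7)
  expect_equal(id$p_sure_correct, 0.3)
  expect_equal(id$p_sure_error, 0.3)
  # law of total probability holds exactly for arbitrary valid triples
  set.seed(5)
  pc <- runif(200, 0.05, 0.95)
  ps <- runif(200, 0, 0.9)
  pcw <- runif(200, 0.05, 0.95)
  z2 <- xpattern_probabilistic(pc, ps, pcw)
  lhs <- z2$p_sure_correct * pc + z2$p_sure_error * (1 - pc)
  expect_equal(lhs, ps, tolerance = 1e-12)
})

test_that("simulated X-pattern recovers constructed conditional frequencies", {
  set.seed(6)
  n <- 2000
  dl <- rep(c(0, 8, 16), length.out = n)
  correct <- runif(n) < 0.5 + dl / 40
  # sure choices: more likely after errors at high evidence
  p_s <- ifelse(correct, 0.5 - dl / 40, 0.5 + dl / 60)
  choice <- ifelse(runif(n) < p_s, "S", ifelse(correct, "L", "R"))
  tr <- fake_trials(n, final_choice = choice,
                    early_choice = ifelse(correct, "L", "R"))
  tr$dlambda <- dl
  xp <- xpattern_simulated(tr)
  xc <- xp[xp$outcome == "correct", ]
  xe <- xp[xp$outcome == "error", ]
  expect_true(all(diff(xc$p_sure[order(xc$dlambda)]) < 0))
  expect_true(all(diff(xe$p_sure[order(xe$dlambda)]) > 0))
})

test_that("reward amount is the stated linear combination", {
  expect_equal(reward_amount(0.7, 0), 0.7)
  expect_equal(reward_amount(0.6, 0.5, w_S = 0.8), 1.0)
  expect_equal(reward_amount(0.6, 0.5, w_S = 1.1) -
                 reward_amount(0.6, 0.5, w_S = 0.8), 0.3 * 0.5)
  expect_equal(formals(reward_amount)$w_S, 0.8)
  tr <- fake_trials(10, final_choice = rep(c("L", "R", "S", "undecided"),
                                           c(4, 3, 2, 1)))
  expect_equal(reward_per_trial(tr, w_S = 0.8), (4 + 0.8 * 2) / 10)
})

test_that("rate distributions summarise across-diagonal asymmetry", {
  set.seed(7)
  sym <- fake_trials(1000, nu_L = runif(1000, 0, 30),
                     nu_R = runif(1000, 0, 30))
  rs <- rate_distributions(sym)$summary
  expect_lt(abs(rs$mean_signed_diff), 1.5)
  skew <- fake_trials(1000, nu_L = runif(1000, 15, 35),
                      nu_R = runif(1000, 0, 10))
  rk <- rate_distributions(skew)$summary
  expect_gt(rk$mean_signed_diff, 15)
  h <- rate_distributions(skew)$histograms
  expect_equal(sum(h$p), 1)
})

test_that("profiles round-trip through YAML and reject unknown keys", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(c("network:", "  N: 200", "decision:", "  theta: 24"), f)
  pf <- read_profile(f)
  expect_equal(pf$network$N, 200)
  expect_equal(pf$decision$theta, 24)
  expect_equal(pf$synapse$g_nmda_exc, 0.327)   # defaults fill the rest
  writeLines(c("network:", "  frobnicate: 1"), f)
  expect_error(read_profile(f), "unknown key")
  writeLines("bogus_section: {}", f)
  expect_error(read_profile(f), "unknown profile section")
  # trial tables round-trip through CSV
  tr <- fake_trials(5)
  g <- tempfile(fileext = ".csv")
  on.exit(unlink(g), add = TRUE)
  write_trials(tr, g)
  back <- read_trials(g)
  expect_equal(back$final_choice, tr$final_choice)
  expect_s3_class(back, "trial_set")
})
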