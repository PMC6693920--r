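test_that("drift_rate follows the signed power law", {
  p <- fix_ddm_params(kappa = 2, mu0 = 0, plaw = 1)
  expect_equal(drift_rate(0, p), 0)
  expect_equal(drift_rate(0.5, p), 1.0)
  p2 <- fix_ddm_params(kappa = 2, mu0 = 0.1, plaw = 0.7)
  expect_equal(drift_rate(-0.5, p2), -2 * 0.5^0.7 + 0.1, tolerance = 1e-12)
  expect_equal(drift_rate(0, p2), 0.1)  # zero strength -> bias only
})

test_that("bound_height is flat until Bdel then collapses exponentially", {
  p <- fix_ddm_params(B0 = 1.5, Bdel = 0.3, B2 = 0.5)
  expect_equal(bound_height(c(0, 0.1, 0.29), p), rep(1.5, 3))
  expect_equal(bound_height(0.3 + 0.5, p), 1.5 / exp(1))
  p_flat <- fix_ddm_params(B0 = 1.5, Bdel = 0, B2 = 1e9)
  expect_equal(bound_height(seq(0, 5, 0.5), p_flat), rep(1.5, 11),
               tolerance = 1e-8)
})

test_that("zero drift with symmetric bounds splits mass evenly", {
  p <- fix_ddm_params(kappa = 1, mu0 = 0, B0 = 1, Bdel = 0.2, B2 = 0.8)
  fp <- solve_first_passage(0, p, solver_grid(t_max = 6))
  pu <- sum(fp$g_upper) * fp$dt
  pl <- sum(fp$g_lower) * fp$dt
  expect_equal(pu, pl, tolerance = 1e-10)
  expect_equal(pu + pl + fp$survivor, 1, tolerance = 1e-3)
})

test_that("flat-bound closed forms hold within 0.5% over |mu|*B0 in [0.1, 3]", {
  for (muB in c(0.1, 0.3, 1, 2, 3)) {
    B0 <- 1
    p <- fix_ddm_params(B0 = B0, Bdel = 1e5, B2 = 1, mu0 = muB / B0,
                        sigma_tnd = 0)
    fp <- solve_first_passage(0, p, solver_grid(t_max = min(25 / muB, 60)))
    pu <- sum(fp$g_upper) * fp$dt
    pl <- sum(fp$g_lower) * fp$dt
    p_th <- 1 / (1 + exp(-2 * muB))
    t_th <- (B0 / (muB / B0)) * tanh(muB)
    expect_lt(abs(pu / (pu + pl) / p_th - 1), 0.005)
    expect_lt(abs(fp_mean_time(fp) / t_th - 1), 0.005)
  }
})

test_that("mass is conserved within 1e-3 across random parameter sets", {
  set.seed(42)
  for (i in 1:8) {
    p <- ddm_params(kappa = runif(1, 0.5, 6), B0 = runif(1, 0.5, 2.5),
                    Bdel = runif(1, 0, 1), B2 = runif(1, 0.2, 3),
                    tnd = 0.3, sigma_tnd = 0.05,
                    mu0 = runif(1, -1, 1), plaw = runif(1, 0.5, 1.5))
    fp <- solve_first_passage(runif(1, -2, 2), p, solver_grid(t_max = 8))
    total <- (sum(fp$g_upper) + sum(fp$g_lower)) * fp$dt + fp$survivor
    expect_equal(total, 1, tolerance = 1e-3)
  }
})

test_that("negating the strength (mu0 = 0) swaps the two densities exactly", {
  p <- fix_ddm_params(mu0 = 0, plaw = 0.8)
  g <- solver_grid(t_max = 5)
  a <- solve_first_passage(0.7, p, g)
  b <- solve_first_passage(-0.7, p, g)
  expect_equal(a$g_upper, b$g_lower, tolerance = 1e-9)
  expect_equal(a$g_lower, b$g_upper, tolerance = 1e-9)
})

test_that("halving dt and dx moves P(upper) by less than 1e-3", {
  p <- fix_ddm_params()
  fine <- solver_grid(dt = 2.5e-4, t_max = 5, n_points = 400)
  dflt <- solver_grid(dt = 5e-4, t_max = 5)
  for (s in c(0.25, 1)) {
    p1 <- fp_choice_prob(solve_first_passage(s, p, dflt))
    p2 <- fp_choice_prob(solve_first_passage(s, p, fine))
    expect_lt(abs(p1 - p2), 1e-3)
  }
})

test_that("a too-coarse grid trips the conservation guard", {
  p <- fix_ddm_params()
  expect_error(solve_first_passage(1, p,
                                   solver_grid(dt = 0.01, t_max = 3,
                                               dx = 0.3)),
               "solver accuracy")
})

test_that("non-decision convolution shifts, spreads and conserves mass", {
  p0 <- fix_ddm_params(tnd = 0.4, sigma_tnd = 0)
  fp <- solve_first_passage(0.5, p0, solver_grid(t_max = 6))
  rtd <- apply_nondecision(fp, p0)
  # sigma -> 0: pure shift by tnd
  expect_equal(fp_mean_time(rtd), fp_mean_time(fp) + 0.4, tolerance = 2e-3)
  # conservation incl. survivor
  tot <- (sum(rtd$d_upper) + sum(rtd$d_lower)) * rtd$dt + rtd$survivor
  expect_equal(tot, 1, tolerance = 2e-3)
  # gaussian case: mean rt = mean decision time + tnd
  p1 <- fix_ddm_params(tnd = 0.4, sigma_tnd = 0.06)
  rtd1 <- apply_nondecision(fp, p1)
  expect_equal(fp_mean_time(rtd1), fp_mean_time(fp) + 0.4,
               tolerance = 3e-3)
  expect_true(all(rtd1$d_upper >= 0) && all(rtd1$d_lower >= 0))
})

test_that("mean RT matches the moment oracle from simulation", {
  p <- fix_ddm_params(tnd = 0.45, sigma_tnd = 0.05)
  rtd <- apply_nondecision(solve_first_passage(0.5, p,
                                               solver_grid(t_max = 8)), p)
  sim <- simulate_ddm_trials(rep(0.5, 2e4), p, deadline = 8, dt = 2e-4,
                             seed = 21)
  m <- sim$valid
  se <- sd(sim$rt[m]) / sqrt(sum(m))
  expect_lt(abs(fp_mean_time(rtd) - mean(sim$rt[m])),
            3 * se + 2 * rtd$dt + 0.5826 * sqrt(2e-4))
})

test_that("trial_loglik is symmetric for mirrored trials and matches its pieces", {
  p <- fix_ddm_params(mu0 = 0)
  g <- solver_grid(dt = 1e-3, t_max = 4)
  ll_up <- trial_loglik(0, 1, 0.9, p, g)
  ll_lo <- trial_loglik(0, 0, 0.9, p, g)
  expect_equal(ll_up, ll_lo, tolerance = 1e-12)
  # definitional consistency with solve + convolve + interpolate
  dens <- apply_nondecision(solve_first_passage(0.5, p, g), p)
  expect_equal(trial_loglik(0.5, 1, 1.1, p, g),
               log(approx(dens$times, dens$d_upper, xout = 1.1)$y))
  # floor instead of -Inf for impossible RTs
  expect_equal(trial_loglik(0.5, 1, 1e-4, p, g), log(1e-10))
})

test_that("RT density matches a Monte-Carlo histogram within binning error", {
  p <- fix_ddm_params()
  g <- solver_grid(dt = 1e-3, t_max = 6)
  dens <- apply_nondecision(solve_first_passage(0.5, p, g), p)
  sim <- simulate_ddm_trials(rep(0.5, 1e5), p, deadline = 6, dt = 2e-4,
                             seed = 31)
  up <- sim$rt[sim$valid & sim$choice == 1]
  br <- seq(0.3, 3, by = 0.15)
  h <- hist(up[up > 0.3 & up < 3], breaks = br, plot = FALSE)
  # model density for upper choices at bin midpoints (per-trial scale)
  d_mod <- approx(dens$times, dens$d_upper, xout = h$mids)$y
  emp <- h$density * length(up[up > 0.3 & up < 3]) / sum(sim$valid)
  for (k in seq_along(h$mids)) {
    n_k <- h$counts[k]
    se_k <- sqrt(max(n_k, 1)) / (sum(sim$valid) * 0.15)
    expect_lt(abs(emp[k] - d_mod[k]), 4 * se_k + 0.02)
  }
})

test_that("ddm_nll equals the sum of per-trial log-likelihoods", {
  p <- fix_ddm_params()
  g <- solver_grid(dt = 2e-3, t_max = 4, n_points = 120)
  tbl <- sim_value_table(p, n_per_level = 2, seed = 8)
  keep <- tbl$valid
  per_trial <- mapply(function(s, ch, rt) trial_loglik(s, ch, rt, p, g),
                      trial_strength(tbl)[keep], trial_choice(tbl)[keep],
                      tbl$rt[keep])
  expect_equal(ddm_nll(tbl, p, g), -sum(per_trial), tolerance = 1e-8)
})
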