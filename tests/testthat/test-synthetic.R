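check_value_design <- function(des) {
  trials <- des$trials
  expect_equal(nrow(trials), 210)
  expect_equal(nrow(des$pairs), 150)
  expect_equal(sum(des$pairs$repeated), 60)
  # each item in exactly 5 unique pairs
  pair_counts <- table(c(des$pairs$item_a, des$pairs$item_b))
  expect_true(all(pair_counts == 5))
  # each item appears exactly 7 times over the 210 trials
  app <- table(c(trials$item_left, trials$item_right))
  expect_true(all(app == 7))
  # repeated pairs give each item exactly 2 extra appearances
  rep_counts <- table(c(des$pairs$item_a[des$pairs$repeated],
                        des$pairs$item_b[des$pairs$repeated]))
  expect_true(all(rep_counts == 2))
  # 150 distinct unordered pairs
  key <- apply(cbind(pmin(des$pairs$item_a, des$pairs$item_b),
                     pmax(des$pairs$item_a, des$pairs$item_b)), 1,
               paste, collapse = "|")
  expect_equal(length(unique(key)), 150)
  # three runs of 70
  expect_equal(as.vector(table(trials$run)), c(70, 70, 70))
  # higher-value side counterbalanced 105/105
  hi_right <- trials$value_right > trials$value_left
  expect_equal(sum(hi_right), 105)
}

test_that("value design invariants hold across 100 seeds", {
  set.seed(1)
  vals <- setNames(runif(60, 0, 3), sprintf("item%02d", 1:60))
  for (seed in 1:100) {
    des <- generate_value_design(vals, seed = seed)
    trials <- des$trials
    expect_equal(nrow(trials), 210)
    app <- table(c(trials$item_left, trials$item_right))
    expect_true(all(app == 7))
    expect_equal(sum(trials$value_right > trials$value_left), 105)
  }
  # full structural check on a couple of seeds
  check_value_design(generate_value_design(vals, seed = 1))
  check_value_design(generate_value_design(vals, seed = 77))
  # determinism
  expect_identical(generate_value_design(vals, seed = 5),
                   generate_value_design(vals, seed = 5))
  expect_error(generate_value_design(vals[1:59]), "60")
})

test_that("pair construction spans small to large value differences", {
  vals <- setNames(seq(0, 3, length.out = 60), sprintf("i%02d", 1:60))
  des <- generate_value_design(vals, seed = 2)
  dv <- abs(vals[des$pairs$item_a] - vals[des$pairs$item_b])
  expect_lt(min(dv), 0.1)
  expect_gt(max(dv), 1.4)
  expect_gt(length(unique(round(dv, 3))), 2)
})

test_that("perceptual design covers the 11 levels, balanced, deterministic", {
  des <- generate_perceptual_design(210, seed = 3)
  expect_equal(nrow(des), 210)
  expect_setequal(unique(des$coherence), coherence_levels())
  counts <- table(des$coherence)
  expect_true(all(counts %in% c(19, 20)))
  # sign balance within binomial error
  signed <- des$coherence[des$coherence != 0]
  expect_lt(abs(mean(signed > 0) - 0.5),
            3 * sqrt(0.25 / length(signed)))
  expect_identical(generate_perceptual_design(210, seed = 3), des)
  expect_equal(as.vector(table(des$run)), c(70, 70, 70))
})

test_that("pblue follows the logistic in coherence", {
  expect_equal(pblue_from_coherence(0), 0.5)
  expect_equal(pblue_from_coherence(2), exp(2) / (1 + exp(2)),
               tolerance = 1e-12)
  expect_equal(pblue_from_coherence(2), 0.88080, tolerance = 1e-5)
  C <- coherence_levels()
  expect_equal(pblue_from_coherence(C) + pblue_from_coherence(-C),
               rep(1, 11))
})

test_that("dot frames match the stated density, color and aperture stats", {
  lambda <- 16.7 * pi * 2.5^2 / 60
  expect_equal(lambda, 5.46, tolerance = 0.01)
  set.seed(99)
  frames <- replicate(2000, nrow(sample_dot_frame(0.5)))
  expect_lt(abs(mean(frames) - lambda),
            3 * sqrt(lambda / 2000))
  big <- sample_dot_frame(0.5, aperture_diameter = 5, density = 16.7 * 500,
                          seed = 4)
  expect_true(all(big$x^2 + big$y^2 <= 2.5^2))
  pb <- mean(big$blue)
  p_th <- pblue_from_coherence(0.5)
  expect_lt(abs(pb - p_th), 3 * sqrt(p_th * (1 - p_th) / nrow(big)))
})

test_that("ddm simulator reproduces symmetry and the flat-bound closed form", {
  p0 <- fix_ddm_params(mu0 = 0)
  sim0 <- simulate_ddm_trials(rep(0, 2e4), p0, deadline = 10, dt = 1e-3,
                              seed = 5)
  m <- sim0$valid
  expect_lt(abs(mean(sim0$choice[m]) - 0.5), 3 * sqrt(0.25 / sum(m)))
  p1 <- fix_ddm_params(B0 = 1, Bdel = 1e5, mu0 = 1, sigma_tnd = 0.02)
  sim1 <- simulate_ddm_trials(rep(0, 2e4), p1, deadline = 30, dt = 2e-4,
                              seed = 6)
  m1 <- sim1$valid
  pu <- mean(sim1$choice[m1])
  p_th <- 1 / (1 + exp(-2))
  expect_lt(abs(pu - p_th), 3 * sqrt(p_th * (1 - p_th) / sum(m1)) + 0.002)
  # rt is decision time plus a nonnegative non-decision draw
  expect_true(all(sim1$rt >= sim1$decision_time))
  # determinism given seed
  expect_identical(simulate_ddm_trials(rep(0.5, 50), p0, seed = 9),
                   simulate_ddm_trials(rep(0.5, 50), p0, seed = 9))
})

test_that("heuristic simulator follows the rules and moments", {
  hp <- fix_heuristic_params(kappa1 = 1, kappa2 = 2, p_trivial = 0.99)
  # D_plus right vs D_minus left: forced right
  sim <- simulate_heuristic_trials(rep(0.2, 1e4), rep(2.8, 1e4), hp,
                                   seed = 10)
  expect_lt(abs(mean(sim$chose_right) - 0.99),
            3 * sqrt(0.99 * 0.01 / 1e4))
  expect_lt(abs(mean(sim$rt) - hp$mu_fast),
            3 * hp$sigma_fast / sqrt(1e4))
  # non-trivial at zero delta: 50/50
  hp0 <- fix_heuristic_params(kappa1 = 1, kappa2 = 2, beta0 = 0)
  simn <- simulate_heuristic_trials(rep(1.5, 1e4), rep(1.5, 1e4), hp0,
                                    seed = 11)
  expect_lt(abs(mean(simn$chose_right) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("synthesized cohorts have the requested structure and round-trip", {
  spec <- default_cohort_spec(seed = 21)
  coh <- synthesize_cohort(spec, sim_dt = 2e-3)
  v <- coh$value
  expect_equal(length(unique(v$subject[v$group == "healthy"])), 14)
  expect_equal(length(unique(v$subject[v$group == "amnesic"])), 6)
  expect_equal(nrow(v), 20 * 210)
  expect_equal(nrow(coh$perceptual), 20 * 210)
  # round-trip through the exp2 writer/reader is lossless
  path <- withr::local_tempfile(fileext = ".csv")
  write_value_trials(v, path, dialect = "exp2")
  back <- read_value_trials(path, dialect = "exp2")
  expect_equal(back$value_left, v$value_left)
  expect_equal(back$chose_right, v$chose_right)
  expect_equal(back$group, v$group)
})

test_that("a steeper-drift group keeps a steeper fitted choice slope end-to-end", {
  spec <- default_cohort_spec(seed = 33)
  coh <- synthesize_cohort(spec, sim_dt = 2e-3, perceptual = FALSE)
  v <- coh$value
  slope_of <- function(g) {
    d <- v[v$group == g & v$valid, ]
    coef(glm(chose_right ~ I(value_right - value_left), d,
             family = binomial()))[2]
  }
  expect_gt(slope_of("healthy"), slope_of("amnesic"))
})
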