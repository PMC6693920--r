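# shared fixtures: small parameter sets and simulated trial tables

fix_ddm_params <- function(...) {
  args <- list(kappa = 2, B0 = 1.2, Bdel = 0.4, B2 = 1.5, tnd = 0.45,
               sigma_tnd = 0.08, mu0 = 0, plaw = 1)
  args[names(list(...))] <- list(...)
  do.call(ddm_params, args)
}

fix_heuristic_params <- function(...) {
  args <- list(kappa1 = -0.6, kappa2 = 0.8, mu_fast = 0.9,
               sigma_fast = 0.25, mu_slow = 1.8, sigma_slow = 0.45,
               beta0 = 0, beta1 = 2.5, p_trivial = 0.99)
  args[names(list(...))] <- list(...)
  do.call(heuristic_params, args)
}

# value table whose strengths are the 11 coherence-like levels, behavior
# simulated from a ddm agent
sim_value_table <- function(params = fix_ddm_params(), n_per_level = 40,
                            deadline = 3.5, dt = 1e-3, seed = 1) {
  s <- rep(coherence_levels(), n_per_level)
  beh <- simulate_ddm_trials(s, params, deadline = deadline, dt = dt,
                             seed = seed)
  value_trials(subject = "s1", value_left = 0, value_right = s,
               chose_right = ifelse(beh$valid, beh$choice, NA),
               rt = ifelse(beh$valid, beh$rt, NA), valid = beh$valid,
               deadline = deadline)
}

# random small value table (uniform values, logistic choices) for IO and
# likelihood-oracle tests
rand_value_table <- function(n = 50, seed = 1, experiment = "exp1") {
  set.seed(seed)
  vl <- round(runif(n, 0, 3), 2)
  vr <- round(runif(n, 0, 3), 2)
  ch <- as.integer(runif(n) < plogis(2 * (vr - vl)))
  rt <- round(runif(n, 0.4, 2.8), 3)
  value_trials(subject = sample(c("s1", "s2"), n, replace = TRUE),
               value_left = vl, value_right = vr, chose_right = ch,
               rt = rt, group = if (experiment == "exp2")
                 sample(c("healthy", "amnesia"), n, replace = TRUE)
                 else NULL,
               experiment = experiment,
               deadline = if (experiment == "exp1") 3.0 else 3.5)
}

rand_perceptual_table <- function(n = 50, seed = 1, experiment = "exp1") {
  set.seed(seed)
  coh <- sample(coherence_levels(), n, replace = TRUE)
  ch <- as.integer(runif(n) < plogis(3 * coh))
  perceptual_trials(subject = sample(c("s1", "s2"), n, replace = TRUE),
                    coherence = coh, chose_blue = ch,
                    rt = round(runif(n, 0.4, 2.2), 3),
                    button_order = sample(1:2, n, replace = TRUE),
                    group = if (experiment == "exp2")
                      sample(c("healthy", "amnesia"), n, replace = TRUE)
                      else NULL,
                    experiment = experiment,
                    deadline = if (experiment == "exp1") 2.5 else 3.5)
}
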