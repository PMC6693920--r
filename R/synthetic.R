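# run expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate the 60-item / 150-pair / 210-trial value-task design
#'
#' Items are rank-ordered by value and paired on a circulant scheme over the
#' rank circle with offsets 1, 7 and 30: 150 unique unordered pairs in which
#' every item appears exactly 5 times, with ΔValue spanning small (adjacent
#' ranks), medium, and large (opposite ranks) differences.  The 60 offset-1
#' pairs are presented twice and the other 90 once, so each item appears 7
#' times across the 210 trials.  Trial order is a seeded shuffle into 3 runs
#' of 70; the side of the higher-value item is counterbalanced (105/105)
#' across trials.
#'
#' @param values numeric vector of exactly 60 per-item values (names used
#'   as item identifiers; defaults to item01..item60).
#' @param seed integer seed; the design is deterministic given the seed.
#' @return a `value_design`: list with `items` (item, value), `pairs`
#'   (item_a, item_b, repeated) and `trials` (trial, run, item_left,
#'   item_right, value_left, value_right).
#' @export
generate_value_design <- function(values, seed = 1) {
  if (length(values) != 60) stop("exactly 60 item values required")
  if (is.null(names(values)))
    names(values) <- sprintf("item%02d", seq_len(60))
  .with_seed(seed, {
    ord <- order(values)  # rank circle
    idx <- function(i) ord[((i - 1) %% 60) + 1]
    pairs <- do.call(rbind, lapply(c(1, 7, 30), function(off) {
      n_edges <- if (off == 30) 30 else 60
      data.frame(a = idx(seq_len(n_edges)),
                 b = idx(seq_len(n_edges) + off),
                 repeated = off == 1)
    }))
    pres <- pairs[c(seq_len(nrow(pairs)), which(pairs$repeated)), ]
    stopifnot(nrow(pres) == 210)
    pres <- pres[sample.int(210), ]
    # counterbalance the side of the higher-value item: exactly 105 right
    hi_right <- sample(rep(c(TRUE, FALSE), 105))
    hi_is_a <- values[pres$a] >= values[pres$b]
    left <- ifelse(hi_right == hi_is_a, pres$b, pres$a)
    right <- ifelse(hi_right == hi_is_a, pres$a, pres$b)
    trials <- data.frame(trial = seq_len(210),
                         run = rep(1:3, each = 70),
                         item_left = names(values)[left],
                         item_right = names(values)[right],
                         value_left = unname(values[left]),
                         value_right = unname(values[right]))
    structure(list(items = data.frame(item = names(values),
                                      value = unname(values)),
                   pairs = data.frame(item_a = names(values)[pairs$a],
                                      item_b = names(values)[pairs$b],
                                      repeated = pairs$repeated),
                   trials = trials),
              class = "value_design")
  })
}

#' Generate a 210-trial perceptual design over the 11 coherence levels
#'
#' Signed coherences are drawn from the canonical 11-level set
#' `{-2, -1, -0.5, -0.25, -0.125, 0, 0.125, 0.25, 0.5, 1, 2}`,
#' approximately balanced across levels (each level appears
#' `floor(n/11)` or `floor(n/11)+1` times) and shuffled into runs.
#'
#' @param n_trials total trials (divisible by `runs`).
#' @param seed integer seed.
#' @param runs number of blocks.
#' @return data frame with `trial`, `run`, `coherence`, `p_blue`.
#' @export
generate_perceptual_design <- function(n_trials = 210, seed = 1, runs = 3) {
  stopifnot(n_trials %% runs == 0)
  lv <- coherence_levels()
  .with_seed(seed, {
    base <- rep(lv, floor(n_trials / length(lv)))
    extra <- sample(lv, n_trials - length(base))
    coh <- sample(c(base, extra))
    data.frame(trial = seq_len(n_trials),
               run = rep(seq_len(runs), each = n_trials / runs),
               coherence = coh, p_blue = pblue_from_coherence(coh))
  })
}

#' The 11 signed color-coherence levels of the perceptual task
#' @export
coherence_levels <- function() {
  c(-2, -1, -0.5, -0.25, -0.125, 0, 0.125, 0.25, 0.5, 1, 2)
}

#' Probability that a dot is blue given the signed coherence
#'
#' `C = log(p_blue / p_yellow)`, so `p_blue = exp(C) / (1 + exp(C))`.
#' @param C signed color coherence (vectorized).
#' @export
pblue_from_coherence <- function(C) {
  stopifnot(all(is.finite(C)))
  plogis(C)
}

#' Sample the dots of a single stimulus video frame
#'
#' Dot count is Poisson with mean `density * aperture area / frame_rate`;
#' positions are uniform in the circular aperture and each dot is blue with
#' probability `pblue_from_coherence(C)`.
#'
#' @param C signed color coherence.
#' @param aperture_diameter cm (default 5).
#' @param density dots per cm^2 per second (default 16.7).
#' @param frame_rate frames per second (default 60).
#' @param seed optional seed.
#' @return data frame with dot `x`, `y` (cm, aperture centered at 0) and
#'   logical `blue`.
#' @export
sample_dot_frame <- function(C, aperture_diameter = 5, density = 16.7,
                             frame_rate = 60, seed = NULL) {
  stopifnot(aperture_diameter > 0, density > 0, frame_rate > 0)
  draw <- function() {
    r_ap <- aperture_diameter / 2
    lambda <- density * pi * r_ap^2 / frame_rate
    n <- stats::rpois(1, lambda)
    r <- r_ap * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    data.frame(x = r * cos(th), y = r * sin(th),
               blue = runif(n) < pblue_from_coherence(C))
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Simulate diffusion trials by Euler-Maruyama
#'
#' Forward-simulates `dx = mu*dt + N(0, dt)` from x = 0 in small time steps
#' until a (collapsing) bound is crossed, then adds a truncated-Gaussian
#' non-decision time.  This path-level simulator shares no code with the
#' Fokker-Planck density solver and serves as its independent Monte-Carlo
#' oracle.  Trials that do not cross a bound in time, or whose RT exceeds
#' the deadline, are invalid.
#'
#' @param strength signed stimulus strength per trial (vectorized).
#' @param params a [ddm_params()].
#' @param deadline response deadline (s).
#' @param dt simulation step (s); default 0.1 ms, finer than the solver
#'   grid so that discretization bias is negligible in oracle comparisons.
#' @param seed optional seed.
#' @return data frame with `strength`, `choice` (1 upper/right/blue, 0
#'   lower, NA none), `decision_time`, `rt`, `valid`.
#' @export
simulate_ddm_trials <- function(strength, params, deadline = 3,
                                dt = 1e-4, seed = NULL) {
  run <- function() {
    n <- length(strength)
    choice <- integer(n); dec <- numeric(n); rt <- numeric(n)
    valid <- logical(n)
    for (u in unique(strength)) {
      j <- which(strength == u)
      mu <- drift_rate(u, params)
      sim <- cpp_em_simulate(length(j), mu, params$B0, params$Bdel,
                             params$B2, params$tnd, params$sigma_tnd,
                             dt, deadline)
      choice[j] <- sim$choice; dec[j] <- sim$decision_time
      rt[j] <- sim$rt; valid[j] <- sim$valid
    }
    data.frame(strength = strength, choice = choice, decision_time = dec,
               rt = rt, valid = valid)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Simulate trials from the heuristic model
#'
#' Trivial pairs choose the rule-forced side with probability `p_trivial`
#' and draw RT from the fast Gaussian; non-trivial pairs choose by the
#' logistic in ΔValue and draw from the slow Gaussian.  RT draws are
#' truncated at zero.
#'
#' @param value_left,value_right per-trial item values.
#' @param params a [heuristic_params()].
#' @param deadline response deadline (s); slower trials are invalid.
#' @param seed optional seed.
#' @return data frame with `chose_right`, `rt`, `valid`, `class`.
#' @export
simulate_heuristic_trials <- function(value_left, value_right, params,
                                      deadline = Inf, seed = NULL) {
  run <- function() {
    cls <- trial_class(classify_value(value_left, params),
                       classify_value(value_right, params))
    trivial <- cls$class == "trivial"
    n <- length(value_left)
    p_right <- ifelse(trivial,
                      ifelse(cls$forced_right == 1, params$p_trivial,
                             1 - params$p_trivial),
                      choice_prob_nontrivial(value_right - value_left,
                                             params))
    chose_right <- as.integer(runif(n) < p_right)
    mu <- ifelse(trivial, params$mu_fast, params$mu_slow)
    sig <- ifelse(trivial, params$sigma_fast, params$sigma_slow)
    rt <- rnorm(n, mu, sig)
    while (any(rt < 0)) { # truncate at zero by redraw
      bad <- rt < 0
      rt[bad] <- rnorm(sum(bad), mu[bad], sig[bad])
    }
    data.frame(chose_right = chose_right, rt = rt, valid = rt <= deadline,
               class = cls$class)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Specification of a synthetic cohort
#'
#' A cohort is a list of groups, each with a label, a number of
#' participants, a generating model (`"ddm"` or `"heuristic"`) with its
#' parameters, a value distribution (`"wtp"`: dollars uniform on 0-3
#' rounded to cents; `"rating"`: integer 0-10 ratings, z-scored within
#' participant) and a response deadline.
#'
#' @param label group label (e.g. "healthy", "amnesic").
#' @param n_participants participants in the group.
#' @param model `"ddm"` or `"heuristic"`.
#' @param params [ddm_params()] or [heuristic_params()] for the group.
#' @param value_dist `"wtp"` or `"rating"`.
#' @param deadline response deadline (s).
#' @export
cohort_group <- function(label, n_participants, model = "ddm",
                         params = NULL, value_dist = "rating",
                         deadline = 3.5) {
  stopifnot(n_participants >= 1, model %in% c("ddm", "heuristic"),
            value_dist %in% c("wtp", "rating"))
  list(label = label, n_participants = n_participants, model = model,
       params = params, value_dist = value_dist, deadline = deadline)
}

#' @rdname cohort_group
#' @param groups list of [cohort_group()]s.
#' @param seed integer master seed for the whole cohort.
#' @export
cohort_spec <- function(groups, seed = 1) {
  stopifnot(length(groups) >= 1)
  structure(list(groups = groups, seed = seed), class = "cohort_spec")
}

#' Default two-group cohort: intact vs impaired deliberation
#'
#' Fourteen "healthy" and six "amnesic" diffusion agents on the z-scored
#' rating scale with a 3.5 s deadline, mirroring the group sizes of a
#' patient-versus-control comparison.  The impaired group has a shallower
#' drift scale (more stochastic choices), a higher and later-collapsing
#' bound, and a longer non-decision time (slower responses), so its
#' efficiency index (accuracy / RT) is configured to be markedly lower.
#' @export
default_cohort_spec <- function(seed = 1) {
  healthy <- ddm_params(kappa = 2.0, B0 = 1.2, Bdel = 0.4, B2 = 1.5,
                        tnd = 0.45, sigma_tnd = 0.08, mu0 = 0, plaw = 1)
  amnesic <- ddm_params(kappa = 0.8, B0 = 1.4, Bdel = 0.8, B2 = 3,
                        tnd = 0.8, sigma_tnd = 0.12, mu0 = 0, plaw = 1)
  cohort_spec(list(
    cohort_group("healthy", 14, "ddm", healthy, "rating", 3.5),
    cohort_group("amnesic", 6, "ddm", amnesic, "rating", 3.5)),
    seed = seed)
}

#' Synthesize a full cohort of value and perceptual trial tables
#'
#' For each participant: item values are drawn from the group's value
#' distribution, a value design and a perceptual design are generated, and
#' choice/RT behavior is simulated from the group's generating model.  The
#' returned tables round-trip through the package's CSV readers/writers.
#'
#' @param spec a [cohort_spec()].
#' @param sim_dt Euler-Maruyama step for behavior synthesis (coarser than
#'   the oracle default for speed; 1 ms is adequate for data generation).
#' @param perceptual generate the perceptual table too (default TRUE).
#' @return list with `value` and (optionally) `perceptual` trial tables
#'   (with `group` columns) and `truth`, the per-group generating
#'   parameters.
#' @export
synthesize_cohort <- function(spec, sim_dt = 1e-3, perceptual = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  vt <- list(); pt <- list()
  sub_i <- 0L
  .with_seed(spec$seed, {
    for (g in spec$groups) {
      for (k in seq_len(g$n_participants)) {
        sub_i <- sub_i + 1L
        sid <- sprintf("%s%02d", g$label, k)
        dseed <- sample.int(2^31 - 2, 1)
        if (g$value_dist == "wtp") {
          vals <- round(runif(60, 0, 3), 2)
        } else {
          vals <- as.numeric(sample(0:10, 60, replace = TRUE))
          vals <- (vals - mean(vals)) / sd(vals)
        }
        des <- generate_value_design(vals, seed = dseed)
        tr <- des$trials
        if (g$model == "ddm") {
          beh <- simulate_ddm_trials(tr$value_right - tr$value_left,
                                     g$params, deadline = g$deadline,
                                     dt = sim_dt)
          chose <- beh$choice
        } else {
          beh <- simulate_heuristic_trials(tr$value_left, tr$value_right,
                                           g$params, deadline = g$deadline)
          chose <- beh$chose_right
        }
        vt[[sub_i]] <- data.frame(subject = sid, group = g$label,
                                  value_left = tr$value_left,
                                  value_right = tr$value_right,
                                  item_left = tr$item_left,
                                  item_right = tr$item_right,
                                  chose_right = chose, rt = beh$rt,
                                  valid = beh$valid)
        if (perceptual) {
          pdes <- generate_perceptual_design(seed = dseed + 1)
          if (g$model == "ddm") {
            pbeh <- simulate_ddm_trials(pdes$coherence, g$params,
                                        deadline = g$deadline, dt = sim_dt)
            pchose <- pbeh$choice
          } else {
            # heuristic agents still need perceptual behavior; reuse the
            # logistic choice rule on coherence with slow RTs
            pp <- plogis(g$params$beta1 * pdes$coherence)
            pchose <- as.integer(runif(210) < pp)
            pbeh <- data.frame(rt = abs(rnorm(210, g$params$mu_slow,
                                              g$params$sigma_slow)))
            pbeh$valid <- pbeh$rt <= g$deadline
          }
          pt[[sub_i]] <- data.frame(subject = sid, group = g$label,
                                    coherence = pdes$coherence,
                                    chose_blue = pchose, rt = pbeh$rt,
                                    button_order = 1L + (sub_i %% 2L),
                                    valid = pbeh$valid)
        }
      }
    }
  })
  v <- do.call(rbind, vt)
  value <- value_trials(subject = v$subject, value_left = v$value_left,
                        value_right = v$value_right,
                        chose_right = ifelse(v$valid, v$chose_right, NA),
                        rt = ifelse(v$valid, v$rt, NA), valid = v$valid,
                        group = v$group, item_left = v$item_left,
                        item_right = v$item_right, experiment = "exp2",
                        deadline = spec$groups[[1]]$deadline)
  out <- list(value = value,
              truth = lapply(spec$groups, function(g)
                list(label = g$label, model = g$model, params = g$params)))
  if (perceptual) {
    p <- do.call(rbind, pt)
    out$perceptual <- perceptual_trials(
      subject = p$subject, coherence = p$coherence,
      chose_blue = ifelse(p$valid, p$chose_blue, NA),
      rt = ifelse(p$valid, p$rt, NA), button_order = p$button_order,
      valid = p$valid, group = p$group, experiment = "exp2",
      deadline = spec$groups[[1]]$deadline)
  }
  out
}
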