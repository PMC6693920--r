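# Multi-start Nelder-Mead over box constraints.  The box is enforced by a
# logistic coordinate transform so the simplex search itself is
# unconstrained.  All starts run with a capped iteration budget; the best
# few are refined by repeated NM restarts (a fresh simplex at the incumbent
# rescues the search from premature simplex collapse in curved valleys),
# stopping when a restart no longer improves the objective materially.
# Fully reproducible given the seed.
.multistart_nm <- function(fn, low, high, n_starts = 20, seed = 1,
                           maxit = 300, refine_top = 3, refine_maxit = 800,
                           refine_restarts = 5, refine_tol = 0.05) {
  stopifnot(length(low) == length(high), all(low < high), n_starts >= 1)
  nm <- names(low)
  to_theta <- function(z) setNames(low + (high - low) * plogis(z), nm)
  to_z <- function(th) qlogis(pmin(pmax((th - low) / (high - low),
                                        1e-6), 1 - 1e-6))
  obj <- function(z) {
    v <- tryCatch(fn(to_theta(z)), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- matrix(runif(n_starts * length(low), rep(low, each = n_starts),
                         rep(high, each = n_starts)), nrow = n_starts)
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fits[[i]] <- optim(to_z(starts[i, ]), obj, method = "Nelder-Mead",
                       control = list(maxit = maxit))
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  top <- order(vals)[seq_len(min(refine_top, n_starts))]
  for (i in top) {
    z <- fits[[i]]$par
    v_prev <- fits[[i]]$value
    for (r in seq_len(refine_restarts)) {
      o <- optim(z, obj, method = "Nelder-Mead",
                 control = list(maxit = refine_maxit, reltol = 1e-10))
      z <- o$par
      improved <- v_prev - o$value
      v_prev <- o$value
      if (improved < refine_tol) break
    }
    fits[[i]] <- list(par = z, value = v_prev)
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- which.min(vals)
  list(par = to_theta(fits[[best]]$par), value = vals[best],
       start_values = vals, n_starts = n_starts, seed = seed)
}

#' Configuration for maximum-likelihood DDM fitting
#'
#' Parameter bounds default to a box with generous margin around typical
#' best-fit values for this model class: kappa (0, 40], B0 [0.2, 5],
#' Bdel [0, 3], B2 (0.01, 10], tnd [0.1, 1], sigma_tnd [0.001, 0.5],
#' mu0 [-5, 5], plaw [0.1, 3].  Random starting points are drawn uniformly
#' within the box.  The fitting solver grid defaults to a coarser time step
#' (2 ms) than the high-accuracy default; the grid-refinement invariant of
#' the solver justifies this at likelihood scale.
#'
#' @param n_starts number of random starting points (the reference
#'   procedure used 100; fewer are adequate at desk scale).
#' @param seed RNG seed controlling the starting points.
#' @param variant `"full"` (8 free parameters), `"no_plaw"` (plaw fixed at
#'   1), or `"no_plaw_flat_bounds"` (additionally no bound collapse).
#' @param bounds named list with `low`/`high` numeric vectors over the 8
#'   parameters.
#' @param grid a [solver_grid()] used during fitting.
#' @param maxit,refine_top,refine_maxit,refine_restarts Nelder-Mead
#'   iteration budget per start; the number of best starts refined; the
#'   iteration budget and maximum number of simplex restarts per
#'   refinement.
#' @param round_to optional ΔValue rounding step passed to the likelihood.
#' @export
fit_config <- function(n_starts = 100, seed = 1,
                       variant = c("full", "no_plaw",
                                   "no_plaw_flat_bounds"),
                       bounds = ddm_bounds(), grid = NULL,
                       maxit = 300, refine_top = 3, refine_maxit = 800,
                       refine_restarts = 5, round_to = NULL) {
  variant <- match.arg(variant)
  stopifnot(n_starts >= 1, all(bounds$low < bounds$high))
  structure(list(n_starts = n_starts, seed = seed, variant = variant,
                 bounds = bounds, grid = grid, maxit = maxit,
                 refine_top = refine_top, refine_maxit = refine_maxit,
                 refine_restarts = refine_restarts, round_to = round_to),
            class = "fit_config")
}

#' @rdname fit_config
#' @export
ddm_bounds <- function() {
  list(low = c(kappa = 0.01, B0 = 0.2, Bdel = 0, B2 = 0.01, tnd = 0.1,
               sigma_tnd = 0.001, mu0 = -5, plaw = 0.1),
       high = c(kappa = 40, B0 = 5, Bdel = 3, B2 = 10, tnd = 1.0,
                sigma_tnd = 0.5, mu0 = 5, plaw = 3))
}

#' Container for a model fit
#'
#' Carries the fitted parameters, the negative log-likelihood, the trial
#' and parameter counts, `BIC = 2*nll + n_params*log(n_trials)`, the
#' McFadden pseudo-R^2 for choices and the R^2 for per-level mean RT.
#'
#' @param params fitted [ddm_params()] or [heuristic_params()].
#' @param nll negative log-likelihood at the optimum.
#' @param n_trials,n_params counts entering the BIC.
#' @param r2_choice,r2_rt goodness-of-fit statistics (may be NA).
#' @param model label.
#' @param opt optimizer details.
#' @export
fit_result <- function(params, nll, n_trials, n_params, r2_choice = NA,
                       r2_rt = NA, model = "ddm", opt = NULL) {
  structure(list(params = params, nll = nll, n_trials = n_trials,
                 n_params = n_params,
                 bic = 2 * nll + n_params * log(n_trials),
                 r2_choice = r2_choice, r2_rt = r2_rt, model = model,
                 opt = opt),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: NLL = %.2f, n = %d, k = %d, BIC = %.2f\n",
              x$model, x$nll, x$n_trials, x$n_params, x$bic))
  cat(sprintf("  R2 choices = %s, R2 RT = %s\n",
              format(x$r2_choice, digits = 4),
              format(x$r2_rt, digits = 4)))
  print(unlist(x$params))
  invisible(x)
}

#' Fit the bounded drift-diffusion model by multi-start Nelder-Mead
#'
#' Minimizes the joint choice/RT negative log-likelihood over the box in
#' `config$bounds`, taking the best of `n_starts` local optima.  The
#' `no_plaw` variant fixes `plaw = 1`; `no_plaw_flat_bounds` additionally
#' disables the bound collapse (the bound stays at `B0` over the whole
#' horizon), leaving 5 free parameters.
#'
#' @param trials a trial table with at least two distinct strength levels.
#' @param config a [fit_config()].
#' @return a [fit_result()].
#' @export
fit_ddm <- function(trials, config = fit_config()) {
  keep <- trials$valid
  s <- trial_strength(trials, config$round_to)[keep]
  ch <- trial_choice(trials)[keep]
  rt <- trials$rt[keep]
  if (length(unique(s)) < 2) stop("need >= 2 distinct strength levels")
  deadline <- attr(trials, "deadline")
  grid <- config$grid
  if (is.null(grid))
    grid <- solver_grid(dt = 2.5e-3, t_max = deadline + 0.4, n_points = 96)

  su <- sort(unique(s))
  idx <- lapply(su, function(u) which(s == u))
  floor_d <- 1e-10

  free <- switch(config$variant,
    full = c("kappa", "B0", "Bdel", "B2", "tnd", "sigma_tnd", "mu0",
             "plaw"),
    no_plaw = c("kappa", "B0", "Bdel", "B2", "tnd", "sigma_tnd", "mu0"),
    no_plaw_flat_bounds = c("kappa", "B0", "tnd", "sigma_tnd", "mu0"))
  fixed <- list(plaw = 1)
  if (config$variant == "no_plaw_flat_bounds") {
    # collapse pushed past the horizon: flat bound at B0 throughout
    fixed$Bdel <- grid$t_max + 1
    fixed$B2 <- 1
  }

  to_params <- function(th) {
    a <- as.list(th)
    for (nm in setdiff(names(fixed), names(a))) a[[nm]] <- fixed[[nm]]
    ddm_params(kappa = a$kappa, B0 = a$B0, Bdel = a$Bdel, B2 = a$B2,
               tnd = a$tnd, sigma_tnd = a$sigma_tnd, mu0 = a$mu0,
               plaw = a$plaw)
  }

  nll_fn <- function(th) {
    p <- to_params(th)
    total <- 0
    for (i in seq_along(su)) {
      dens <- apply_nondecision(solve_first_passage(su[i], p, grid), p)
      j <- idx[[i]]
      du <- approx(dens$times, dens$d_upper, xout = rt[j], rule = 2)$y
      dl <- approx(dens$times, dens$d_lower, xout = rt[j], rule = 2)$y
      d <- ifelse(ch[j] == 1, du, dl)
      total <- total - sum(log(pmax(d, floor_d)))
    }
    total
  }

  opt <- .multistart_nm(nll_fn, config$bounds$low[free],
                        config$bounds$high[free],
                        n_starts = config$n_starts, seed = config$seed,
                        maxit = config$maxit,
                        refine_top = config$refine_top,
                        refine_maxit = config$refine_maxit,
                        refine_restarts = config$refine_restarts)
  if (!is.finite(opt$value) || opt$value >= 1e10)
    stop("optimization failed: no start reached a finite likelihood; ",
         "start values: ", paste(signif(opt$start_values, 4),
                                 collapse = ", "))
  params <- to_params(opt$par)

  pred <- ddm_predict(params = params, grid = grid, strengths = su)
  p_trial <- pred$p_upper[match(s, su)]
  r2c <- tryCatch(mcfadden_r2(ch, p_trial), error = function(e) NA_real_)
  obs_rt <- vapply(idx, function(j) mean(rt[j]), numeric(1))
  r2r <- tryCatch(rt_r2(obs_rt, pred$mean_rt), error = function(e) NA_real_)

  fit_result(params = params, nll = opt$value, n_trials = length(s),
             n_params = length(free), r2_choice = r2c, r2_rt = r2r,
             model = paste0("ddm_", config$variant), opt = opt)
}

#' Bin ΔValue into a fixed number of levels
#'
#' Bin edges are fixed (not quantile-based): the 11 target levels are the
#' signed coherence levels `{-2, ..., 2}` scaled to the observed ΔValue
#' range, and the edges sit at the midpoints between consecutive targets
#' (outermost bins are open).  Trials exactly on an edge fall in the upper
#' bin.  Each retained level is represented by the mean ΔValue of its
#' members; empty levels are dropped with a warning.  The returned trial
#' table has its values replaced so that the trial strength equals the
#' level representative, which matches the discrete-level structure of the
#' perceptual task.
#'
#' @param trials a value trial table.
#' @param n_levels number of levels (default 11).
#' @return list with `trials` (binned trial table) and `levels` (data
#'   frame: level, strength, n).
#' @export
bin_delta_value <- function(trials, n_levels = 11) {
  stopifnot(attr(trials, "task") == "value")
  dv <- compute_delta_value(trials$value_left, trials$value_right)
  coh <- c(-2, -1, -0.5, -0.25, -0.125, 0, 0.125, 0.25, 0.5, 1, 2)
  if (n_levels == 11) targets <- coh * max(abs(dv)) / 2
  else targets <- seq(-max(abs(dv)), max(abs(dv)), length.out = n_levels)
  edges <- (targets[-1] + targets[-n_levels]) / 2
  lev <- findInterval(dv, edges) + 1L  # x == edge goes to the upper bin
  rep_dv <- tapply(dv, factor(lev, levels = seq_len(n_levels)), mean)
  if (anyNA(rep_dv)) {
    warning(sprintf("%d empty bin(s) dropped", sum(is.na(rep_dv))))
  }
  out <- trials
  out$value_left <- 0
  out$value_right <- as.numeric(rep_dv[lev])
  levels_df <- data.frame(level = seq_len(n_levels),
                          strength = as.numeric(rep_dv),
                          n = as.integer(table(factor(lev,
                                                      levels = seq_len(n_levels)))))
  levels_df <- levels_df[!is.na(levels_df$strength), ]
  list(trials = out, levels = levels_df)
}

#' BIC difference between two fits of the same data
#'
#' `bic_compare(a, b)` returns `BIC(b) - BIC(a)`; positive values favor
#' model `a`.  When the two models have the same number of parameters this
#' equals the deviance difference `2 * (nll_b - nll_a)`.
#'
#' @param result_a,result_b [fit_result()]s fit to the same trials.
#' @export
bic_compare <- function(result_a, result_b) {
  if (result_a$n_trials != result_b$n_trials)
    stop("fits are not on the same number of trials")
  result_b$bic - result_a$bic
}

#' McFadden pseudo-R^2 for binary choices
#'
#' `1 - LL_model / LL_null`, where the null model is the intercept-only
#' Bernoulli fit (constant probability = observed choice rate).
#'
#' @param choices observed 0/1 choices.
#' @param probs fitted probability of choice = 1, per trial, in (0, 1).
#' @export
mcfadden_r2 <- function(choices, probs) {
  stopifnot(length(choices) == length(probs),
            all(probs > 0), all(probs < 1))
  p0 <- mean(choices)
  if (p0 == 0 || p0 == 1)
    stop("degenerate null model: all choices identical")
  ll_model <- sum(ifelse(choices == 1, log(probs), log(1 - probs)))
  ll_null <- sum(ifelse(choices == 1, log(p0), log(1 - p0)))
  1 - ll_model / ll_null
}

#' R^2 for per-level mean reaction times
#'
#' `1 - SS_res / SS_tot` over the per-level observed mean RTs against the
#' model-predicted means.
#'
#' @param observed,predicted per-level mean RTs (same length).
#' @export
rt_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("zero total variance in observed mean RTs")
  1 - sum((observed - predicted)^2) / ss_tot
}
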