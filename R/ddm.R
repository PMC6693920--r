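#' Parameters of the bounded drift-diffusion model
#'
#' The decision variable accumulates evidence `dx = mu*dt + N(0, dt)` from
#' x = 0 (unit diffusion: all evidence units are defined relative to the
#' diffusion coefficient).  Drift depends on signed stimulus strength
#' (ΔValue or coherence) through a power law, `mu = kappa * sign(s) *
#' |s|^plaw + mu0`.  The symmetric bounds stay at `B0` until `Bdel` seconds
#' and then collapse exponentially toward zero with time constant `B2`.
#' RT is decision time plus Gaussian non-decision time (mean `tnd`, sd
#' `sigma_tnd`, truncated at zero).  The upper bound codes a right/blue
#' choice, the lower bound left/yellow.
#'
#' @param kappa drift scale, 1/(evidence-unit^plaw * s); > 0.
#' @param B0 initial bound height (evidence units); > 0.
#' @param Bdel collapse onset delay (s); >= 0.
#' @param B2 collapse time constant (s); > 0.
#' @param tnd mean non-decision time (s); > 0.
#' @param sigma_tnd sd of non-decision time (s); >= 0.
#' @param mu0 drift bias (1/s).
#' @param plaw power-law exponent; > 0.
#' @export
ddm_params <- function(kappa, B0, Bdel = 0, B2 = 1e6, tnd = 0.3,
                       sigma_tnd = 0.05, mu0 = 0, plaw = 1) {
  stopifnot(kappa > 0, B0 > 0, Bdel >= 0, B2 > 0, tnd > 0,
            sigma_tnd >= 0, plaw > 0)
  structure(list(kappa = kappa, B0 = B0, Bdel = Bdel, B2 = B2, tnd = tnd,
                 sigma_tnd = sigma_tnd, mu0 = mu0, plaw = plaw),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params>\n")
  print(unlist(x))
  invisible(x)
}

#' Solver discretization settings
#'
#' Defaults: dt = 0.5 ms; dx chosen per call so that at least 200 points
#' span `[-B0, B0]` but never coarser than needed to resolve the one-step
#' Gaussian kernel (dx <= 0.75 * sqrt(dt)); `t_max` should be the response
#' deadline plus a few non-decision sds.
#'
#' @param dt time step (s).
#' @param t_max time horizon (s).
#' @param dx evidence-space step, or `NA` to choose automatically as
#'   `2 * B0 / n_points` (capped at 0.75 * sqrt(dt) so the one-step kernel
#'   stays resolved).
#' @param n_points minimum number of evidence-grid points spanning
#'   `[-B0, B0]` when `dx` is automatic.
#' @param conservation_tol tolerance on total probability mass.
#' @export
solver_grid <- function(dt = 5e-4, t_max = 3, dx = NA_real_,
                        n_points = 200, conservation_tol = 1e-3) {
  stopifnot(dt > 0, t_max > 0, is.na(dx) || dx > 0, n_points >= 20)
  structure(list(dt = dt, t_max = t_max, dx = dx, n_points = n_points,
                 conservation_tol = conservation_tol),
            class = "solver_grid")
}

.resolve_dx <- function(grid, B0) {
  if (!is.na(grid$dx)) return(grid$dx)
  min(2 * B0 / grid$n_points, 0.75 * sqrt(grid$dt))
}

#' Drift rate from signed stimulus strength
#'
#' `mu = kappa * sign(strength) * |strength|^plaw + mu0`; a strength of 0
#' yields `mu0`.
#' @param strength signed ΔValue or coherence (vectorized).
#' @param params a [ddm_params()].
#' @export
drift_rate <- function(strength, params) {
  params$kappa * sign(strength) * abs(strength)^params$plaw + params$mu0
}

#' Bound height at time t
#'
#' `B(t) = B0` for `t < Bdel`, then `B0 * exp(-(t - Bdel)/B2)`; the bounds
#' are symmetric at `+-B(t)`.
#' @param t time in seconds (vectorized).
#' @param params a [ddm_params()].
#' @export
bound_height <- function(t, params) {
  stopifnot(all(t >= 0))
  ifelse(t < params$Bdel, params$B0,
         params$B0 * exp(-(t - params$Bdel) / params$B2))
}

#' First-passage time densities by Fokker-Planck propagation
#'
#' Numerically propagates the density of the accumulating evidence with a
#' fast convolution scheme (Gaussian transition kernel, absorption at the
#' collapsing bounds each step) and returns the densities of absorption at
#' the upper and lower bound on the time grid, plus the surviving mass at
#' `t_max`.
#'
#' @param strength signed stimulus strength (scalar).
#' @param params a [ddm_params()].
#' @param grid a [solver_grid()].
#' @return a `first_passage` object: `times`, `g_upper`, `g_lower`
#'   (densities, 1/s), `survivor`, `dt`.
#' @export
solve_first_passage <- function(strength, params, grid = solver_grid()) {
  mu <- drift_rate(strength, params)
  dx <- .resolve_dx(grid, params$B0)
  if (dx > sqrt(grid$dt))
    stop(sprintf("solver accuracy: dx = %g is too coarse to resolve the one-step kernel (sd = %g); refine the grid",
                 dx, sqrt(grid$dt)))
  sol <- cpp_fp_solve(mu, params$B0, params$Bdel, params$B2,
                      grid$dt, dx, grid$t_max)
  total <- sol$absorbed + sol$survivor
  if (abs(total - 1) > grid$conservation_tol)
    stop(sprintf("solver accuracy: total mass %.6f deviates from 1 beyond %g; refine the grid",
                 total, grid$conservation_tol))
  structure(list(times = sol$times,
                 g_upper = sol$mass_upper / grid$dt,
                 g_lower = sol$mass_lower / grid$dt,
                 survivor = sol$survivor, dt = grid$dt),
            class = "first_passage")
}

#' @export
print.first_passage <- function(x, ...) {
  cat(sprintf("<first_passage> %d time steps (dt = %.4g s): P(upper) = %.4f, P(lower) = %.4f, survivor = %.4g\n",
              length(x$times), x$dt, sum(x$g_upper) * x$dt,
              sum(x$g_lower) * x$dt, x$survivor))
  invisible(x)
}

#' Probability of absorbing at the upper bound
#'
#' Integral of the upper first-passage density; with `conditional = TRUE`
#' (default) it is normalized by the total absorbed mass, ignoring the
#' survivor (missed trials are modeled separately).
#' @param fp a `first_passage` or `rt_density` object.
#' @param conditional normalize by absorbed mass.
#' @export
fp_choice_prob <- function(fp, conditional = TRUE) {
  up <- sum(if (!is.null(fp$g_upper)) fp$g_upper else fp$d_upper) * fp$dt
  lo <- sum(if (!is.null(fp$g_lower)) fp$g_lower else fp$d_lower) * fp$dt
  if (conditional) up / (up + lo) else up
}

#' Mean absorption (or RT) time implied by the densities
#' @param fp a `first_passage` or `rt_density` object.
#' @export
fp_mean_time <- function(fp) {
  gu <- if (!is.null(fp$g_upper)) fp$g_upper else fp$d_upper
  gl <- if (!is.null(fp$g_lower)) fp$g_lower else fp$d_lower
  g <- gu + gl
  sum(fp$times * g) / sum(g)
}

# Discrete non-decision kernel on the dt grid: Gaussian(tnd, sigma)
# truncated at zero and renormalized.  For sigma below the grid resolution
# the kernel degenerates to a two-bin linear split of a pure shift.
.nd_kernel <- function(tnd, sigma_tnd, dt) {
  if (sigma_tnd < dt / 2) {
    j <- floor(tnd / dt)
    frac <- tnd / dt - j
    w <- numeric(j + 2)
    w[j + 1] <- 1 - frac
    w[j + 2] <- frac
    return(w)
  }
  jmax <- ceiling((tnd + 5 * sigma_tnd) / dt)
  tt <- (0:jmax) * dt
  w <- dnorm(tt, tnd, sigma_tnd)
  w / sum(w)
}

#' Convolve first-passage densities with the non-decision time
#'
#' Each absorption density is convolved with a Gaussian of mean `tnd` and
#' sd `sigma_tnd`, truncated at zero and renormalized.  The time grid is
#' extended so that no mass is lost off the end of the horizon.
#'
#' @param fp a `first_passage` from [solve_first_passage()].
#' @param params a [ddm_params()].
#' @return an `rt_density` object: `times`, `d_upper`, `d_lower`,
#'   `survivor`, `dt`.
#' @export
apply_nondecision <- function(fp, params) {
  dt <- fp$dt
  w <- .nd_kernel(params$tnd, params$sigma_tnd, dt)
  nt <- length(fp$times)
  n_out <- nt + length(w) - 1
  du <- .conv_open(fp$g_upper, w)
  dl <- .conv_open(fp$g_lower, w)
  structure(list(times = (seq_len(n_out)) * dt, d_upper = du, d_lower = dl,
                 survivor = fp$survivor, dt = dt),
            class = "rt_density")
}

.conv_open <- function(x, w) {
  if (length(w) == 1L) return(x * w)
  cpp_conv_open(x, w)
}

#' Joint choice/RT log-likelihood of a single trial
#'
#' The log of the RT density for the chosen bound, interpolated at the
#' observed RT.  Densities below `floor` are clipped (not an error): the
#' floor keeps the simplex search finite in regions of parameter space
#' where an observed RT is essentially impossible.
#'
#' @param strength signed stimulus strength of the trial.
#' @param choice 1 for the upper bound (right/blue), 0 for lower.
#' @param rt observed reaction time (s).
#' @param params a [ddm_params()].
#' @param grid a [solver_grid()].
#' @param floor density floor (1/s).
#' @export
trial_loglik <- function(strength, choice, rt, params,
                         grid = solver_grid(), floor = 1e-10) {
  dens <- apply_nondecision(solve_first_passage(strength, params, grid),
                            params)
  d <- if (choice == 1) dens$d_upper else dens$d_lower
  val <- approx(dens$times, d, xout = rt, rule = 2)$y
  log(max(val, floor))
}

#' Dataset negative log-likelihood under the drift-diffusion model
#'
#' Sums `-trial_loglik` over all valid trials, solving the first-passage
#' problem once per unique stimulus strength.  Survivor mass at the
#' deadline is ignored (missed trials are excluded, not renormalized over).
#'
#' @param trials a trial table.
#' @param params a [ddm_params()].
#' @param grid a [solver_grid()].
#' @param round_to optional ΔValue rounding step (dollar-scale data).
#' @param floor per-trial density floor.
#' @export
ddm_nll <- function(trials, params, grid = solver_grid(), round_to = NULL,
                    floor = 1e-10) {
  keep <- trials$valid
  s <- trial_strength(trials, round_to)[keep]
  ch <- trial_choice(trials)[keep]
  rt <- trials$rt[keep]
  nll <- 0
  for (u in unique(s)) {
    idx <- s == u
    dens <- apply_nondecision(solve_first_passage(u, params, grid), params)
    lu <- log(pmax(approx(dens$times, dens$d_upper, xout = rt[idx],
                          rule = 2)$y, floor))
    ll <- log(pmax(approx(dens$times, dens$d_lower, xout = rt[idx],
                          rule = 2)$y, floor))
    nll <- nll - sum(ifelse(ch[idx] == 1, lu, ll))
  }
  nll
}

#' Model-predicted choice probability and mean RT per strength
#'
#' One row per unique strength with the probability of an upper-bound
#' (right/blue) choice and the mean RT implied by the model, used for
#' psychometric/chronometric overlays and goodness-of-fit.
#' @inheritParams ddm_nll
#' @param strengths strengths at which to predict (defaults to the unique
#'   strengths in `trials`).
#' @export
ddm_predict <- function(trials = NULL, params, grid = solver_grid(),
                        strengths = NULL, round_to = NULL) {
  if (is.null(strengths)) {
    stopifnot(!is.null(trials))
    strengths <- sort(unique(trial_strength(trials, round_to)[trials$valid]))
  }
  out <- lapply(strengths, function(u) {
    dens <- apply_nondecision(solve_first_passage(u, params, grid), params)
    data.frame(strength = u, p_upper = fp_choice_prob(dens),
               mean_rt = fp_mean_time(dens))
  })
  do.call(rbind, out)
}
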