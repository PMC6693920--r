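#' Parameters of the rule-based (heuristic) choice model
#'
#' Items are classified by two criteria into highly undesirable (`D-`,
#' value < `kappa1`), highly desirable (`D+`, value > `kappa2`) or middling
#' (`D~`, in between; boundary values inclusive to `D~`).  Decisions where
#' the rules force a side (a `D+` item against anything else; `D~` against
#' `D-`) are *trivial*: fast, with the forced side chosen with probability
#' `p_trivial`.  Same-category decisions are *non-trivial*: slow, with the
#' right item chosen with probability `logistic(beta0 + beta1 * ΔValue)`.
#' Trivial RTs are Gaussian with mean `mu_fast`, sd `sigma_fast`;
#' non-trivial RTs use the slow Gaussian.
#'
#' @param kappa1,kappa2 category criteria, `kappa1 <= kappa2` (value units).
#' @param mu_fast,sigma_fast fast-RT Gaussian (s).
#' @param mu_slow,sigma_slow slow-RT Gaussian (s).
#' @param beta0,beta1 logistic intercept/slope for non-trivial choices.
#' @param p_trivial probability of the rule-consistent trivial choice
#'   (fixed at 0.99, or free in the trembling-hand variant).
#' @export
heuristic_params <- function(kappa1, kappa2, mu_fast, sigma_fast,
                             mu_slow, sigma_slow, beta0, beta1,
                             p_trivial = 0.99) {
  stopifnot(kappa1 <= kappa2, sigma_fast > 0, sigma_slow > 0,
            p_trivial > 0.5, p_trivial < 1)
  structure(list(kappa1 = kappa1, kappa2 = kappa2, mu_fast = mu_fast,
                 sigma_fast = sigma_fast, mu_slow = mu_slow,
                 sigma_slow = sigma_slow, beta0 = beta0, beta1 = beta1,
                 p_trivial = p_trivial),
            class = "heuristic_params")
}

#' @export
print.heuristic_params <- function(x, ...) {
  cat("<heuristic_params>\n")
  print(unlist(x))
  invisible(x)
}

#' Desirability category of an item value
#'
#' @param v item value(s).
#' @param params a [heuristic_params()].
#' @return character vector in `{"D_minus", "D_mid", "D_plus"}`.
#' @export
classify_value <- function(v, params) {
  ifelse(v < params$kappa1, "D_minus",
         ifelse(v > params$kappa2, "D_plus", "D_mid"))
}

#' Trivial / non-trivial classification of a pair of item categories
#'
#' A pair is trivial when the rules force a side: a `D_plus` item beats any
#' other category, and `D_mid` beats `D_minus`.  Same-category pairs are
#' non-trivial.
#'
#' @param left_cat,right_cat categories from [classify_value()]
#'   (vectorized).
#' @return data frame with `class` (`"trivial"`/`"non_trivial"`) and
#'   `forced_right` (1 if the rule forces the right item, 0 left, NA for
#'   non-trivial pairs).
#' @export
trial_class <- function(left_cat, right_cat) {
  rank <- c(D_minus = 1, D_mid = 2, D_plus = 3)
  rl <- rank[left_cat]
  rr <- rank[right_cat]
  trivial <- rl != rr
  data.frame(class = ifelse(trivial, "trivial", "non_trivial"),
             forced_right = ifelse(trivial, as.numeric(rr > rl), NA_real_),
             row.names = NULL)
}

#' Logistic choice probability for a non-trivial trial
#'
#' @param delta_value signed value difference (right minus left).
#' @param params a [heuristic_params()].
#' @return probability of choosing the right item.
#' @export
choice_prob_nontrivial <- function(delta_value, params) {
  plogis(params$beta0 + params$beta1 * delta_value)
}

#' Number of free parameters of a heuristic-model variant
#'
#' The fixed-p variant has 8 free parameters (equal to the diffusion
#' model, so BIC comparison reduces to a deviance comparison); the
#' trembling-hand variant frees `p_trivial` for 9.
#' @param variant `"fixed"` or `"trembling"`.
#' @export
heuristic_n_params <- function(variant = c("fixed", "trembling")) {
  switch(match.arg(variant), fixed = 8L, trembling = 9L)
}

#' Negative log-likelihood of the heuristic model
#'
#' Per valid trial: a Gaussian RT term (fast for trivial, slow for
#' non-trivial trials, untruncated) plus a Bernoulli choice term.  In
#' `fit` mode, trivial choices consistent with the rule get probability
#' `p_trivial` and exceptions `1 - p_trivial`.  In `bic_eval` mode (used
#' for model-comparison statistics) the trivial-choice probability is
#' instead taken from the fitted logistic evaluated at the maximum
#' `|ΔValue|` in the dataset.
#'
#' @param trials a value trial table.
#' @param params a [heuristic_params()].
#' @param mode `"fit"` or `"bic_eval"`.
#' @export
heuristic_nll <- function(trials, params, mode = c("fit", "bic_eval")) {
  mode <- match.arg(mode)
  keep <- trials$valid
  if (!any(keep)) stop("no valid trials")
  vl <- trials$value_left[keep]
  vr <- trials$value_right[keep]
  ch <- trials$chose_right[keep]
  rt <- trials$rt[keep]
  dv <- vr - vl
  cls <- trial_class(classify_value(vl, params), classify_value(vr, params))
  trivial <- cls$class == "trivial"

  rt_nll <- -dnorm(rt,
                   mean = ifelse(trivial, params$mu_fast, params$mu_slow),
                   sd = ifelse(trivial, params$sigma_fast,
                               params$sigma_slow), log = TRUE)

  p_triv <- if (mode == "fit") params$p_trivial
            else plogis(params$beta0 + params$beta1 * max(abs(dv)))
  consistent <- ch == cls$forced_right
  choice_nll <- numeric(length(ch))
  choice_nll[trivial] <- -log(ifelse(consistent[trivial], p_triv,
                                     1 - p_triv))
  p_right <- choice_prob_nontrivial(dv[!trivial], params)
  choice_nll[!trivial] <- -log(ifelse(ch[!trivial] == 1, p_right,
                                      1 - p_right))
  sum(rt_nll + choice_nll)
}

#' Fit the heuristic model by multi-start Nelder-Mead
#'
#' Maximizes the joint choice/RT likelihood in `fit` mode.  The criteria
#' are kept ordered by fitting `kappa2` as `kappa1` plus a positive gap.
#' The returned result carries the fit-mode NLL; `heuristic_nll(...,
#' mode = "bic_eval")` gives the penalized likelihood used for model
#' comparison.
#'
#' @param trials a value trial table.
#' @param variant `"fixed"` (p_trivial = 0.99) or `"trembling"`
#'   (p_trivial free).
#' @param n_starts number of random starting points.
#' @param seed RNG seed for the starting points.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return a `fit_result` (see [fit_ddm()]).
#' @export
fit_heuristic <- function(trials, variant = c("fixed", "trembling"),
                          n_starts = 50, seed = 1, maxit = 500) {
  variant <- match.arg(variant)
  keep <- trials$valid
  if (!any(keep)) stop("no valid trials")
  v_all <- c(trials$value_left[keep], trials$value_right[keep])
  rng <- range(v_all)
  span <- diff(rng)
  if (span == 0) stop("degenerate values")
  deadline <- attr(trials, "deadline")

  low <- c(kappa1 = rng[1] - 0.05 * span, gap = 0,
           mu_fast = 0.05, sigma_fast = 0.01,
           mu_slow = 0.05, sigma_slow = 0.01,
           beta0 = -10, beta1 = -30)
  high <- c(kappa1 = rng[2] + 0.05 * span, gap = 1.1 * span,
            mu_fast = deadline, sigma_fast = 2,
            mu_slow = deadline, sigma_slow = 2,
            beta0 = 10, beta1 = 30)
  if (variant == "trembling") {
    low <- c(low, p_trivial = 0.501)
    high <- c(high, p_trivial = 0.999)
  }

  to_params <- function(th) {
    heuristic_params(kappa1 = th[["kappa1"]],
                     kappa2 = th[["kappa1"]] + th[["gap"]],
                     mu_fast = th[["mu_fast"]],
                     sigma_fast = th[["sigma_fast"]],
                     mu_slow = th[["mu_slow"]],
                     sigma_slow = th[["sigma_slow"]],
                     beta0 = th[["beta0"]], beta1 = th[["beta1"]],
                     p_trivial = if (variant == "trembling")
                       th[["p_trivial"]] else 0.99)
  }
  fn <- function(th) heuristic_nll(trials, to_params(th), mode = "fit")
  opt <- .multistart_nm(fn, low, high, n_starts = n_starts, seed = seed,
                        maxit = maxit)
  params <- to_params(opt$par)

  dv <- trials$value_right[keep] - trials$value_left[keep]
  cls <- trial_class(classify_value(trials$value_left[keep], params),
                     classify_value(trials$value_right[keep], params))
  p_right <- ifelse(cls$class == "trivial",
                    ifelse(cls$forced_right == 1, params$p_trivial,
                           1 - params$p_trivial),
                    choice_prob_nontrivial(dv, params))
  r2c <- tryCatch(mcfadden_r2(trials$chose_right[keep], p_right),
                  error = function(e) NA_real_)
  fit_result(params = params, nll = opt$value, n_trials = sum(keep),
             n_params = heuristic_n_params(variant),
             r2_choice = r2c, r2_rt = NA_real_,
             model = paste0("heuristic_", variant), opt = opt)
}
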