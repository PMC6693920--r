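#' Per-trial consistency / accuracy score
#'
#' Value trials score 1 when the chosen item has the strictly higher value,
#' 0 when lower, and 0.5 for exact value ties (parallel to the zero-
#' coherence rule).  Perceptual trials score 1 when the choice matches the
#' sign of the coherence, 0 otherwise, and 0.5 for zero coherence
#' regardless of the choice.
#'
#' @param trials a trial table.
#' @return numeric vector of scores in `{0, 0.5, 1}` (NA for invalid
#'   trials).
#' @export
score_trials <- function(trials) {
  if (attr(trials, "task") == "value") {
    dv <- trials$value_right - trials$value_left
    sc <- ifelse(dv == 0, 0.5,
                 as.numeric((dv > 0) == (trials$chose_right == 1)))
  } else {
    C <- trials$coherence
    sc <- ifelse(C == 0, 0.5,
                 as.numeric((C > 0) == (trials$chose_blue == 1)))
  }
  sc[!trials$valid] <- NA_real_
  sc
}

#' Psychometric / chronometric summaries per strength level
#'
#' One row per level: the proportion of upper-bound (right/blue) choices,
#' the mean RT and its standard error (sample sd / sqrt(n)).  Perceptual
#' tables are grouped by their discrete coherences; value tables are first
#' binned into `n_levels` ΔValue levels with [bin_delta_value()].
#'
#' @param trials a trial table.
#' @param n_levels number of ΔValue levels for value tables.
#' @return data frame with `strength`, `p_choice`, `mean_rt`, `sem_rt`,
#'   `n`.
#' @export
summarize_levels <- function(trials, n_levels = 11) {
  if (attr(trials, "task") == "value")
    trials <- bin_delta_value(trials, n_levels)$trials
  keep <- trials$valid
  s <- trial_strength(trials)[keep]
  ch <- trial_choice(trials)[keep]
  rt <- trials$rt[keep]
  su <- sort(unique(s))
  out <- lapply(su, function(u) {
    j <- s == u
    data.frame(strength = u, p_choice = mean(ch[j]),
               mean_rt = mean(rt[j]),
               sem_rt = if (sum(j) > 1) sd(rt[j]) / sqrt(sum(j))
                        else NA_real_,
               n = sum(j))
  })
  do.call(rbind, out)
}

#' Per-participant efficiency index
#'
#' `i_e = accuracy / mean RT` per subject, over valid trials only:
#' a participant who deliberates longer without becoming more consistent
#' has a lower index.  Subjects with no valid trials are excluded with a
#' warning.
#'
#' @param trials a trial table.
#' @return data frame with `subject`, `group` (if present), `accuracy`,
#'   `mean_rt`, `i_e`.
#' @export
efficiency_index <- function(trials) {
  sc <- score_trials(trials)
  keep <- trials$valid
  subs <- unique(trials$subject)
  rows <- lapply(subs, function(sid) {
    j <- keep & trials$subject == sid
    if (!any(j)) return(NULL)
    acc <- mean(sc[j])
    mrt <- mean(trials$rt[j])
    data.frame(subject = sid,
               group = if (!is.null(trials$group))
                 trials$group[which(trials$subject == sid)[1]] else NA,
               accuracy = acc, mean_rt = mrt, i_e = acc / mrt,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d subject(s) with no valid trials excluded", dropped))
  do.call(rbind, rows)
}

#' Welch's unequal-variance two-sample t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Implemented from the formulas (an independent reference implementation
#' is `t.test(..., var.equal = FALSE)`).
#'
#' @param group_a,group_b numeric vectors, each with n >= 2 and positive
#'   variance.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  va <- var(group_a); vb <- var(group_b)
  if (va <= 0 || vb <= 0) stop("degenerate (zero) variance in a group")
  se2a <- va / na; se2b <- vb / nb
  tstat <- (mean(group_a) - mean(group_b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}
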