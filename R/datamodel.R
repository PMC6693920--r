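#' Trial tables for two-alternative decision data
#'
#' A trial table is a data frame of one decision per row, plus metadata:
#' the task kind (`"value"` or `"perceptual"`), an experiment label, and the
#' response deadline in seconds.  Value trials carry the subjective value of
#' the left and right item (dollars of willingness-to-pay, or z-scored
#' ratings) and a binary `chose_right`; perceptual trials carry the signed
#' color coherence `C` (log-odds that a dot is blue), `p_blue = logistic(C)`,
#' a binary `chose_blue`, and the button order (1 means blue maps to the left
#' button).  Rows with a missing or late response are retained with
#' `valid = FALSE` and excluded by downstream likelihoods.
#'
#' @param subject subject identifiers.
#' @param value_left,value_right subjective values of the left/right item.
#' @param chose_right 0/1, whether the right item was chosen.
#' @param rt reaction time in seconds (NA for missed trials).
#' @param valid logical, response given before the deadline.
#' @param group optional group label per trial (e.g. "healthy", "amnesia").
#' @param item_left,item_right optional item identifiers.
#' @param experiment experiment label.
#' @param deadline response deadline in seconds.
#' @return A `trial_table` (data frame subclass) with attributes `task`,
#'   `experiment` and `deadline`.
#' @export
value_trials <- function(subject, value_left, value_right, chose_right, rt,
                         valid = NULL, group = NULL,
                         item_left = NULL, item_right = NULL,
                         experiment = "exp1", deadline = 3.0) {
  n <- length(rt)
  if (is.null(valid)) valid <- !is.na(rt) & !is.na(chose_right)
  rec <- function(x) {
    stopifnot(length(x) %in% c(1L, n))
    rep_len(x, n)
  }
  value_left <- rec(value_left); value_right <- rec(value_right)
  chose_right <- rec(chose_right)
  if (any(valid & (is.na(rt) | rt <= 0)))
    stop("valid trials must have rt > 0")
  if (!all(chose_right[valid] %in% c(0, 1)))
    stop("chose_right must be 0 or 1 on valid trials")
  df <- data.frame(subject = subject, value_left = value_left,
                   value_right = value_right, chose_right = chose_right,
                   rt = rt, valid = valid, stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  if (!is.null(item_left)) df$item_left <- item_left
  if (!is.null(item_right)) df$item_right <- item_right
  new_trial_table(df, task = "value", experiment = experiment,
                  deadline = deadline)
}

#' @rdname value_trials
#' @param coherence signed color coherence `C` (log-odds blue).
#' @param chose_blue 0/1, whether blue was chosen.
#' @param button_order 1 = blue on the left button, 2 = blue on the right.
#' @param p_blue optional; defaults to `plogis(coherence)`.
#' @export
perceptual_trials <- function(subject, coherence, chose_blue, rt,
                              button_order = 1L, p_blue = NULL,
                              valid = NULL, group = NULL,
                              experiment = "exp1", deadline = 2.5) {
  n <- length(rt)
  if (is.null(valid)) valid <- !is.na(rt) & !is.na(chose_blue)
  if (is.null(p_blue)) p_blue <- plogis(coherence)
  stopifnot(length(coherence) == n, length(chose_blue) == n)
  if (any(abs(p_blue - plogis(coherence)) > 1e-9))
    stop("p_blue inconsistent with coherence")
  if (any(valid & (is.na(rt) | rt <= 0)))
    stop("valid trials must have rt > 0")
  df <- data.frame(subject = subject, coherence = coherence,
                   p_blue = p_blue, chose_blue = chose_blue, rt = rt,
                   button_order = as.integer(button_order), valid = valid,
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  new_trial_table(df, task = "perceptual", experiment = experiment,
                  deadline = deadline)
}

new_trial_table <- function(df, task, experiment, deadline) {
  stopifnot(task %in% c("value", "perceptual"), deadline > 0)
  structure(df, task = task, experiment = experiment, deadline = deadline,
            class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> %s task, experiment %s, deadline %.1f s, %d trials (%d valid)\n",
              attr(x, "task"), attr(x, "experiment"), attr(x, "deadline"),
              nrow(x), sum(x$valid)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# column orders of the published trial-level CSV dialects
.dialect_cols <- list(
  value_exp1 = c("subject", "rt", "chose_right", "value_left", "value_right",
                 "item_left", "item_right", "response"),
  value_exp2 = c("subject", "group", "item_left", "item_right", "response",
                 "rt", "rating_left", "rating_right", "chose_right",
                 "z_left", "z_right", "delta_value"),
  perc_exp1 = c("subject", "coherence", "p_blue", "response", "rt",
                "button_order", "chose_blue"),
  perc_exp2 = c("subject", "group", "coherence", "p_blue", "response", "rt",
                "button_order", "chose_blue"))

.parse_numeric <- function(x, what) {
  x <- as.character(x)
  miss <- is.na(x) | x == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!miss & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric %s in row %d: '%s'", what, bad[1], x[bad[1]]))
  out
}

#' Read trial-level CSVs in the published dialects
#'
#' Two dialects exist for each task.  For the value task: `exp1` has 8
#' columns (subject, rt, chose_right, left/right WTP in dollars, left/right
#' item name, raw response key) and `exp2` has 12 (adds group, raw 0-10
#' ratings, their z-scores, and a precomputed delta value; the z-scored
#' columns populate the trial values).  For the perceptual task: `exp1` has
#' 7 columns and `exp2` adds a group column.  Raw response-key codes are
#' discarded in favor of the canonical `chose_right` / `chose_blue` columns.
#'
#' @param path path to a CSV file.
#' @param dialect `"exp1"` or `"exp2"`.
#' @param header whether the file has a header row (the column order is
#'   fixed by the dialect either way).
#' @return a [value_trials()] / [perceptual_trials()] table.
#' @export
read_value_trials <- function(path, dialect = c("exp1", "exp2"),
                              header = TRUE) {
  dialect <- match.arg(dialect)
  cols <- .dialect_cols[[paste0("value_", dialect)]]
  raw <- read.csv(path, header = header, colClasses = "character",
                  stringsAsFactors = FALSE)
  if (ncol(raw) != length(cols))
    stop(sprintf("dialect '%s' expects %d columns, file has %d",
                 dialect, length(cols), ncol(raw)))
  names(raw) <- cols
  rt <- .parse_numeric(raw$rt, "rt")
  chose <- .parse_numeric(raw$chose_right, "chose_right")
  if (dialect == "exp1") {
    vl <- .parse_numeric(raw$value_left, "value_left")
    vr <- .parse_numeric(raw$value_right, "value_right")
    value_trials(subject = raw$subject, value_left = vl, value_right = vr,
                 chose_right = chose, rt = rt,
                 item_left = raw$item_left, item_right = raw$item_right,
                 experiment = "exp1", deadline = 3.0)
  } else {
    vl <- .parse_numeric(raw$z_left, "z_left")
    vr <- .parse_numeric(raw$z_right, "z_right")
    value_trials(subject = raw$subject, value_left = vl, value_right = vr,
                 chose_right = chose, rt = rt, group = raw$group,
                 item_left = raw$item_left, item_right = raw$item_right,
                 experiment = "exp2", deadline = 3.5)
  }
}

#' @rdname read_value_trials
#' @export
read_perceptual_trials <- function(path, dialect = c("exp1", "exp2"),
                                   header = TRUE) {
  dialect <- match.arg(dialect)
  cols <- .dialect_cols[[paste0("perc_", dialect)]]
  raw <- read.csv(path, header = header, colClasses = "character",
                  stringsAsFactors = FALSE)
  if (ncol(raw) != length(cols))
    stop(sprintf("dialect '%s' expects %d columns, file has %d",
                 dialect, length(cols), ncol(raw)))
  names(raw) <- cols
  coh <- .parse_numeric(raw$coherence, "coherence")
  pb <- .parse_numeric(raw$p_blue, "p_blue")
  if (any(abs(pb - plogis(coh)) > 1e-6, na.rm = TRUE))
    warning("p_blue inconsistent with coherence beyond 1e-6; using coherence")
  rt <- .parse_numeric(raw$rt, "rt")
  chose <- .parse_numeric(raw$chose_blue, "chose_blue")
  bo <- .parse_numeric(raw$button_order, "button_order")
  perceptual_trials(subject = raw$subject, coherence = coh,
                    chose_blue = chose, rt = rt, button_order = bo,
                    group = if (dialect == "exp2") raw$group else NULL,
                    experiment = dialect,
                    deadline = if (dialect == "exp1") 2.5 else 3.5)
}

#' Write trial tables back out in the published CSV dialects
#'
#' The inverse of [read_value_trials()] / [read_perceptual_trials()].  Raw
#' response-key codes are reconstructed from the canonical binaries
#' (`'#3'`/`'$4'` left/right keys for exp1, `'z'`/`'m'` for exp2); missed
#' trials are written with an empty response and rt.
#'
#' @param trials a trial table.
#' @param path output path.
#' @inheritParams read_value_trials
#' @export
write_value_trials <- function(trials, path, dialect = c("exp1", "exp2"),
                               header = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(attr(trials, "task") == "value")
  keys <- if (dialect == "exp1") c("#3", "$4") else c("z", "m")
  resp <- ifelse(trials$valid, keys[trials$chose_right + 1L], "")
  il <- if (!is.null(trials$item_left)) trials$item_left else
    paste0("item", seq_len(nrow(trials)) * 2L - 1L)
  ir <- if (!is.null(trials$item_right)) trials$item_right else
    paste0("item", seq_len(nrow(trials)) * 2L)
  out <- if (dialect == "exp1") {
    data.frame(subject = trials$subject, rt = trials$rt,
               chose_right = trials$chose_right,
               value_left = trials$value_left,
               value_right = trials$value_right,
               item_left = il, item_right = ir, response = resp)
  } else {
    grp <- if (!is.null(trials$group)) trials$group else "none"
    data.frame(subject = trials$subject, group = grp,
               item_left = il, item_right = ir, response = resp,
               rt = trials$rt,
               rating_left = if (!is.null(trials$rating_left))
                 trials$rating_left else NA,
               rating_right = if (!is.null(trials$rating_right))
                 trials$rating_right else NA,
               chose_right = trials$chose_right,
               z_left = trials$value_left, z_right = trials$value_right,
               delta_value = trials$value_right - trials$value_left)
  }
  write.table(out, path, sep = ",", row.names = FALSE, col.names = header,
              qmethod = "double")
  invisible(path)
}

#' @rdname write_value_trials
#' @export
write_perceptual_trials <- function(trials, path,
                                    dialect = c("exp1", "exp2"),
                                    header = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(attr(trials, "task") == "perceptual")
  keys <- if (dialect == "exp1") c("#3", "$4") else c("z", "m")
  # button_order 1: blue is the left key; 2: blue is the right key
  left_press <- (trials$chose_blue == 1) == (trials$button_order == 1L)
  resp <- ifelse(trials$valid, ifelse(left_press, keys[1], keys[2]), "")
  out <- data.frame(subject = trials$subject)
  if (dialect == "exp2")
    out$group <- if (!is.null(trials$group)) trials$group else "none"
  out <- cbind(out, data.frame(coherence = trials$coherence,
                               p_blue = trials$p_blue, response = resp,
                               rt = trials$rt,
                               button_order = trials$button_order,
                               chose_blue = trials$chose_blue))
  write.table(out, path, sep = ",", row.names = FALSE, col.names = header,
              qmethod = "double")
  invisible(path)
}

#' Z-score preference ratings within participant
#'
#' Standardizes each participant's ratings to mean 0 and sample (n-1)
#' standard deviation 1.  Participants whose ratings are constant cannot be
#' standardized and raise an error rather than silently producing zeros.
#'
#' @param ratings data frame with columns `subject`, `item`, `rating`.
#' @return the input with a `z_rating` column added.
#' @export
zscore_ratings <- function(ratings) {
  stopifnot(all(c("subject", "rating") %in% names(ratings)))
  z <- ave(ratings$rating, ratings$subject, FUN = function(v) {
    s <- sd(v)
    if (length(v) < 2 || is.na(s) || s == 0)
      stop("cannot z-score constant or singleton ratings for a participant")
    (v - mean(v)) / s
  })
  ratings$z_rating <- z
  ratings
}

#' Signed value difference (right minus left)
#'
#' `delta_value = value_right - value_left`, optionally rounded to the
#' nearest multiple of `round_to` (dollars), rounding halves away from zero.
#' Rounding to $0.1 reduces the number of distinct drift rates when fitting
#' dollar-scale data; it is not applied to z-scored values.
#'
#' @param value_left,value_right item values (vectors or a trial table's
#'   columns).
#' @param round_to step size in value units, or `NULL` for no rounding.
#' @export
compute_delta_value <- function(value_left, value_right, round_to = NULL) {
  dv <- value_right - value_left
  if (!is.null(round_to)) {
    stopifnot(round_to > 0)
    dv <- sign(dv) * floor(abs(dv) / round_to + 0.5) * round_to
  }
  dv
}

#' Per-trial stimulus strength for a trial table
#'
#' ΔValue (right minus left) for value tables, signed coherence for
#' perceptual tables.
#' @param trials a trial table.
#' @param round_to optional rounding step for ΔValue (value tables only).
#' @export
trial_strength <- function(trials, round_to = NULL) {
  if (attr(trials, "task") == "value")
    compute_delta_value(trials$value_left, trials$value_right, round_to)
  else
    trials$coherence
}

#' The side chosen on each trial as an upper/lower-bound indicator
#'
#' 1 when the response corresponds to the upper bound of the diffusion
#' (right item, or blue), 0 for the lower bound.
#' @param trials a trial table.
#' @export
trial_choice <- function(trials) {
  if (attr(trials, "task") == "value") trials$chose_right
  else trials$chose_blue
}
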