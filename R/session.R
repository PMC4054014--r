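new_trial_log <- function(df, condition, observer) {
  attr(df, "condition") <- condition
  attr(df, "observer_label") <- observer$label
  class(df) <- c("trial_log", class(df))
  df
}

#' Run one adaptive 2-IFC session
#'
#' Interleaves four n-down/1-up staircases (two converging on the 70.7%
#' point, two on the 84.1% point), 75 trials each by default, for one
#' stimulus condition and one simulated observer. On every trial a fresh
#' white-noise mask is drawn for each interval and a fresh sample of signal
#' noise (windowed by the contrast envelope) is added to the signal interval,
#' which is balanced-random within each staircase. Per-trial RNG seeds are
#' stored so the stimuli can be replayed exactly (for classification
#' imaging).
#'
#' Draws from the current R RNG stream; seed it for a reproducible session.
#'
#' @param observer A [template_observer].
#' @param condition A [noise_condition].
#' @param n_per_staircase Trials per staircase (75; 300 per condition).
#' @param start_contrast Starting contrast of the 71% staircases; the 84%
#'   staircases start 0.3 log10 units lower. Defaults to 4x the closed-form
#'   threshold estimate (clearly visible), or 0.3 if that is unavailable.
#' @param rules Down-rules of the four staircases.
#' @param step_init,step_final,reversal_switch Staircase step schedule, log10
#'   units.
#' @return A `trial_log` data frame with one row per trial: `trial`,
#'   `condition`, `staircase`, `contrast`, `signal_interval`, `choice`,
#'   `correct`, `seed1`, `seed2`, `seed_sig`. The condition object is
#'   attached as attribute `"condition"`.
#' @export
run_session <- function(observer, condition, n_per_staircase = 75,
                        start_contrast = NULL, rules = c(2, 2, 4, 4),
                        step_init = 0.1, step_final = 0.05,
                        reversal_switch = 2) {
  stopifnot(inherits(observer, "template_observer"),
            inherits(condition, "noise_condition"))
  if (is.null(start_contrast)) {
    start_contrast <- suppressWarnings(
      4 * analytic_threshold(observer, condition))
    if (!is.finite(start_contrast)) start_contrast <- 0.3
    start_contrast <- min(start_contrast, 1)
  }
  k <- length(rules)
  stairs <- lapply(rules, function(r)
    staircase(rule = r,
              start_contrast = if (r <= 2) start_contrast
                               else start_contrast * 10^-0.3,
              step_init = step_init, step_final = step_final,
              reversal_switch = reversal_switch,
              max_trials = n_per_staircase))
  sig_int <- lapply(seq_len(k), function(i)
    sample(rep_len(c(1L, 2L), n_per_staircase)))
  done <- integer(k)
  order_sc <- sample(rep(seq_len(k), each = n_per_staircase))
  n_tot <- k * n_per_staircase
  rec <- data.frame(trial = seq_len(n_tot), condition = condition$label,
                    staircase = 0L, contrast = 0, signal_interval = 0L,
                    choice = 0L, correct = FALSE,
                    seed1 = 0L, seed2 = 0L, seed_sig = 0L)
  for (t in seq_len(n_tot)) {
    sc <- order_sc[t]
    done[sc] <- done[sc] + 1L
    contrast <- staircase_contrast(stairs[[sc]])
    si <- sig_int[[sc]][done[sc]]
    seeds <- sample.int(2147483646L, 3)
    stim <- trial_stimuli(condition, contrast, si, seeds)
    choice <- decide_2ifc(observer, stim$Pstim1, stim$Pstim2)
    correct <- choice == si
    stairs[[sc]] <- staircase_update(stairs[[sc]], correct)
    rec$staircase[t] <- sc
    rec$contrast[t] <- contrast
    rec$signal_interval[t] <- si
    rec$choice[t] <- choice
    rec$correct[t] <- correct
    rec$seed1[t] <- seeds[1]; rec$seed2[t] <- seeds[2]; rec$seed_sig[t] <- seeds[3]
  }
  new_trial_log(rec, condition, observer)
}

#' Run a fixed-contrast 2-IFC session
#'
#' As [run_session] but with the signal contrast held constant (at the 75%
#' threshold in the classification-image procedure) for `n_trials` trials.
#' Replay seeds for both intervals' masks are stored so classification
#' images can be computed from the trial log.
#'
#' @param observer A [template_observer].
#' @param condition A [noise_condition].
#' @param contrast Fixed signal RMS contrast (> 0).
#' @param n_trials Number of trials (2500 per classification image in the
#'   standard procedure).
#' @return A `trial_log` data frame (staircase column is `NA`).
#' @export
run_fixed_contrast_session <- function(observer, condition, contrast,
                                       n_trials = 2500) {
  stopifnot(inherits(observer, "template_observer"),
            inherits(condition, "noise_condition"))
  if (!is.numeric(contrast) || contrast <= 0)
    stop("'contrast' must be positive")
  sig_int <- sample(rep_len(c(1L, 2L), n_trials))
  rec <- data.frame(trial = seq_len(n_trials), condition = condition$label,
                    staircase = NA_integer_, contrast = contrast,
                    signal_interval = sig_int, choice = 0L, correct = FALSE,
                    seed1 = 0L, seed2 = 0L, seed_sig = 0L)
  for (t in seq_len(n_trials)) {
    seeds <- sample.int(2147483646L, 3)
    stim <- trial_stimuli(condition, contrast, sig_int[t], seeds)
    choice <- decide_2ifc(observer, stim$Pstim1, stim$Pstim2)
    rec$choice[t] <- choice
    rec$correct[t] <- choice == sig_int[t]
    rec$seed1[t] <- seeds[1]; rec$seed2[t] <- seeds[2]; rec$seed_sig[t] <- seeds[3]
  }
  new_trial_log(rec, condition, observer)
}

#' Write / read a trial log as CSV
#'
#' The CSV stores the per-trial record (including replay seeds) but not the
#' condition object; supply the condition again when replaying (e.g. to
#' [classification_image]).
#'
#' @param trials A `trial_log`.
#' @param path File path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns a data frame.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.csv(path)
}

#' Measure a detection threshold with the full adaptive pipeline
#'
#' Runs one or more interleaved-staircase sessions and fits a single
#' cumulative-normal psychometric function to all trials pooled, returning
#' the 75%-correct RMS contrast threshold.
#'
#' @param observer A [template_observer].
#' @param condition A [noise_condition].
#' @param n_sessions Number of independent 300-trial sessions to pool.
#' @param ... Passed to [run_session].
#' @return List with `threshold`, `se_log10` (delta-method SE of the log10
#'   threshold), the psychometric `fit`, and the pooled `trials`.
#' @export
measure_threshold <- function(observer, condition, n_sessions = 1, ...) {
  logs <- lapply(seq_len(n_sessions), function(i)
    run_session(observer, condition, ...))
  trials <- do.call(rbind, lapply(logs, as.data.frame))
  fit <- fit_psychometric(trials)
  list(threshold = fit$threshold, se_log10 = fit$se[1], fit = fit,
       trials = new_trial_log(trials, condition, observer))
}
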