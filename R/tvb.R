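#' Fit a threshold-versus-bandwidth power law
#'
#' Weighted least-squares fit of log10 threshold on log10 component count.
#' The fitted exponent is the power-law slope; the ideal observer for
#' band-limited noise in white noise predicts the quarter-root law (exponent
#' 0.25). The narrowest bandwidth is excluded by default: sufficiently
#' narrow-band stimuli fall inside the critical band, flattening the
#' function, and characterizing that flattening is out of scope.
#'
#' @param thresholds Positive RMS-contrast thresholds, one per condition.
#' @param component_counts Positive stimulus component counts.
#' @param weights Regression weights (conventionally inverse variances of the
#'   log10 thresholds from the psychometric fits); equal by default.
#' @param exclude_narrowest Drop the smallest component count from the fit.
#' @return Object of class `tvb_fit`: `exponent`, `intercept`, the
#'   underlying `lm` fit, a data frame with `included` flags, and (after
#'   [bootstrap_tvb]) a confidence interval.
#' @export
fit_power_law <- function(thresholds, component_counts, weights = NULL,
                          exclude_narrowest = TRUE) {
  stopifnot(length(thresholds) == length(component_counts))
  if (any(thresholds <= 0) || any(component_counts <= 0))
    stop("thresholds and component counts must be positive")
  if (is.null(weights)) weights <- rep(1, length(thresholds))
  included <- rep(TRUE, length(thresholds))
  if (exclude_narrowest) included[which.min(component_counts)] <- FALSE
  if (sum(included) < 3)
    stop("need at least 3 included points to fit the power law")
  di <- data.frame(lN = log10(component_counts)[included],
                   lt = log10(thresholds)[included],
                   w = weights[included])
  fit <- stats::lm(lt ~ lN, data = di, weights = w)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit = fit,
                 data = data.frame(component_count = component_counts,
                                   threshold = thresholds, weight = weights,
                                   included = included),
                 ci = NULL),
            class = "tvb_fit")
}

#' @export
print.tvb_fit <- function(x, ...) {
  cat(sprintf("Threshold-vs-bandwidth power law: exponent %.4f, intercept %.4f (%d of %d points)\n",
              x$exponent, x$intercept, sum(x$data$included), nrow(x$data)))
  if (!is.null(x$ci))
    cat(sprintf("  95%% bootstrap CI on the exponent: [%.4f, %.4f]\n",
                x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
coef.tvb_fit <- function(object, ...)
  c(intercept = object$intercept, exponent = object$exponent)

#' @export
predict.tvb_fit <- function(object, component_counts = NULL, ...) {
  if (is.null(component_counts)) component_counts <- object$data$component_count
  10^(object$intercept + object$exponent * log10(component_counts))
}

#' @export
plot.tvb_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$component_count, d$threshold, log = "xy",
                 pch = ifelse(d$included, 16, 1),
                 xlab = "number of Fourier components",
                 ylab = "RMS contrast threshold", ...)
  Ns <- 10^seq(log10(min(d$component_count)), log10(max(d$component_count)),
               length.out = 100)
  graphics::lines(Ns, predict(x, Ns), col = "blue", lwd = 2)
  if (!is.null(x$ci)) {
    graphics::lines(Ns, 10^(x$intercept + x$ci[1] * log10(Ns)), col = "blue", lty = 3)
    graphics::lines(Ns, 10^(x$intercept + x$ci[2] * log10(Ns)), col = "blue", lty = 3)
  }
  invisible(x)
}

#' Bootstrap confidence interval for the power-law exponent
#'
#' Nonparametric trial-level bootstrap: within each condition, trials are
#' resampled with replacement, the psychometric function refit, and the
#' power law refit; the exponent's 95% percentile interval over the
#' replicates is returned (999 replicates for final analyses).
#' Replicates whose psychometric fits fail are logged and skipped; more than
#' 10% failures is an error.
#'
#' @param trial_list List of trial data frames, one per condition.
#' @param component_counts Component counts, same order.
#' @param n_boot Number of replicate fits.
#' @param weights Power-law weights reused across replicates.
#' @param exclude_narrowest As in [fit_power_law].
#' @return List with `ci` (2.5/97.5 percentiles), `replicates`, `n_fail`.
#' @export
bootstrap_tvb <- function(trial_list, component_counts, n_boot = 999,
                          weights = NULL, exclude_narrowest = TRUE) {
  stopifnot(is.list(trial_list),
            length(trial_list) == length(component_counts))
  k <- length(trial_list)
  reps <- rep(NA_real_, n_boot)
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    thr <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      d <- trial_list[[j]]
      idx <- sample.int(nrow(d), nrow(d), replace = TRUE)
      f <- tryCatch(fit_psychometric(d[idx, c("contrast", "correct")]),
                    error = function(e) NULL)
      if (is.null(f)) break
      thr[j] <- f$threshold
    }
    if (anyNA(thr)) { n_fail <- n_fail + 1L; next }
    pl <- tryCatch(fit_power_law(thr, component_counts, weights,
                                 exclude_narrowest),
                   error = function(e) NULL)
    if (is.null(pl)) { n_fail <- n_fail + 1L; next }
    reps[b] <- pl$exponent
  }
  if (n_fail > 0.1 * n_boot)
    stop(sprintf("bootstrap failed in %d of %d replicates (> 10%%)", n_fail, n_boot))
  ok <- !is.na(reps)
  list(ci = stats::quantile(reps[ok], c(0.025, 0.975)),
       replicates = reps[ok], n_fail = n_fail)
}

#' Absolute efficiency
#'
#' The squared ratio of the ideal observer's threshold to the observer's
#' threshold for identical stimuli: `eta = (c_ideal / c_observer)^2`. Equals
#' 1 for the ideal observer itself; human values of 20-40% indicate
#' near-optimal summation.
#'
#' @param c_ideal,c_observer Positive RMS-contrast thresholds measured with
#'   identical stimuli.
#' @return Efficiency (dimensionless).
#' @export
efficiency <- function(c_ideal, c_observer) {
  if (any(c_ideal <= 0) || any(c_observer <= 0))
    stop("thresholds must be positive")
  (c_ideal / c_observer)^2
}
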