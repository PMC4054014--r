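#' Constrained difference-of-Gaussians orientation tuning parameters
#'
#' A narrow excitatory Gaussian minus a broader inhibitory Gaussian sharing a
#' common center, the classic orientation-channel shape. Two constraints are
#' built in: the excitatory amplitude is exactly twice the inhibitory
#' amplitude (`A_e = 2 * A_i`, consistent with cortical surround physiology),
#' and the excitatory standard deviation is narrower than the inhibitory one.
#'
#' @param mu Center orientation, degrees.
#' @param sigma_e Excitatory (central) standard deviation, degrees; must be
#'   smaller than `sigma_i`.
#' @param sigma_i Inhibitory (surround) standard deviation, degrees.
#' @param amp_i Inhibitory amplitude; the excitatory amplitude is `2 * amp_i`.
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(mu = 0, sigma_e, sigma_i, amp_i = 1) {
  if (!is.numeric(sigma_e) || sigma_e <= 0) stop("'sigma_e' must be positive")
  if (!is.numeric(sigma_i) || sigma_i <= 0) stop("'sigma_i' must be positive")
  if (sigma_e >= sigma_i)
    stop("'sigma_e' must be smaller than 'sigma_i' (narrow excitation, broad inhibition)")
  if (!is.numeric(amp_i) || amp_i <= 0) stop("'amp_i' must be positive")
  structure(list(mu = mu, sigma_e = sigma_e, sigma_i = sigma_i,
                 amp_i = amp_i, amp_e = 2 * amp_i),
            class = "dog_params")
}

#' @export
print.dog_params <- function(x, ...) {
  cat(sprintf("DoG tuning: center %.3g deg, sigma_e %.4g deg, sigma_i %.4g deg, A_i %.4g (A_e = 2 A_i)\n",
              x$mu, x$sigma_e, x$sigma_i, x$amp_i))
  invisible(x)
}

# signed wrapped orientation difference in (-90, 90]
wrap_ori <- function(d) {
  d <- (d + 90) %% 180 - 90
  d[d == -90] <- 90
  d
}

#' Evaluate a difference-of-Gaussians tuning function
#'
#' `2*A_i*exp(-d^2/(2*sigma_e^2)) - A_i*exp(-d^2/(2*sigma_i^2))` with `d` the
#' orientation distance to the center, wrapped on the 180-degree orientation
#' circle. At the center the value is `A_i` (the 2:1 amplitude ratio minus
#' the unit inhibition).
#'
#' @param params A [dog_params].
#' @param theta Orientations in degrees (vector or matrix).
#' @return Tuning weights, same shape as `theta`.
#' @export
dog_eval <- function(params, theta) {
  stopifnot(inherits(params, "dog_params"))
  d <- wrap_ori(theta - params$mu)
  params$amp_i * (2 * exp(-d^2 / (2 * params$sigma_e^2)) -
                    exp(-d^2 / (2 * params$sigma_i^2)))
}

dog_rss <- function(par, theta, w) {
  # par = (mu, sigma_e, delta, amp_i); sigma_i = sigma_e + delta
  d <- wrap_ori(theta - par[1])
  f <- par[4] * (2 * exp(-d^2 / (2 * par[2]^2)) -
                   exp(-d^2 / (2 * (par[2] + par[3])^2)))
  sum((w - f)^2)
}

#' Fit a constrained difference-of-Gaussians to an orientation profile
#'
#' Least-squares fit of the constrained DoG (common center, 2:1 amplitude
#' ratio, excitatory narrower than inhibitory) to a one-dimensional
#' orientation profile. The ordering constraint is enforced by parameterizing
#' `sigma_i = sigma_e + delta` with `delta > 0`; a fit driven to the `delta`
#' boundary (data favouring `sigma_e >= sigma_i`) returns the boundary
#' solution with a warning. Optimization is multi-start L-BFGS-B over a
#' coarse grid of bandwidths.
#'
#' @param profile An orientation profile (data frame with columns `ori` in
#'   degrees and `weight`), e.g. from [orientation_profile].
#' @param normalize Divide the profile by its extreme value before fitting so
#'   the peak is 1 (the convention under which fitted amplitudes are read).
#' @param starts Optional matrix of starting values `(mu, sigma_e, delta,
#'   amp_i)`; by default a coarse bandwidth grid anchored at the profile peak.
#' @return Object of class `dog_fit`: fitted [dog_params], `rss`,
#'   `rss_single_gaussian` (best single-Gaussian fit, for shape comparison),
#'   `convergence`, the (possibly normalized) data, and `boundary` flag.
#' @export
fit_dog <- function(profile, normalize = TRUE, starts = NULL) {
  theta <- profile$ori
  w <- profile$weight
  if (!is.null(profile$n_bins) && any(profile$n_bins == 0)) {
    # orientation wedges with no Fourier components carry no data
    keep <- profile$n_bins > 0
    theta <- theta[keep]
    w <- w[keep]
  }
  if (length(theta) < 8) stop("profile too short to fit a DoG")
  if (normalize) {
    s <- w[which.max(abs(w))]
    if (s == 0) stop("profile is identically zero")
    w <- w / s
  }
  mu0 <- theta[which.max(w)]
  a0 <- max(w)
  if (a0 <= 0) stop("profile has no positive peak to anchor the fit")
  if (is.null(starts)) {
    se0 <- c(5, 12, 25, 45)
    d0 <- c(5, 20, 60)
    starts <- as.matrix(expand.grid(mu = mu0, sigma_e = se0, delta = d0, amp_i = a0))
  }
  # delta capped at 120: surrounds broader than that are flat over the
  # +-90 degree orientation range and unidentifiable
  lower <- c(mu0 - 90, 0.5, 1e-3, 1e-3)
  upper <- c(mu0 + 90, 89, 120, 10)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lower), upper), dog_rss,
                   theta = theta, w = w, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all DoG fit starts failed; profile may be degenerate")
  p <- best$par
  boundary <- p[3] <= lower[3] * 1.01 + 1e-6
  if (boundary)
    warning("sigma_e < sigma_i constraint is binding: fit returned a boundary solution with sigma_e ~ sigma_i")
  params <- structure(list(mu = wrap_ori(p[1]), sigma_e = p[2],
                           sigma_i = p[2] + p[3], amp_i = p[4], amp_e = 2 * p[4]),
                      class = "dog_params")
  # single-Gaussian reference fit (amplitude, center, sd)
  g_rss <- function(q) {
    d <- wrap_ori(theta - q[1]); sum((w - q[3] * exp(-d^2 / (2 * q[2]^2)))^2)
  }
  g <- stats::optim(c(mu0, max(p[2], 5), a0), g_rss, method = "L-BFGS-B",
                    lower = c(mu0 - 90, 0.5, 1e-3), upper = c(mu0 + 90, 120, 10),
                    control = list(factr = 1e3))
  structure(list(params = params, rss = best$value,
                 rss_single_gaussian = g$value,
                 convergence = best$convergence, boundary = boundary,
                 data = data.frame(ori = theta, weight = w),
                 ci = NULL),
            class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat("Constrained difference-of-Gaussians fit\n")
  print(x$params)
  cat(sprintf("  RSS %.4g (single Gaussian %.4g), convergence %d%s\n",
              x$rss, x$rss_single_gaussian, x$convergence,
              if (x$boundary) ", boundary solution" else ""))
  if (!is.null(x$ci)) {
    cat("  95% bootstrap CIs:\n")
    print(round(x$ci, 3))
  }
  invisible(x)
}

#' @export
coef.dog_fit <- function(object, ...) {
  with(object$params,
       c(mu = mu, sigma_e = sigma_e, sigma_i = sigma_i, amp_i = amp_i))
}

#' @export
predict.dog_fit <- function(object, theta = NULL, ...) {
  if (is.null(theta)) theta <- object$data$ori
  dog_eval(object$params, theta)
}

#' @export
plot.dog_fit <- function(x, ...) {
  graphics::plot(x$data$ori, x$data$weight, pch = 16, cex = 0.5,
                 xlab = "orientation (deg)", ylab = "weight", ...)
  th <- seq(min(x$data$ori), max(x$data$ori), length.out = 361)
  graphics::lines(th, dog_eval(x$params, th), col = "red", lwd = 2)
  invisible(x)
}

#' Percentile bootstrap for DoG channel parameters
#'
#' Resamples classification-image trials with replacement, recomputes the
#' orientation profile and the constrained DoG fit for each replicate, and
#' returns 2.5/97.5 percentile confidence intervals per parameter. Requires a
#' classification image computed with `keep_trials = TRUE` (per-trial
#' collapsed profiles are retained exactly for this purpose; the profile of a
#' resampled classification image is a linear combination of them).
#'
#' @param ci A `classif_image` with trial profiles.
#' @param n_boot Number of bootstrap replicates (default 199 for routine use;
#'   999 for final analyses).
#' @param fit Optional point-estimate `dog_fit` whose parameters seed each
#'   replicate fit.
#' @return Object of class `dog_boot`: matrix `ci` (parameters x 2),
#'   data frame `replicates`, and `n_fail`.
#' @export
bootstrap_dog <- function(ci, n_boot = 199, fit = NULL) {
  tp <- ci$trial_profiles
  if (is.null(tp))
    stop("classification image was computed without 'keep_trials = TRUE'; per-trial profiles are unavailable")
  prof0 <- ci_profile_from_trials(ci, seq_len(nrow(tp)))
  if (is.null(fit)) fit <- fit_dog(prof0)
  p0 <- c(fit$params$mu, fit$params$sigma_e,
          fit$params$sigma_i - fit$params$sigma_e, fit$params$amp_i)
  reps <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("mu", "sigma_e", "sigma_i", "amp_i")))
  n <- nrow(tp)
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- tryCatch({
      prof <- ci_profile_from_trials(ci, idx)
      suppressWarnings(fit_dog(prof, starts = rbind(p0)))
    }, error = function(e) NULL)
    if (is.null(f)) { n_fail <- n_fail + 1L; next }
    reps[b, ] <- coef.dog_fit(f)
  }
  if (n_fail > 0.1 * n_boot)
    stop(sprintf("bootstrap failed in %d of %d replicates (> 10%%)", n_fail, n_boot))
  ok <- stats::complete.cases(reps)
  cis <- t(apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                 probs = c(0.025, 0.975)))
  structure(list(ci = cis, replicates = as.data.frame(reps[ok, , drop = FALSE]),
                 n_fail = n_fail, n_boot = n_boot),
            class = "dog_boot")
}

#' @export
print.dog_boot <- function(x, ...) {
  cat(sprintf("DoG percentile bootstrap: %d replicates (%d failed)\n",
              x$n_boot, x$n_fail))
  print(round(x$ci, 3))
  invisible(x)
}

#' Weighted trend of fitted channel bandwidths across stimulus bandwidths
#'
#' Weighted least-squares regression of the fitted excitatory and inhibitory
#' standard deviations on stimulus orientation bandwidth, with the percent
#' increase of each parameter from the narrowest to the widest condition
#' (read off the fitted lines). This is the statistic that distinguishes
#' adjustable channels (positive slope, ~50% increase for channel bandwidths
#' that scale 20-30 and 60-90 degrees) from fixed channels (zero slope).
#'
#' @param bandwidths Stimulus two-sided orientation bandwidths, degrees.
#' @param sigma_e,sigma_i Fitted DoG standard deviations per condition.
#' @param weights_e,weights_i Optional regression weights (conventionally
#'   `1 / CI-half-width^2` from [bootstrap_dog]); equal weights by default.
#' @return Object of class `bandwidth_trend` with components `fit_e`,
#'   `fit_i` (lm fits), `slope_e`, `slope_i`, `pct_increase_e`,
#'   `pct_increase_i`.
#' @export
bandwidth_trend <- function(bandwidths, sigma_e, sigma_i,
                            weights_e = NULL, weights_i = NULL) {
  if (length(bandwidths) < 2) stop("at least 2 conditions are required")
  stopifnot(length(sigma_e) == length(bandwidths),
            length(sigma_i) == length(bandwidths))
  if (is.null(weights_e)) weights_e <- rep(1, length(bandwidths))
  if (is.null(weights_i)) weights_i <- rep(1, length(bandwidths))
  de <- data.frame(bw = bandwidths, s = sigma_e)
  di <- data.frame(bw = bandwidths, s = sigma_i)
  fe <- stats::lm(s ~ bw, data = de, weights = weights_e)
  fi <- stats::lm(s ~ bw, data = di, weights = weights_i)
  rng <- range(bandwidths)
  pe <- stats::predict(fe, data.frame(bw = rng))
  pi_ <- stats::predict(fi, data.frame(bw = rng))
  structure(list(bandwidths = bandwidths,
                 fit_e = fe, fit_i = fi,
                 slope_e = unname(stats::coef(fe)[2]),
                 slope_i = unname(stats::coef(fi)[2]),
                 pct_increase_e = unname(100 * (pe[2] - pe[1]) / pe[1]),
                 pct_increase_i = unname(100 * (pi_[2] - pi_[1]) / pi_[1])),
            class = "bandwidth_trend")
}

#' @export
print.bandwidth_trend <- function(x, ...) {
  cat("Channel bandwidth vs stimulus bandwidth (weighted least squares)\n")
  cat(sprintf("  sigma_e: slope %.4g deg/deg, %+.1f%% narrowest -> widest\n",
              x$slope_e, x$pct_increase_e))
  cat(sprintf("  sigma_i: slope %.4g deg/deg, %+.1f%% narrowest -> widest\n",
              x$slope_i, x$pct_increase_i))
  invisible(x)
}

#' @export
plot.bandwidth_trend <- function(x, ...) {
  se <- x$fit_e$model$s; si <- x$fit_i$model$s
  graphics::plot(range(x$bandwidths), range(c(se, si)), type = "n",
                 xlab = "stimulus orientation bandwidth (deg)",
                 ylab = "fitted channel SD (deg)", ...)
  graphics::points(x$bandwidths, se, col = "blue", pch = 16)
  graphics::points(x$bandwidths, si, col = "red", pch = 17)
  graphics::abline(x$fit_e, col = "blue")
  graphics::abline(x$fit_i, col = "red")
  graphics::legend("topleft", c("excitatory", "inhibitory"),
                   col = c("blue", "red"), pch = c(16, 17), bty = "n")
  invisible(x)
}

#' Joint bootstrap of the recovered bandwidth increase
#'
#' Resamples trials independently within each condition's classification
#' image, refits the constrained DoG per condition, recomputes the bandwidth
#' trend, and returns percentile CIs for the percent increase of each
#' parameter.
#'
#' @param ci_list List of `classif_image` objects (with trial profiles), one
#'   per condition, ordered as `bandwidths`.
#' @param bandwidths Stimulus orientation bandwidths, degrees.
#' @param n_boot Number of replicates.
#' @param fits Optional list of point-estimate `dog_fit`s used to seed
#'   replicate fits.
#' @return List with `ci_e`, `ci_i` (95% percentile CIs of the percent
#'   increases), and the replicate data frame.
#' @export
bootstrap_bandwidth_trend <- function(ci_list, bandwidths, n_boot = 199,
                                      fits = NULL) {
  k <- length(ci_list)
  stopifnot(k == length(bandwidths), k >= 2)
  if (is.null(fits))
    fits <- lapply(ci_list, function(ci)
      fit_dog(ci_profile_from_trials(ci, seq_len(nrow(ci$trial_profiles)))))
  seeds <- lapply(fits, function(f)
    c(f$params$mu, f$params$sigma_e, f$params$sigma_i - f$params$sigma_e,
      f$params$amp_i))
  reps <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("pct_e", "pct_i")))
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    se <- si <- numeric(k)
    ok <- TRUE
    for (j in seq_len(k)) {
      tp <- ci_list[[j]]$trial_profiles
      idx <- sample.int(nrow(tp), nrow(tp), replace = TRUE)
      f <- tryCatch({
        prof <- ci_profile_from_trials(ci_list[[j]], idx)
        suppressWarnings(fit_dog(prof, starts = rbind(seeds[[j]])))
      }, error = function(e) NULL)
      if (is.null(f)) { ok <- FALSE; break }
      se[j] <- f$params$sigma_e; si[j] <- f$params$sigma_i
    }
    if (!ok) { n_fail <- n_fail + 1L; next }
    tr <- bandwidth_trend(bandwidths, se, si)
    reps[b, ] <- c(tr$pct_increase_e, tr$pct_increase_i)
  }
  if (n_fail > 0.1 * n_boot)
    stop(sprintf("bootstrap failed in %d of %d replicates (> 10%%)", n_fail, n_boot))
  okr <- stats::complete.cases(reps)
  list(ci_e = stats::quantile(reps[okr, 1], c(0.025, 0.975)),
       ci_i = stats::quantile(reps[okr, 2], c(0.025, 0.975)),
       replicates = as.data.frame(reps[okr, , drop = FALSE]),
       n_fail = n_fail)
}
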