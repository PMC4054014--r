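#' Simulate a threshold-versus-bandwidth experiment
#'
#' Runs the full adaptive procedure (four interleaved staircases, cumulative-
#' normal psychometric fits, 75%-correct thresholds) for a set of orientation
#' bandwidths at a fixed spatial-frequency band, then fits the weighted
#' power law of log threshold against log component count. For the default
#' (ideal) observer the fitted exponent tests the quarter-root law.
#'
#' @param bandwidths Two-sided orientation bandwidths in degrees.
#' @param grid A [fourier_grid] for all conditions.
#' @param sf_octaves Spatial-frequency bandwidth of the signal band, octaves.
#' @param center_sf Center spatial frequency, cy/deg.
#' @param observer `NULL` for the per-condition ideal observer, or a function
#'   `(grid, spec) -> template_observer` building the observer for each
#'   condition, or a single fixed `template_observer`.
#' @param n_sessions 300-trial sessions pooled per condition.
#' @param n_boot Replicates for the bootstrap CI on the exponent (0 skips).
#' @param exclude_narrowest Exclude the narrowest bandwidth from the fit.
#' @param mask_variance,envelope Passed to [noise_condition].
#' @return Object of class `tvb_experiment`: `conditions` data frame
#'   (bandwidth, components, threshold, se_log10), the `fit` (a [fit_power_law]
#'   object, with bootstrap `ci` when requested), and the per-condition
#'   trial logs.
#' @export
tvb_experiment <- function(bandwidths = c(8, 16, 32, 64, 128, 180),
                           grid = fourier_grid(512, 94.8),
                           sf_octaves = 1, center_sf = 5,
                           observer = NULL, n_sessions = 3, n_boot = 0,
                           exclude_narrowest = TRUE,
                           mask_variance = 0.32, envelope = TRUE) {
  k <- length(bandwidths)
  thr <- se <- N <- numeric(k)
  logs <- vector("list", k)
  for (j in seq_len(k)) {
    spec <- filter_spec(center_sf, sf_octaves, 0, bandwidths[j])
    cond <- noise_condition(grid, spec, mask_variance = mask_variance,
                            envelope = envelope)
    obs <- if (is.null(observer)) ideal_template(grid, spec)
           else if (is.function(observer)) observer(grid, spec)
           else observer
    m <- measure_threshold(obs, cond, n_sessions = n_sessions)
    thr[j] <- m$threshold; se[j] <- m$se_log10; N[j] <- cond$n_components
    logs[[j]] <- m$trials
  }
  w <- ifelse(is.finite(se) & se > 0, 1 / se^2, 1)
  fit <- fit_power_law(thr, N, weights = w,
                       exclude_narrowest = exclude_narrowest)
  if (n_boot > 0) {
    b <- bootstrap_tvb(logs, N, n_boot = n_boot, weights = w,
                       exclude_narrowest = exclude_narrowest)
    fit$ci <- b$ci
  }
  structure(list(conditions = data.frame(bandwidth = bandwidths,
                                         components = N, threshold = thr,
                                         se_log10 = se),
                 fit = fit, trials = logs),
            class = "tvb_experiment")
}

#' @export
print.tvb_experiment <- function(x, ...) {
  cat("Threshold-versus-bandwidth experiment\n")
  print(x$conditions, row.names = FALSE)
  print(x$fit)
  invisible(x)
}

#' Simulate a classification-image channel experiment
#'
#' The fixed-contrast procedure: for each orientation-bandwidth condition a
#' DoG-template proxy observer is built, its 75%-correct threshold measured
#' with the adaptive pipeline, a fixed-contrast session run at that
#' threshold, the power-spectrum classification image computed and collapsed
#' to an orientation profile, and the constrained DoG fitted. The fitted
#' channel bandwidths are then regressed on stimulus bandwidth
#' ([bandwidth_trend]) with inverse-CI-width weights, and the percent
#' increase of each parameter bootstrapped jointly across conditions.
#'
#' With `fixed_template = TRUE` every condition uses the middle condition's
#' template (the fixed-channel hypothesis); the recovered trend slope should
#' then be indistinguishable from zero.
#'
#' @param bandwidths Stimulus two-sided orientation bandwidths, degrees.
#' @param sigma_e,sigma_i Generating excitatory/inhibitory SDs per condition.
#' @param grid A [fourier_grid].
#' @param sf_octaves,center_sf Signal band geometry.
#' @param n_trials Fixed-contrast trials per condition.
#' @param n_sessions Staircase sessions pooled for the threshold.
#' @param n_boot Bootstrap replicates for parameter CIs and the trend CI.
#' @param fixed_template Use one template for all conditions.
#' @param smooth Apply the triangular smoothing kernel before collapsing
#'   (see [classification_image]); on by default, as the per-component
#'   estimates are otherwise noise-dominated at 2,500 trials.
#' @param crop Classification-image crop size.
#' @param mask_variance,envelope Passed to [noise_condition].
#' @return Object of class `channel_experiment`: per-condition list `fits`
#'   (each with the classification image, profile, `dog_fit`, bootstrap), the
#'   `trend`, its bootstrap `trend_ci`, and a summary data frame.
#' @export
channel_experiment <- function(bandwidths = c(2, 48, 90),
                               sigma_e = c(20, 25, 30),
                               sigma_i = c(60, 75, 90),
                               grid = fourier_grid(512, 94.8),
                               sf_octaves = 1, center_sf = 5,
                               n_trials = 2500, n_sessions = 3, n_boot = 199,
                               fixed_template = FALSE, smooth = TRUE,
                               crop = 64,
                               mask_variance = 0.32, envelope = TRUE) {
  k <- length(bandwidths)
  stopifnot(length(sigma_e) == k, length(sigma_i) == k)
  if (fixed_template) {
    mid <- ceiling(k / 2)
    sigma_e <- rep(sigma_e[mid], k)
    sigma_i <- rep(sigma_i[mid], k)
  }
  fits <- vector("list", k)
  for (j in seq_len(k)) {
    spec <- filter_spec(center_sf, sf_octaves, 0, bandwidths[j])
    cond <- noise_condition(grid, spec, mask_variance = mask_variance,
                            envelope = envelope)
    obs <- dog_template(grid, dog_params(0, sigma_e[j], sigma_i[j]),
                        c(spec$sf_lo, spec$sf_hi),
                        label = sprintf("dog_%gdeg", bandwidths[j]))
    m <- measure_threshold(obs, cond, n_sessions = n_sessions)
    tl <- run_fixed_contrast_session(obs, cond, m$threshold, n_trials)
    ci <- suppressWarnings(
      classification_image(tl, crop = crop, smooth = smooth,
                           keep_trials = TRUE))
    prof <- suppressWarnings(orientation_profile(ci))
    f <- fit_dog(prof)
    b <- if (n_boot > 0) bootstrap_dog(ci, n_boot = n_boot, fit = f) else NULL
    fits[[j]] <- list(bandwidth = bandwidths[j], threshold = m$threshold,
                      pc = mean(tl$correct), image = ci, profile = prof,
                      fit = f, boot = b,
                      generating = c(sigma_e = sigma_e[j],
                                     sigma_i = sigma_i[j]))
  }
  fe <- vapply(fits, function(z) z$fit$params$sigma_e, 0)
  fi <- vapply(fits, function(z) z$fit$params$sigma_i, 0)
  # equal trend weights: all conditions carry identical trial counts, and
  # weights estimated from bootstrap CI widths are noisy enough (heavy-tailed
  # replicate distributions) to dominate the trend estimate itself
  trend <- bandwidth_trend(bandwidths, fe, fi)
  trend_ci <- if (n_boot > 0)
    bootstrap_bandwidth_trend(lapply(fits, `[[`, "image"), bandwidths,
                              n_boot = n_boot,
                              fits = lapply(fits, `[[`, "fit"))
  else NULL
  structure(list(fits = fits, trend = trend, trend_ci = trend_ci,
                 summary = data.frame(
                   bandwidth = bandwidths,
                   gen_sigma_e = sigma_e, gen_sigma_i = sigma_i,
                   fit_sigma_e = fe, fit_sigma_i = fi),
                 fixed_template = fixed_template),
            class = "channel_experiment")
}

#' @export
print.channel_experiment <- function(x, ...) {
  cat(sprintf("Classification-image channel experiment (%s templates)\n",
              if (x$fixed_template) "fixed" else "adjustable"))
  print(x$summary, row.names = FALSE)
  print(x$trend)
  if (!is.null(x$trend_ci)) {
    cat(sprintf("  95%% bootstrap CI on the percent increase: sigma_e [%.1f, %.1f], sigma_i [%.1f, %.1f]\n",
                x$trend_ci$ci_e[1], x$trend_ci$ci_e[2],
                x$trend_ci$ci_i[1], x$trend_ci$ci_i[2]))
  }
  invisible(x)
}

#' Measure absolute efficiency of a DoG-template proxy observer
#'
#' For each condition, 75%-correct thresholds are measured with the full
#' adaptive pipeline for a DoG-template proxy and for the ideal observer on
#' identical stimuli, and absolute efficiency (the squared threshold ratio)
#' computed, alongside the closed-form matched-template prediction.
#'
#' @param bandwidths Orientation bandwidths, degrees.
#' @param sigma_e,sigma_i Proxy channel SDs per condition.
#' @param grid A [fourier_grid].
#' @param sf_octaves,center_sf Signal band geometry.
#' @param n_sessions Sessions pooled per threshold.
#' @param mask_variance,envelope Passed to [noise_condition].
#' @return Data frame with per-condition thresholds, measured efficiency, and
#'   the closed-form oracle efficiency (both as fractions).
#' @export
efficiency_experiment <- function(bandwidths = c(48, 90),
                                  sigma_e = c(25, 30), sigma_i = c(75, 90),
                                  grid = fourier_grid(512, 94.8),
                                  sf_octaves = 1, center_sf = 5,
                                  n_sessions = 3,
                                  mask_variance = 0.32, envelope = TRUE) {
  k <- length(bandwidths)
  out <- data.frame(bandwidth = bandwidths, threshold_proxy = NA_real_,
                    threshold_ideal = NA_real_, eta = NA_real_,
                    eta_oracle = NA_real_)
  for (j in seq_len(k)) {
    spec <- filter_spec(center_sf, sf_octaves, 0, bandwidths[j])
    cond <- noise_condition(grid, spec, mask_variance = mask_variance,
                            envelope = envelope)
    proxy <- dog_template(grid, dog_params(0, sigma_e[j], sigma_i[j]),
                          c(spec$sf_lo, spec$sf_hi))
    ideal <- ideal_template(grid, spec)
    mp <- measure_threshold(proxy, cond, n_sessions = n_sessions)
    mi <- measure_threshold(ideal, cond, n_sessions = n_sessions)
    out$threshold_proxy[j] <- mp$threshold
    out$threshold_ideal[j] <- mi$threshold
    out$eta[j] <- efficiency(mi$threshold, mp$threshold)
    out$eta_oracle[j] <- template_efficiency(proxy, cond)
  }
  out
}
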