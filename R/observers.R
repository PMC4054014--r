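#' Linear template observer on the power spectrum
#'
#' An observer that weights the power spectrum of each stimulus interval by a
#' fixed conjugate-symmetric weight map, adds independent zero-mean Gaussian
#' internal noise to each interval's decision variable, and chooses the
#' interval with the larger value.
#'
#' @param weights Numeric conjugate-symmetric matrix of per-component weights
#'   (may be negative).
#' @param internal_noise_sd SD of the internal noise added per interval, in
#'   decision-variable units (0 = deterministic rule).
#' @param label Optional label.
#' @return Object of class `template_observer`.
#' @export
template_observer <- function(weights, internal_noise_sd = 0, label = "template") {
  stopifnot(is.matrix(weights), is.numeric(weights),
            nrow(weights) == ncol(weights))
  ci <- conjugate_index(nrow(weights))
  if (max(abs(weights - weights[ci, ci])) > 1e-8)
    stop("'weights' must be conjugate-symmetric")
  if (internal_noise_sd < 0) stop("'internal_noise_sd' must be non-negative")
  structure(list(weights = weights, internal_noise_sd = internal_noise_sd,
                 label = label),
            class = "template_observer")
}

#' @export
print.template_observer <- function(x, ...) {
  cat(sprintf("Template observer '%s': %d x %d weight map, %d non-zero components, internal noise SD %.3g\n",
              x$label, nrow(x$weights), ncol(x$weights),
              sum(x$weights != 0), x$internal_noise_sd))
  invisible(x)
}

#' Ideal observer template for a band-limited noise target
#'
#' Uniform unit weights on the stimulus component band, zero elsewhere, no
#' internal noise. For detecting Gaussian noise of known flat in-band
#' spectrum in white Gaussian noise, the likelihood-ratio observer is
#' monotone in the in-band energy of each interval, so comparing
#' uniformly-weighted in-band power across intervals is the standard
#' noise-in-noise ideal decision rule.
#'
#' @param grid A [fourier_grid].
#' @param spec A [filter_spec] (or a precomputed logical mask).
#' @return A `template_observer`.
#' @export
ideal_template <- function(grid, spec) {
  mask <- if (is.matrix(spec)) spec else band_mask(grid, spec)
  if (!any(mask)) stop("band is empty on this grid")
  template_observer(mask * 1, 0, label = "ideal")
}

#' Difference-of-Gaussians channel observer
#'
#' A human-proxy observer whose power-spectrum weights follow a constrained
#' DoG orientation tuning function, extruded over a spatial-frequency
#' annulus, with an optional uniform negative weight on a low-spatial-
#' frequency disk (emulating suppression from uninformative low
#' frequencies).
#'
#' @param grid A [fourier_grid].
#' @param dog A [dog_params] giving the orientation tuning (its `mu` is the
#'   channel center orientation in display coordinates).
#' @param sf_band Length-2 numeric, the spatial-frequency passband (cy/deg)
#'   over which the tuning is extruded.
#' @param low_sf_weight Weight assigned to bins below `low_sf_cutoff`
#'   (typically negative; 0 disables the disk).
#' @param low_sf_cutoff Radius of the low-frequency disk, cy/deg.
#' @param internal_noise_sd Internal noise SD.
#' @param label Optional label.
#' @return A `template_observer`.
#' @export
dog_template <- function(grid, dog, sf_band, low_sf_weight = 0,
                         low_sf_cutoff = 2, internal_noise_sd = 0,
                         label = "dog") {
  stopifnot(inherits(grid, "fourier_grid"), inherits(dog, "dog_params"),
            length(sf_band) == 2, sf_band[1] < sf_band[2])
  w <- matrix(0, grid$size, grid$size)
  ann <- grid$sf >= sf_band[1] & grid$sf <= sf_band[2]
  w[ann] <- dog_eval(dog, grid$ori[ann])
  if (low_sf_weight != 0) {
    disk <- grid$sf < low_sf_cutoff & grid$sf > 0
    w[disk] <- low_sf_weight
  }
  half <- grid$size / 2
  w[abs(grid$kx) == half | abs(grid$ky) == half] <- 0
  w[1, 1] <- 0
  template_observer(w, internal_noise_sd, label = label)
}

#' Two-interval forced-choice decision
#'
#' Each interval's decision variable is the template-weighted sum of its
#' power spectrum (conjugate pairs counted once) plus independent Gaussian
#' internal noise; the observer chooses the interval with the larger value.
#' Ties break to interval 1, making the zero-noise rule fully deterministic.
#'
#' @param observer A [template_observer].
#' @param power1,power2 Power spectra of intervals 1 and 2 (matrices on the
#'   observer's grid, as from [power_spectrum]).
#' @return Integer choice, 1 or 2.
#' @export
decide_2ifc <- function(observer, power1, power2) {
  stopifnot(inherits(observer, "template_observer"))
  if (!identical(dim(power1), dim(observer$weights)) ||
      !identical(dim(power2), dim(observer$weights)))
    stop("power spectra do not match the observer's grid")
  v1 <- sum(observer$weights * power1) / 2
  v2 <- sum(observer$weights * power2) / 2
  if (observer$internal_noise_sd > 0) {
    z <- stats::rnorm(2, 0, observer$internal_noise_sd)
    v1 <- v1 + z[1]; v2 <- v2 + z[2]
  }
  if (v1 >= v2) 1L else 2L
}

half_plane <- function(grid) grid$kx > 0 | (grid$kx == 0 & grid$ky > 0)

#' Closed-form proportion correct for a template observer
#'
#' Normal approximation to the 2-IFC percent correct of a linear power-
#' spectrum template at a given signal contrast, from the analytic mean and
#' variance of the decision-variable difference. Per half-plane component the
#' mask power is exponential with mean equal to the mask contrast variance,
#' and the signal adds `size^2 * c^2 / (2 N)` mean power to each of the `N`
#' in-band components. The contrast envelope is ignored (exact for
#' unenveloped conditions; a close approximation otherwise).
#'
#' @param observer A [template_observer].
#' @param condition A [noise_condition].
#' @param contrast Signal RMS contrast.
#' @return Predicted proportion correct.
#' @export
analytic_proportion_correct <- function(observer, condition, contrast) {
  grid <- condition$grid
  hp <- half_plane(grid)
  w <- observer$weights[hp]
  b <- condition$mask[hp]
  m <- condition$mask_variance
  N <- condition$n_components
  s <- grid$size^2 * contrast^2 / (2 * N)
  sk <- ifelse(b, s, 0)
  mu <- s * sum(w[b])
  v <- sum(w^2 * ((m + sk)^2 + m^2)) + 2 * observer$internal_noise_sd^2
  stats::pnorm(mu / sqrt(v))
}

#' Closed-form threshold estimate for a template observer
#'
#' Inverts [analytic_proportion_correct] for the contrast giving a target
#' percent correct. Returns `NA` with a warning when the template's net
#' in-band weight is not positive (the observer cannot reach the target).
#'
#' @param observer A [template_observer].
#' @param condition A [noise_condition].
#' @param pc Target proportion correct (default 0.75).
#' @return RMS contrast, or `NA`.
#' @export
analytic_threshold <- function(observer, condition, pc = 0.75) {
  f <- function(lc) analytic_proportion_correct(observer, condition, 10^lc) - pc
  lo <- -5; hi <- 0.7
  if (f(hi) < 0 || f(lo) > 0) {
    warning("no analytic threshold in range: template cannot reach the target percent correct")
    return(NA_real_)
  }
  10^stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Closed-form absolute efficiency of a template observer
#'
#' Matched-template efficiency for noise-in-noise detection. Because the
#' decision variable is linear in stimulus *power*, sensitivity grows as the
#' squared contrast, and the squared threshold ratio of Eq.-style absolute
#' efficiency reduces in the small-signal limit to the cosine similarity
#' between the template and the stimulus band indicator:
#' `eta = sum(w[band]) / sqrt(N * sum(w^2))` over half-plane components.
#' Valid for zero internal noise.
#'
#' @param observer A [template_observer] (internal noise 0).
#' @param condition A [noise_condition].
#' @return Efficiency (dimensionless, 1 = ideal).
#' @export
template_efficiency <- function(observer, condition) {
  if (observer$internal_noise_sd > 0)
    warning("closed-form efficiency assumes zero internal noise")
  grid <- condition$grid
  hp <- half_plane(grid)
  w <- observer$weights[hp]
  b <- condition$mask[hp]
  sum(w[b]) / sqrt(condition$n_components * sum(w^2))
}

#' Calibrate internal noise to a target percent correct
#'
#' Bisection on the internal noise SD so that a template observer performs at
#' a target percent correct for a fixed stimulus, using the closed-form
#' percent-correct approximation.
#'
#' @param observer A [template_observer].
#' @param condition A [noise_condition].
#' @param contrast Signal RMS contrast at which to calibrate.
#' @param target_pc Target proportion correct.
#' @return The observer with `internal_noise_sd` set; errors if the target is
#'   unreachable (above the zero-noise performance).
#' @export
calibrate_internal_noise <- function(observer, condition, contrast,
                                     target_pc = 0.75) {
  obs0 <- observer; obs0$internal_noise_sd <- 0
  p0 <- analytic_proportion_correct(obs0, condition, contrast)
  if (p0 < target_pc)
    stop(sprintf("target %.3f exceeds zero-noise performance %.3f", target_pc, p0))
  f <- function(sd) {
    o <- observer; o$internal_noise_sd <- sd
    analytic_proportion_correct(o, condition, contrast) - target_pc
  }
  hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 10
  sd <- stats::uniroot(f, c(0, hi), tol = 1e-9)$root
  observer$internal_noise_sd <- sd
  observer
}
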