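#' Power spectrum of a patch
#'
#' Squared modulus of the 2D DFT, scaled by `1/length(x)` so that Parseval's
#' identity reads `sum(power_spectrum(x)) == sum(x^2)`. Under this convention
#' the expected per-bin power of white noise with pixel variance `v` is `v`.
#'
#' @param patch Numeric matrix of pixel contrasts.
#' @return Numeric matrix of per-bin power, DFT layout (DC at `[1, 1]`).
#' @export
power_spectrum <- function(patch) {
  stopifnot(is.matrix(patch), is.numeric(patch))
  Mod(stats::fft(patch))^2 / length(patch)
}

#' RMS contrast of a patch
#' @param patch Numeric matrix of pixel contrasts.
#' @return `sqrt(mean(patch^2))`.
#' @export
rms_contrast <- function(patch) sqrt(mean(patch^2))

#' Synthesize band-limited Gaussian noise
#'
#' A white Gaussian field is transformed to the frequency domain, zeroed
#' outside the component mask, transformed back, and rescaled to the target
#' RMS contrast. With `rescale = "exact"` the sample RMS equals the target
#' exactly (the definition of stimulus contrast used throughout); with
#' `rescale = "expected"` the field is scaled by a deterministic constant so
#' that the *expected* RMS equals the target, leaving per-component powers
#' independent (useful for closed-form checks).
#'
#' Draws from the current R RNG stream.
#'
#' @param grid A [fourier_grid].
#' @param mask Logical component mask (e.g. from [band_mask]).
#' @param target_rms Target RMS contrast; 0 returns the zero patch.
#' @param rescale Rescaling rule, `"exact"` (default) or `"expected"`.
#' @return Numeric `size x size` matrix with sample mean ~0.
#' @export
filtered_noise <- function(grid, mask, target_rms, rescale = c("exact", "expected")) {
  stopifnot(inherits(grid, "fourier_grid"), is.matrix(mask), is.logical(mask))
  rescale <- match.arg(rescale)
  if (!is.numeric(target_rms) || length(target_rms) != 1L || target_rms < 0)
    stop("'target_rms' must be a single non-negative number")
  n <- grid$size
  if (target_rms == 0) return(matrix(0, n, n))
  if (!any(mask))
    stop("cannot synthesize noise with positive contrast from an empty component mask")
  x <- matrix(stats::rnorm(n * n), n, n)
  X <- stats::fft(x)
  X[!mask] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / (n * n)
  if (rescale == "exact") {
    y * (target_rms / sqrt(mean(y^2)))
  } else {
    # filtered white field passes a fraction sum(mask)/n^2 of unit variance
    y * (target_rms / sqrt(sum(mask) / (n * n)))
  }
}

#' Gaussian white-noise mask patch
#'
#' i.i.d. Gaussian pixels with mean 0 and the given contrast variance, the
#' masking noise added to every stimulus interval. Draws from the current R
#' RNG stream.
#'
#' @param size Patch size in pixels.
#' @param contrast_variance Pixel contrast variance (default 0.32). Note this
#'   is a variance, implying an RMS contrast of about 0.57; treated as a
#'   configuration value.
#' @return Numeric `size x size` matrix.
#' @export
white_noise <- function(size, contrast_variance = 0.32) {
  if (!is.numeric(contrast_variance) || contrast_variance < 0)
    stop("'contrast_variance' must be non-negative")
  matrix(stats::rnorm(size * size, 0, sqrt(contrast_variance)), size, size)
}

#' Circular Gaussian contrast envelope
#'
#' Centered at pixel `(size/2 + 1, size/2 + 1)` with peak 1 and standard
#' deviation `sd_deg` of visual angle, used to window the signal and avoid
#' hard stimulus edges.
#'
#' @param size Patch size in pixels.
#' @param sd_deg Envelope standard deviation in degrees.
#' @param px_per_deg Pixels per degree.
#' @return Numeric `size x size` matrix in `(0, 1]`.
#' @export
gaussian_envelope <- function(size, sd_deg, px_per_deg) {
  if (!is.numeric(sd_deg) || sd_deg <= 0) stop("'sd_deg' must be positive")
  sd_px <- sd_deg * px_per_deg
  d <- (1:size) - (size / 2 + 1)
  r2 <- outer(d^2, d^2, "+")
  exp(-r2 / (2 * sd_px^2))
}

#' Apply a Gaussian contrast envelope to a patch
#'
#' @param patch Numeric matrix.
#' @param sd_deg Envelope standard deviation in degrees.
#' @param px_per_deg Pixels per degree.
#' @return The windowed patch.
#' @export
apply_envelope <- function(patch, sd_deg, px_per_deg) {
  stopifnot(is.matrix(patch))
  patch * gaussian_envelope(nrow(patch), sd_deg, px_per_deg)
}
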