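#' Fourier-domain coordinate grid
#'
#' Builds the spatial-frequency / orientation coordinate system for a square
#' stimulus patch. Each DFT bin is annotated with its radial frequency in
#' cycles per degree and its grating orientation in degrees.
#'
#' Orientation follows the display convention for gratings: 0 degrees denotes
#' a horizontally-oriented grating, whose frequency vector points along the
#' vertical frequency axis. The mapping from the geometric angle of the
#' frequency vector to grating orientation is therefore a 90-degree rotation,
#' fixed once here; every other function in the package inherits it.
#'
#' @param size Patch size in pixels (one side of the square); must be even.
#' @param px_per_deg Pixels per degree of visual angle.
#'
#' @return An object of class `fourier_grid`: a list with the integer
#'   frequency-index matrices `kx`, `ky` (in DFT order, DC at `[1, 1]`), the
#'   radial frequency map `sf` (cy/deg), the orientation map `ori` (degrees in
#'   `[0, 180)`), `size`, `px_per_deg`, and `nyquist` (cy/deg).
#'
#' @examples
#' g <- fourier_grid(64, 64)
#' g$sf[1, 1]   # DC
#' g$ori[2, 1]  # one step along the vertical frequency axis: horizontal, 0 deg
#' @export
fourier_grid <- function(size, px_per_deg) {
  if (!is.numeric(size) || length(size) != 1L || size <= 0 || size != round(size))
    stop("'size' must be a positive integer")
  if (size %% 2 != 0)
    stop("'size' must be even (the DFT layout assumes a Nyquist row/column)")
  if (size < 4)
    stop("'size' must be at least 4")
  if (!is.numeric(px_per_deg) || length(px_per_deg) != 1L || px_per_deg <= 0)
    stop("'px_per_deg' must be a positive number")
  size <- as.integer(size)
  k <- 0:(size - 1L)
  k <- ifelse(k <= size / 2, k, k - size)
  kx <- matrix(k, size, size, byrow = TRUE)
  ky <- matrix(k, size, size, byrow = FALSE)
  sf <- sqrt(kx^2 + ky^2) * px_per_deg / size
  # 0 deg = horizontal grating = frequency vector along the vertical axis
  ori <- (atan2(kx, ky) * 180 / pi) %% 180
  structure(
    list(size = size, px_per_deg = px_per_deg, kx = kx, ky = ky,
         sf = sf, ori = ori, nyquist = px_per_deg / 2),
    class = "fourier_grid")
}

#' @export
print.fourier_grid <- function(x, ...) {
  cat(sprintf("Fourier grid: %d x %d px, %.2f px/deg (Nyquist %.2f cy/deg, resolution %.3f cy/deg)\n",
              x$size, x$size, x$px_per_deg, x$nyquist, x$px_per_deg / x$size))
  invisible(x)
}

#' Band-limited noise filter specification
#'
#' Geometry of an ideal (hard-edged) spatial frequency and orientation
#' passband. The spatial-frequency passband spans `center_sf * 2^(-b/2)` to
#' `center_sf * 2^(b/2)` for a bandwidth of `b` octaves; the orientation
#' passband spans `center_ori` plus/minus half the two-sided orientation
#' bandwidth, wrapped modulo 180 degrees. A two-sided bandwidth of 16 degrees
#' about horizontal passes orientations from -8 to +8 degrees.
#'
#' @param center_sf Center spatial frequency, cy/deg.
#' @param sf_bandwidth Spatial-frequency bandwidth in octaves.
#' @param center_ori Center orientation in degrees (0 = horizontal).
#' @param ori_bandwidth Two-sided orientation bandwidth in degrees, in
#'   `(0, 180]`; 180 passes all orientations.
#'
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(center_sf = 5, sf_bandwidth = 1,
                        center_ori = 0, ori_bandwidth = 180) {
  if (!is.numeric(center_sf) || center_sf <= 0)
    stop("'center_sf' must be positive")
  if (!is.numeric(sf_bandwidth) || sf_bandwidth <= 0)
    stop("'sf_bandwidth' (octaves) must be positive")
  if (!is.numeric(ori_bandwidth) || ori_bandwidth <= 0 || ori_bandwidth > 180)
    stop("'ori_bandwidth' must lie in (0, 180] degrees")
  structure(
    list(center_sf = center_sf, sf_bandwidth = sf_bandwidth,
         center_ori = center_ori %% 180, ori_bandwidth = ori_bandwidth,
         sf_lo = center_sf * 2^(-sf_bandwidth / 2),
         sf_hi = center_sf * 2^(sf_bandwidth / 2)),
    class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Band filter: %.3g cy/deg center, %.3g octave(s) [%.3g-%.3g cy/deg], %.4g deg center orientation, %.4g deg two-sided orientation bandwidth\n",
              x$center_sf, x$sf_bandwidth, x$sf_lo, x$sf_hi,
              x$center_ori, x$ori_bandwidth))
  invisible(x)
}

#' Binary Fourier component mask for a band filter
#'
#' A bin is included iff its radial frequency lies in the closed
#' spatial-frequency passband and its orientation lies within half the
#' two-sided bandwidth of the center orientation (180-degree wrapped). DC and
#' the Nyquist row/column are always excluded: DC carries no orientation and
#' Nyquist bins lack conjugate partners. The result is conjugate-symmetric.
#'
#' @param grid A [fourier_grid].
#' @param spec A [filter_spec].
#' @return Logical matrix of the grid size.
#' @export
band_mask <- function(grid, spec) {
  stopifnot(inherits(grid, "fourier_grid"), inherits(spec, "filter_spec"))
  if (spec$sf_hi > grid$nyquist + 1e-9)
    stop(sprintf("spatial-frequency passband upper edge %.4g cy/deg exceeds the grid Nyquist frequency %.4g cy/deg",
                 spec$sf_hi, grid$nyquist))
  eps <- 1e-9
  in_sf <- grid$sf >= spec$sf_lo - eps & grid$sf <= spec$sf_hi + eps
  d <- abs(grid$ori - spec$center_ori) %% 180
  d <- pmin(d, 180 - d)
  in_ori <- d <= spec$ori_bandwidth / 2 + eps
  mask <- in_sf & in_ori
  half <- grid$size / 2
  mask[abs(grid$kx) == half | abs(grid$ky) == half] <- FALSE
  mask[1, 1] <- FALSE
  mask
}

#' All usable Fourier components of a grid
#'
#' Every bin except DC and the Nyquist row/column; the component mask of an
#' unfiltered white-noise target.
#'
#' @param grid A [fourier_grid].
#' @return Logical matrix.
#' @export
full_component_mask <- function(grid) {
  stopifnot(inherits(grid, "fourier_grid"))
  half <- grid$size / 2
  mask <- abs(grid$kx) != half & abs(grid$ky) != half
  mask[1, 1] <- FALSE
  mask
}

# index permutation mapping each bin to its conjugate partner (frequency negation)
conjugate_index <- function(n) c(1L, n:2L)

#' Count independent Fourier components in a mask
#'
#' Counts conjugate pairs once. This is the bandwidth axis of the
#' threshold-versus-bandwidth analysis: the number of independent components
#' in the stimulus, on which the ideal observer's threshold depends.
#'
#' @param mask Logical conjugate-symmetric matrix (as from [band_mask]).
#' @return Integer number of conjugate pairs.
#' @export
component_count <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask) || nrow(mask) != ncol(mask))
    stop("'mask' must be a square logical matrix")
  ci <- conjugate_index(nrow(mask))
  if (!identical(mask, mask[ci, ci]))
    stop("'mask' is not conjugate-symmetric")
  s <- sum(mask)
  if (s %% 2 != 0)
    stop("'mask' contains self-conjugate bins (DC or Nyquist); these are not valid components")
  as.integer(s / 2)
}
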