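# centered-crop machinery shared by the classification-image functions:
# mapping from centered positions (DC at m/2+1) to DFT-layout indices of the
# full grid, plus per-bin coordinates of the cropped spectrum
crop_coords <- function(n, m, px_per_deg) {
  stopifnot(m %% 2 == 0, m <= n)
  kv <- (-(m / 2)):(m / 2 - 1)
  idx <- kv %% n + 1
  kx <- matrix(kv, m, m, byrow = TRUE)
  ky <- matrix(kv, m, m, byrow = FALSE)
  list(idx = idx, k = kv, kx = kx, ky = ky,
       sf = sqrt(kx^2 + ky^2) * px_per_deg / n,
       ori = (atan2(kx, ky) * 180 / pi) %% 180)
}

# 0/1 collapse operator: rows = 1-degree orientation wedges (centers -90..89
# relative to center_ori), columns = selected half-plane bins of the crop
collapse_operator <- function(cc, m, sf_band, center_ori) {
  hp <- cc$kx > 0 | (cc$kx == 0 & cc$ky > 0)
  sel <- hp & abs(cc$kx) < m / 2 & abs(cc$ky) < m / 2 &
    cc$sf > 1e-12 & cc$sf >= sf_band[1] & cc$sf <= sf_band[2]
  if (!any(sel)) stop("no Fourier components fall in the requested band")
  d <- wrap_ori(cc$ori[sel] - center_ori)
  wedge <- round(d)
  wedge[wedge == 90] <- -90
  wi <- wedge + 91L  # 1..180 for -90..89
  selv <- which(sel)
  W <- matrix(0, 180, length(selv))
  W[cbind(wi, seq_along(selv))] <- 1
  list(W = W, sel = selv, n_bins = tabulate(wi, 180))
}

#' Power-spectrum classification image from 2-IFC trials
#'
#' Reconstructs the linear decision template from fixed-contrast trials. For
#' each trial the power spectra of the two intervals' noise are replayed from
#' the stored seeds, and the difference spectrum (signal interval minus
#' non-signal interval) is accumulated into one of four bins defined by the
#' signal interval (1 or 2) and the response (correct or incorrect). Bin
#' averages use bin-specific trial counts; the two correct-bin averages are
#' averaged, likewise the incorrect-bin averages; the classification image is
#' their difference, normalized to a peak magnitude of 1 with the sign chosen
#' so that the signal band is positive. For a linear template observer the
#' result is proportional to its weight map.
#'
#' The image is returned on a centered crop of the full spectrum (64 x 64 by
#' default; power spectra of real stimuli are conjugate-symmetric, so the two
#' half-planes are identical by construction).
#'
#' @param trials A `trial_log` from [run_fixed_contrast_session] (any trial
#'   log with replay seeds works).
#' @param condition The [noise_condition] to replay; defaults to the one
#'   attached to the trial log.
#' @param crop Output size in bins (even, at most the grid size).
#' @param sf_band Spatial-frequency band (cy/deg) for the per-trial collapsed
#'   orientation profiles; default spans the whole crop.
#' @param spectra `"mask"` (default) computes spectra of the noise masks
#'   alone; `"stimulus"` includes the signal in the signal interval.
#' @param smooth Apply the 5 x 5 triangular kernel to each trial's cropped
#'   difference spectrum before accumulating. Because every later step is
#'   linear this equals smoothing the finished image, and the stored
#'   per-trial profiles (hence bootstraps) stay consistent with it. At the
#'   signal annulus radius the kernel blurs orientation by only 2-3 degrees,
#'   negligible against channel bandwidths, while suppressing the
#'   trial-sampling noise that otherwise dominates per-component estimates.
#' @param keep_trials Retain per-trial collapsed profiles (needed by
#'   [bootstrap_dog] and [bootstrap_bandwidth_trend]).
#' @param center_ori Center orientation for the profile axis; defaults to the
#'   condition's filter center (0 for white-noise conditions).
#' @return Object of class `classif_image` with the normalized `map`, the
#'   unnormalized `raw` map, coordinate matrices `sf` and `ori`, `bin_counts`,
#'   the retained `sf_max`, and optionally `trial_profiles`.
#' @export
classification_image <- function(trials, condition = attr(trials, "condition"),
                                 crop = 64, sf_band = NULL,
                                 spectra = c("mask", "stimulus"),
                                 smooth = FALSE,
                                 keep_trials = FALSE, center_ori = NULL) {
  spectra <- match.arg(spectra)
  if (is.null(condition) || !inherits(condition, "noise_condition"))
    stop("a 'noise_condition' is required to replay the trials")
  grid <- condition$grid
  n <- grid$size
  if (is.null(crop)) crop <- n
  crop <- as.integer(crop)
  if (crop > n) stop("'crop' exceeds the grid size")
  if (is.null(center_ori))
    center_ori <- if (is.null(condition$spec)) 0 else condition$spec$center_ori
  cc <- crop_coords(n, crop, grid$px_per_deg)
  if (is.null(sf_band)) sf_band <- c(0, (crop / 2) * grid$px_per_deg / n)
  op <- collapse_operator(cc, crop, sf_band, center_ori)
  if (any(op$n_bins == 0))
    warning("some 1-degree orientation bins contain no Fourier components at this grid resolution; their profile values are 0")

  nt <- nrow(trials)
  sums <- array(0, c(crop, crop, 4))
  counts <- integer(4)
  tp <- if (keep_trials) matrix(0, nt, 180) else NULL
  bin_of <- function(si, corr) (si - 1L) * 2L + ifelse(corr, 1L, 2L)
  for (t in seq_len(nt)) {
    si <- trials$signal_interval[t]
    seeds <- c(trials$seed1[t], trials$seed2[t], trials$seed_sig[t])
    st <- trial_stimuli(condition, trials$contrast[t], si, seeds,
                        what = if (spectra == "mask") "mask" else "stimulus")
    if (spectra == "mask") {
      D <- if (si == 1L) st$Pmask1 - st$Pmask2 else st$Pmask2 - st$Pmask1
    } else {
      D <- if (si == 1L) st$Pstim1 - st$Pstim2 else st$Pstim2 - st$Pstim1
    }
    Dc <- D[cc$idx, cc$idx]
    if (smooth) Dc <- conv2_sep(Dc, c(1, 2, 3, 2, 1) / 9)
    b <- bin_of(si, trials$correct[t])
    sums[, , b] <- sums[, , b] + Dc
    counts[b] <- counts[b] + 1L
    if (keep_trials) tp[t, ] <- as.vector(op$W %*% Dc[op$sel])
  }
  bin_names <- c("sig1_correct", "sig1_incorrect", "sig2_correct", "sig2_incorrect")
  names(counts) <- bin_names
  if (any(counts == 0))
    stop("no trials in bin(s): ", paste(bin_names[counts == 0], collapse = ", "))
  mc <- (sums[, , 1] / counts[1] + sums[, , 3] / counts[3]) / 2
  mi <- (sums[, , 2] / counts[2] + sums[, , 4] / counts[4]) / 2
  raw <- mc - mi
  scale <- max(abs(raw))
  map <- raw / scale
  flipped <- FALSE
  band_sel <- if (!is.null(condition$spec)) {
    d <- wrap_ori(cc$ori - condition$spec$center_ori)
    cc$sf >= condition$spec$sf_lo & cc$sf <= condition$spec$sf_hi &
      abs(d) <= condition$spec$ori_bandwidth / 2
  } else cc$sf > 0
  if (mean(map[band_sel]) < 0) { map <- -map; flipped <- TRUE }
  structure(list(map = map, raw = raw, norm_scale = scale, flipped = flipped,
                 size = crop, full_size = n, px_per_deg = grid$px_per_deg,
                 k = cc$k, sf = cc$sf, ori = cc$ori,
                 sf_max = (crop / 2) * grid$px_per_deg / n,
                 center_ori = center_ori, sf_band = sf_band,
                 bin_counts = counts, n_trials = nt,
                 smoothed = smooth, spectra = spectra,
                 condition_label = condition$label,
                 stimulus_band = if (is.null(condition$spec)) NULL
                                 else c(condition$spec$sf_lo, condition$spec$sf_hi),
                 ori_axis = -90:89, profile_n_bins = op$n_bins,
                 trial_profiles = tp,
                 trial_sig = if (keep_trials) trials$signal_interval else NULL,
                 trial_correct = if (keep_trials) trials$correct else NULL),
            class = "classif_image")
}

#' @export
print.classif_image <- function(x, ...) {
  cat(sprintf("%s power-spectrum classification image ('%s', %d trials)\n",
              if (x$smoothed) "Smoothed" else "Raw", x$condition_label, x$n_trials))
  cat(sprintf("  %d x %d crop of %d x %d spectrum; DC to %.3g cy/deg on-axis\n",
              x$size, x$size, x$full_size, x$full_size, x$sf_max))
  cat("  trials per bin: ", paste(names(x$bin_counts), x$bin_counts,
                                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.classif_image <- function(x, ...) {
  lim <- max(abs(x$map))
  graphics::image(x$k, x$k, t(x$map), zlim = c(-lim, lim),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "horizontal frequency index",
                  ylab = "vertical frequency index", asp = 1, ...)
  invisible(x)
}

#' Crop a classification image about DC
#'
#' Retains the central `out_size x out_size` region of the (already centered)
#' classification image; the retained on-axis spatial-frequency range is
#' reported in the result's `sf_max`. Cropping to a smaller size discards the
#' stored per-trial profiles (they were collapsed over the original region).
#'
#' @param ci A `classif_image`.
#' @param out_size Output size in bins (even).
#' @return A `classif_image`.
#' @export
crop_center <- function(ci, out_size = 64) {
  stopifnot(inherits(ci, "classif_image"))
  m <- ci$size
  out_size <- as.integer(out_size)
  if (out_size > m) stop("'out_size' exceeds the classification image size")
  if (out_size %% 2 != 0) stop("'out_size' must be even")
  if (out_size == m) return(ci)
  keep <- (m / 2 - out_size / 2 + 1):(m / 2 + out_size / 2)
  ci$map <- ci$map[keep, keep]
  ci$raw <- ci$raw[keep, keep]
  ci$sf <- ci$sf[keep, keep]
  ci$ori <- ci$ori[keep, keep]
  ci$k <- ci$k[keep]
  ci$size <- out_size
  ci$sf_max <- (out_size / 2) * ci$px_per_deg / ci$full_size
  ci$trial_profiles <- NULL
  ci$trial_sig <- NULL
  ci$trial_correct <- NULL
  ci
}

# separable 2D convolution with reflected edges
conv2_sep <- function(x, k) {
  p <- (length(k) - 1) / 2
  n1 <- nrow(x); n2 <- ncol(x)
  ri <- c(p:1, 1:n1, n1:(n1 - p + 1))
  ci_ <- c(p:1, 1:n2, n2:(n2 - p + 1))
  xp <- x[ri, ci_]
  y <- apply(xp, 2, function(col) stats::filter(col, k, sides = 2))
  y <- y[(p + 1):(p + n1), ]
  y <- t(apply(y, 1, function(row) stats::filter(row, k, sides = 2)))
  y[, (p + 1):(p + n2)]
}

#' Smooth a classification image
#'
#' Convolution with a separable 5 x 5 triangular kernel
#' (`(1,2,3,2,1)/9` per axis, equivalent to linear interpolation), used to
#' reduce the trial-sampling noise of raw classification images. Edges are
#' handled by reflection so the crop borders are not darkened.
#'
#' @param ci A `classif_image`.
#' @param kernel Kernel name; only `"triangular5"` is defined.
#' @return The smoothed `classif_image` (`smoothed = TRUE`).
#' @export
smooth_ci <- function(ci, kernel = "triangular5") {
  stopifnot(inherits(ci, "classif_image"))
  kernel <- match.arg(kernel)
  k <- c(1, 2, 3, 2, 1) / 9
  ci$map <- conv2_sep(ci$map, k)
  ci$raw <- conv2_sep(ci$raw, k)
  ci$smoothed <- TRUE
  ci
}

# profile of the classification image built from a subset of trials
# (linear in the per-trial difference spectra, so it can be recomputed from
# the stored per-trial collapsed profiles)
ci_profile_from_trials <- function(ci, idx) {
  tp <- ci$trial_profiles
  if (is.null(tp)) stop("classification image lacks per-trial profiles")
  sig <- ci$trial_sig[idx]
  corr <- ci$trial_correct[idx]
  rows <- tp[idx, , drop = FALSE]
  g <- list(sig == 1L & corr, sig == 1L & !corr,
            sig == 2L & corr, sig == 2L & !corr)
  if (any(vapply(g, sum, 0L) == 0))
    stop("a signal-interval x correctness bin is empty in this resample")
  m <- lapply(g, function(s) colMeans(rows[s, , drop = FALSE]))
  w <- (m[[1]] + m[[3]]) / 2 - (m[[2]] + m[[4]]) / 2
  s <- w[which.max(abs(w))]
  structure(data.frame(ori = ci$ori_axis, weight = w / s, sum = w,
                       n_bins = ci$profile_n_bins),
            class = c("orientation_profile", "data.frame"))
}

#' Collapse a classification image to a 1D orientation profile
#'
#' Sums classification-image values in 1-degree orientation steps across a
#' spatial-frequency band, over the conjugate half-plane, yielding 180
#' weights on an axis of orientation relative to the signal center (-90 to
#' +89 degrees; equivalent to the [0, 180) view of the orientation circle).
#' The profile is normalized so its extreme value is +1.
#'
#' @param ci A `classif_image` (smooth first with [smooth_ci] if desired).
#' @param sf_band Spatial-frequency band (cy/deg); defaults to the band used
#'   when the image was computed (the whole crop unless specified).
#' @return An `orientation_profile` data frame with columns `ori` (degrees),
#'   `weight` (normalized), `sum` (raw sums), and `n_bins` (components per
#'   wedge).
#' @export
orientation_profile <- function(ci, sf_band = NULL) {
  stopifnot(inherits(ci, "classif_image"))
  if (is.null(sf_band)) sf_band <- ci$sf_band
  cc <- list(kx = matrix(ci$k, ci$size, ci$size, byrow = TRUE),
             ky = matrix(ci$k, ci$size, ci$size, byrow = FALSE),
             sf = ci$sf, ori = ci$ori)
  op <- collapse_operator(cc, ci$size, sf_band, ci$center_ori)
  if (any(op$n_bins == 0))
    warning("some 1-degree orientation bins contain no Fourier components; their values are 0")
  w <- as.vector(op$W %*% ci$map[op$sel])
  s <- w[which.max(abs(w))]
  structure(data.frame(ori = ci$ori_axis, weight = w / s, sum = w,
                       n_bins = op$n_bins),
            class = c("orientation_profile", "data.frame"))
}
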