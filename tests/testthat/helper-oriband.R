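# Shared fixtures: small grids and conditions used across test files.
# Tests run at 64 px with 16 px/deg: a 4-degree patch whose 1-octave band
# around 5 cy/deg occupies the same physical annulus as the full-scale
# stimuli, with Nyquist 8 cy/deg.

test_grid <- function(size = 64, ppd = 16) fourier_grid(size, ppd)

test_condition <- function(ori_bw = 48, size = 64, ppd = 16,
                           envelope = FALSE, ...) {
  noise_condition(test_grid(size, ppd), filter_spec(5, 1, 0, ori_bw),
                  envelope = envelope, ...)
}

# independent brute-force component classification used as the band_mask
# oracle: loops over integer frequency indices and classifies each bin from
# first principles (closed passbands, DC and Nyquist excluded)
brute_force_mask <- function(size, ppd, center_sf, sf_oct, center_ori, ori_bw) {
  lo <- center_sf * 2^(-sf_oct / 2)
  hi <- center_sf * 2^(sf_oct / 2)
  m <- matrix(FALSE, size, size)
  for (i in 1:size) {
    for (j in 1:size) {
      ky <- if (i - 1 <= size / 2) i - 1 else i - 1 - size
      kx <- if (j - 1 <= size / 2) j - 1 else j - 1 - size
      if (kx == 0 && ky == 0) next
      if (abs(kx) == size / 2 || abs(ky) == size / 2) next
      f <- sqrt(kx^2 + ky^2) * ppd / size
      if (f < lo - 1e-9 || f > hi + 1e-9) next
      # grating orientation: angle of the frequency vector from the vertical
      # frequency axis, folded onto [0, 90] distance from the filter center
      ang <- atan2(kx, ky) * 180 / pi
      d <- abs(ang - center_ori) %% 180
      d <- min(d, 180 - d)
      if (d <= ori_bw / 2 + 1e-9) m[i, j] <- TRUE
    }
  }
  m
}

# minimal classif_image wrapper around an arbitrary centered map, for testing
# the collapse and smoothing operators in isolation
fake_ci <- function(map, full_size, ppd, center_ori = 0, sf_band = NULL) {
  m <- nrow(map)
  cc <- oriband:::crop_coords(full_size, m, ppd)
  if (is.null(sf_band)) sf_band <- c(0, (m / 2) * ppd / full_size)
  structure(list(map = map, raw = map, size = m, full_size = full_size,
                 px_per_deg = ppd, k = cc$k, sf = cc$sf, ori = cc$ori,
                 sf_max = (m / 2) * ppd / full_size, center_ori = center_ori,
                 sf_band = sf_band, smoothed = FALSE,
                 ori_axis = -90:89),
            class = "classif_image")
}

# centered (DC in the middle) rearrangement of a DFT-layout matrix
fftshift2 <- function(x) {
  n <- nrow(x)
  idx <- c((n / 2 + 1):n, 1:(n / 2))
  x[idx, idx]
}

# Monte-Carlo percent correct for an observer at a fixed contrast
mc_percent_correct <- function(observer, condition, contrast, n_trials,
                               signal_intervals = NULL) {
  if (is.null(signal_intervals))
    signal_intervals <- sample(rep_len(c(1L, 2L), n_trials))
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    st <- oriband:::trial_stimuli(condition, contrast, signal_intervals[i],
                                  sample.int(2147483646L, 3))
    correct[i] <- decide_2ifc(observer, st$Pstim1, st$Pstim2) ==
      signal_intervals[i]
  }
  mean(correct)
}
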