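# Two shared fixed-contrast runs (ideal and inhibitory-surround observers),
# computed once and reused by the template-recovery, negativity, profile, and
# smoothing tests below.
set.seed(62)
ci_cond <- test_condition(48, size = 64, envelope = TRUE)
ci_ideal_obs <- ideal_template(ci_cond$grid, ci_cond$spec)
ci_ideal_tl <- run_fixed_contrast_session(
  ci_ideal_obs, ci_cond, analytic_threshold(ci_ideal_obs, ci_cond), 2500)
ci_ideal <- suppressWarnings(
  classification_image(ci_ideal_tl, crop = 64, keep_trials = TRUE))

ci_cond90 <- test_condition(90, size = 64, envelope = TRUE)
ci_dog_obs <- dog_template(ci_cond90$grid, dog_params(0, 30, 90),
                           c(ci_cond90$spec$sf_lo, ci_cond90$spec$sf_hi))
ci_dog_tl <- run_fixed_contrast_session(
  ci_dog_obs, ci_cond90, analytic_threshold(ci_dog_obs, ci_cond90), 2500)
ci_dog <- suppressWarnings(
  classification_image(ci_dog_tl, crop = 64, keep_trials = TRUE))

test_that("trial bins partition the session and empty bins are named errors", {
  set.seed(60)
  cond <- test_condition(48, size = 32)
  obs <- ideal_template(cond$grid, cond$spec)
  tl <- run_fixed_contrast_session(obs, cond,
                                   analytic_threshold(obs, cond), 400)
  ci <- suppressWarnings(classification_image(tl, crop = 32))
  expect_identical(sum(ci$bin_counts), 400L)
  expect_true(all(ci$bin_counts > 0))
  # a log with no incorrect signal-in-2 trials triggers a named error
  bad <- tl[!(tl$signal_interval == 2L & !tl$correct), ]
  attr(bad, "condition") <- cond
  expect_error(suppressWarnings(classification_image(bad, crop = 32)),
               "sig2_incorrect")
})

test_that("a weightless (random) observer yields a near-zero classification image", {
  set.seed(61)
  cond <- test_condition(48, size = 32)
  obs <- template_observer(matrix(0, 32, 32), internal_noise_sd = 1)
  tl <- run_fixed_contrast_session(obs, cond, 0.1, 1200)
  ci <- suppressWarnings(classification_image(tl, crop = 32))
  # per-bin difference spectra have SD ~ sqrt(2) * mask variance; the CI
  # variance is var(D) * (1/4) * sum(1/n_bin) ~ var(D) / (n/4)
  se <- sqrt(2) * 0.32 / sqrt(nrow(tl) / 4)
  z <- ci$raw / se
  expect_lt(mean(abs(z) > 3), 0.01)   # no more than the Gaussian tail share
  expect_lt(abs(mean(z)), 0.2)
})

test_that("the classification image recovers a linear template", {
  w_centered <- fftshift2(ci_ideal_obs$weights)
  # the raw estimator is noisy at 2500 trials (per-component SNR ~ 1/sqrt(N));
  # the triangular smoothing step recovers the template shape cleanly
  expect_gt(cor(as.vector(ci_ideal$raw), as.vector(w_centered)), 0.5)
  cs <- smooth_ci(ci_ideal)
  ws <- oriband:::conv2_sep(w_centered, c(1, 2, 3, 2, 1) / 9)
  expect_gt(cor(as.vector(cs$raw), as.vector(ws)), 0.8)
  # the map is normalized to peak 1 with a positive signal band
  expect_equal(max(abs(ci_ideal$map)), 1)
  expect_gt(mean(ci_ideal$map[w_centered > 0]), 0)
  # no systematic negative region for the ideal observer: in the smoothed
  # image the band is far above the noise floor and strongly negative bins
  # are no more common than the sampling-noise tail
  sd_out <- sd(cs$map[ws == 0])
  expect_lt(mean(cs$map < -4 * sd_out), 0.001)
  expect_gt(mean(cs$map[w_centered > 0]), 5 * sd_out)
})

test_that("the ideal observer's orientation profile is rectangular over the band", {
  prof <- suppressWarnings(orientation_profile(ci_ideal))
  inside <- abs(prof$ori) <= 20 & prof$n_bins > 0
  outside <- abs(prof$ori) >= 35 & prof$n_bins > 0
  expect_gt(mean(prof$weight[inside]), 0.5)
  expect_lt(mean(abs(prof$weight[outside])), 0.25)
})

test_that("an inhibitory-surround template produces negative classification-image regions", {
  w_centered <- fftshift2(ci_dog_obs$weights)
  expect_gt(cor(as.vector(ci_dog$raw), as.vector(w_centered)), 0.5)
  cs <- smooth_ci(ci_dog)
  ws <- oriband:::conv2_sep(w_centered, c(1, 2, 3, 2, 1) / 9)
  expect_gt(cor(as.vector(cs$raw), as.vector(ws)), 0.8)
  # the far-orientation flank (negative template weights) is recovered dark
  expect_lt(mean(ci_dog$map[w_centered < 0]), 0)
  prof <- suppressWarnings(orientation_profile(ci_dog))
  flank <- abs(prof$ori) > 60 & prof$n_bins > 0
  expect_lt(mean(prof$weight[flank]), 0)
})

test_that("profiles recomputed from per-trial data match the image profile", {
  p1 <- suppressWarnings(orientation_profile(ci_dog))
  p2 <- ci_profile_from_trials(ci_dog, seq_len(nrow(ci_dog$trial_profiles)))
  # both are normalized to peak 1; the underlying sums are proportional
  expect_equal(p1$weight, p2$weight, tolerance = 1e-10)
})

test_that("cropping keeps DC centered, reports the retained band, and is idempotent", {
  c32 <- crop_center(ci_ideal, 32)
  expect_identical(c32$size, 32L)
  expect_equal(c32$sf[17, 17], 0)                      # DC stays centered
  expect_equal(c32$sf_max, 16 * 16 / 64)               # 4 cy/deg retained
  expect_identical(crop_center(c32, 32), c32)          # idempotent
  expect_equal(c32$map, ci_ideal$map[17:48, 17:48])
  expect_error(crop_center(c32, 64), "exceeds")
})

test_that("the retained frequency range follows the crop geometry", {
  set.seed(64)
  cond <- test_condition(48, size = 32)
  obs <- ideal_template(cond$grid, cond$spec)
  tl <- run_fixed_contrast_session(obs, cond, 0.1, 60)
  ci <- suppressWarnings(classification_image(tl, crop = 16))
  expect_equal(ci$sf_max, 8 * 16 / 32)
})

test_that("triangular smoothing preserves constants, spreads impulses, reduces noise", {
  k <- c(1, 2, 3, 2, 1) / 9
  const <- matrix(2.5, 20, 20)
  expect_equal(oriband:::conv2_sep(const, k), const, tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- oriband:::conv2_sep(imp, k)
  expect_equal(sm[9:13, 9:13], outer(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 1)) / 81,
               tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # kernel is normalized
  set.seed(65)
  noise <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(var(as.vector(oriband:::conv2_sep(noise, k))),
            0.5 * var(as.vector(noise)))
  cs <- smooth_ci(ci_ideal)
  expect_true(cs$smoothed)
  # smoothing shrinks the out-of-band noise floor
  w_centered <- fftshift2(ci_ideal_obs$weights)
  expect_lt(sd(cs$map[w_centered == 0]), sd(ci_ideal$map[w_centered == 0]))
})

test_that("collapse is peaked at the band center and equivariant to rotation", {
  g <- fourier_grid(64, 16)
  m0 <- fftshift2(band_mask(g, filter_spec(5, 1, 0, 16)) * 1)
  m90 <- fftshift2(band_mask(g, filter_spec(5, 1, 90, 16)) * 1)
  p0 <- suppressWarnings(orientation_profile(fake_ci(m0, 64, 16)))
  p90 <- suppressWarnings(orientation_profile(fake_ci(m90, 64, 16)))
  expect_lt(abs(p0$ori[which.max(p0$weight)]), 9)
  # rotating the image by 90 degrees moves the profile peak to +-90
  expect_gte(abs(p90$ori[which.max(p90$weight)]), 81)
  # wedge sums outside the band are zero for a mask image
  expect_true(all(p0$weight[abs(p0$ori) > 12 & p0$n_bins > 0] == 0))
})
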