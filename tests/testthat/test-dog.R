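test_that("dog_eval has the constrained center value, symmetry, and crossing point", {
  p <- dog_params(0, 20, 60, amp_i = 1.3)
  expect_equal(dog_eval(p, 0), 1.3)                      # A_e - A_i = A_i
  d <- c(5, 17, 40, 80)
  expect_equal(dog_eval(p, d), dog_eval(p, -d))          # even about the center
  p2 <- dog_params(10, 20, 60)
  expect_equal(dog_eval(p2, 10 + d), dog_eval(p2, 10 - d))
  # closed-form zero crossing: d* = se*si*sqrt(2*log(2)/(si^2 - se^2))
  dstar <- 20 * 60 * sqrt(2 * log(2) / (60^2 - 20^2))
  expect_lt(dog_eval(p, dstar + 1e-6) * dog_eval(p, dstar - 1e-6), 0)
  expect_equal(dog_eval(p, dstar), 0, tolerance = 1e-9)
  # wrapping: evaluation is periodic on the orientation circle
  expect_equal(dog_eval(p, 170), dog_eval(p, -10))
})

test_that("the DoG integral matches its closed form when wrap is negligible", {
  p <- dog_params(0, 5, 12, amp_i = 0.7)
  th <- seq(-90, 90, by = 0.01)
  num <- sum(dog_eval(p, th)) * 0.01
  closed <- 0.7 * sqrt(2 * pi) * (2 * 5 - 12)
  expect_equal(num, closed, tolerance = 1e-6)
})

test_that("constructor enforces the channel constraints", {
  expect_error(dog_params(0, 60, 20), "smaller")
  expect_error(dog_params(0, 20, 20), "smaller")
  expect_error(dog_params(0, -5, 20), "positive")
  expect_error(dog_params(0, 5, 20, amp_i = 0), "positive")
  expect_equal(dog_params(0, 20, 60, 2)$amp_e, 4)        # 2:1 ratio enforced
})

test_that("noiseless profiles are recovered essentially exactly", {
  gen <- dog_params(3, 22, 70, amp_i = 1)
  prof <- data.frame(ori = -90:89, weight = dog_eval(gen, -90:89))
  f <- fit_dog(prof)
  expect_lt(abs(f$params$mu - 3) / 3, 1e-5)
  expect_lt(abs(f$params$sigma_e - 22) / 22, 1e-5)
  expect_lt(abs(f$params$sigma_i - 70) / 70, 1e-5)
  expect_lt(f$rss, 1e-10)
  # the DoG fits these data better than a single Gaussian
  expect_lt(f$rss, f$rss_single_gaussian)
})

test_that("a symmetric profile yields a center near zero under noise", {
  set.seed(70)
  gen <- dog_params(0, 25, 75)
  for (i in 1:3) {
    prof <- data.frame(ori = -90:89,
                       weight = dog_eval(gen, -90:89) + rnorm(180, 0, 0.05))
    f <- fit_dog(prof)
    expect_lt(abs(f$params$mu), 5)
    expect_lt(abs(f$params$sigma_e - 25), 6)
  }
})

test_that("surround-free data drive the fit to the constraint boundary with a warning", {
  # a pure single Gaussian asks for no inhibitory surround; the exact
  # least-squares optimum of the constrained family sits on the
  # sigma_e = sigma_i boundary (where the DoG collapses to one Gaussian)
  th <- -90:89
  w <- exp(-th^2 / (2 * 25^2))
  expect_warning(f <- fit_dog(data.frame(ori = th, weight = w)), "binding")
  expect_lt(f$params$sigma_i - f$params$sigma_e, 0.1)
  expect_lt(f$rss, 1e-4)
})

test_that("wedges without Fourier components are excluded from fitting", {
  gen <- dog_params(0, 25, 75)
  prof <- data.frame(ori = -90:89, weight = dog_eval(gen, -90:89),
                     n_bins = rep(10L, 180))
  # zero out some wedges as a coarse grid would
  holes <- c(10, 50, 90, 130, 170)
  prof$weight[holes] <- 0
  prof$n_bins[holes] <- 0L
  f <- fit_dog(prof)
  expect_lt(abs(f$params$sigma_e - 25), 0.1)
  expect_lt(abs(f$params$sigma_i - 75), 0.5)
})

test_that("degenerate (noise-free) trial profiles collapse the bootstrap CI", {
  gen <- dog_params(0, 25, 75)
  base <- dog_eval(gen, -90:89)
  nt <- 40
  corr <- rep(c(TRUE, FALSE, TRUE, FALSE), nt / 4)
  # noise-free within bins: every correct trial carries profile 1.5*base,
  # every incorrect trial 0.5*base, so any resample gives the same image
  tp <- matrix(rep(base, each = nt), nt, 180) * ifelse(corr, 1.5, 0.5)
  ci <- structure(list(
    trial_profiles = tp,
    trial_sig = rep(c(1L, 1L, 2L, 2L), nt / 4),
    trial_correct = corr,
    ori_axis = -90:89, profile_n_bins = rep(10L, 180)),
    class = "classif_image")
  b <- bootstrap_dog(ci, n_boot = 30)
  expect_lt(b$ci["sigma_e", 2] - b$ci["sigma_e", 1], 1e-3)
  expect_lt(b$ci["sigma_i", 2] - b$ci["sigma_i", 1], 1e-2)
  expect_equal(unname(b$ci["sigma_e", 1]), 25, tolerance = 1e-3)
})

test_that("bandwidth trends recover slopes and percent increases", {
  bws <- c(2, 48, 90)
  # constant channel: zero slope, zero increase
  tr0 <- bandwidth_trend(bws, c(25, 25, 25), c(75, 75, 75))
  expect_equal(tr0$slope_e, 0, tolerance = 1e-12)
  expect_equal(tr0$pct_increase_e, 0, tolerance = 1e-10)
  expect_equal(tr0$pct_increase_i, 0, tolerance = 1e-10)
  # the adjustable generating values scale by 50% (the fitted line's
  # endpoints differ slightly since the three conditions are not collinear)
  tr <- bandwidth_trend(bws, c(20, 25, 30), c(60, 75, 90))
  expect_lt(abs(tr$pct_increase_e - 50), 0.5)
  expect_lt(abs(tr$pct_increase_i - 50), 0.5)
  # a 30-degree increment has three times the slope of a 10-degree increment
  expect_gt(tr$slope_i, tr$slope_e)
  expect_equal(tr$slope_i / tr$slope_e, 3, tolerance = 1e-8)
  expect_error(bandwidth_trend(2, 25, 75), "2 conditions")
})
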