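test_that("the ideal template is the band indicator with no internal noise", {
  g <- test_grid()
  sp <- filter_spec(5, 1, 0, 48)
  obs <- ideal_template(g, sp)
  expect_identical(obs$weights, band_mask(g, sp) * 1)
  expect_identical(obs$internal_noise_sd, 0)
  expect_error(ideal_template(g, filter_spec(5, 0.001, 77.7, 0.4)), "empty")
})

test_that("observer constructors reject asymmetric weights and bad noise", {
  w <- matrix(0, 16, 16); w[2, 3] <- 1
  expect_error(template_observer(w), "symmetric")
  expect_error(template_observer(matrix(0, 16, 16), internal_noise_sd = -1),
               "non-negative")
})

test_that("at zero signal contrast choice accuracy is at chance", {
  set.seed(10)
  cond <- test_condition(48)
  obs <- ideal_template(cond$grid, cond$spec)
  n <- 4000
  si <- sample(rep_len(c(1L, 2L), n))
  correct <- logical(n)
  for (i in seq_len(n)) {
    st <- oriband:::trial_stimuli(cond, 0, si[i], sample.int(2147483646L, 3))
    correct[i] <- decide_2ifc(obs, st$Pstim1, st$Pstim2) == si[i]
  }
  expect_lt(abs(mean(correct) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("accuracy is nondecreasing in signal contrast", {
  set.seed(11)
  cond <- test_condition(48)
  obs <- ideal_template(cond$grid, cond$spec)
  contrasts <- analytic_threshold(obs, cond) * c(0.3, 0.6, 1, 1.7, 3)
  pc <- vapply(contrasts, function(cc) mc_percent_correct(obs, cond, cc, 800), 0)
  # true percent correct is strictly increasing at these spacings; allow
  # Monte-Carlo jitter
  expect_true(all(diff(pc) > -0.02))
  expect_gt(pc[5], 0.95)
  expect_lt(pc[1], 0.65)
})

test_that("DoG templates have the constrained center value and negative flanks", {
  g <- test_grid()
  dog <- dog_params(0, 25, 75, amp_i = 0.8)
  obs <- dog_template(g, dog, c(5 * 2^-0.5, 5 * 2^0.5))
  # center-orientation bins carry weight A_e - A_i = A_i
  ctr <- which(g$ori == 0 & obs$weights != 0)
  expect_true(all(abs(obs$weights[ctr] - 0.8) < 1e-12))
  # 90 degrees off-center the surround dominates: weights are negative
  flank <- which(g$ori == 90 & g$sf >= 5 * 2^-0.5 & g$sf <= 5 * 2^0.5 &
                   abs(g$kx) != 32 & abs(g$ky) != 32)
  expect_true(all(obs$weights[flank] < 0))
  # the weight map is an evaluation of the DoG at each bin's orientation
  inb <- obs$weights != 0
  expect_equal(obs$weights[inb], dog_eval(dog, g$ori[inb]))
})

test_that("a vanishing surround reduces the DoG to a single Gaussian", {
  th <- seq(-90, 89)
  dog <- dog_params(0, 20, 5000, amp_i = 1)
  # subtracting the (flat, ~ -A_i) surround leaves the excitatory Gaussian
  resid <- dog_eval(dog, th) + 1 - 2 * exp(-th^2 / (2 * 20^2))
  expect_lt(max(abs(resid)), 1e-3)
})

test_that("2-IFC decisions are deterministic, tie-break to interval 1, and follow energy", {
  g <- test_grid()
  sp <- filter_spec(5, 1, 0, 48)
  obs <- ideal_template(g, sp)
  P <- matrix(1, 64, 64)
  expect_identical(decide_2ifc(obs, P, P), 1L)   # tie
  P2 <- P
  P2[band_mask(g, sp)] <- 2                       # extra in-band energy
  expect_identical(decide_2ifc(obs, P, P2), 2L)
  expect_identical(decide_2ifc(obs, P2, P), 1L)
  expect_error(decide_2ifc(obs, matrix(1, 32, 32), P), "grid")
})

test_that("percent correct matches the closed-form normal approximation", {
  # expected-rescale, unenveloped signals make the analytic moments exact
  set.seed(12)
  cond <- test_condition(90)
  obs <- ideal_template(cond$grid, cond$spec)
  n <- 4000
  contrast <- analytic_threshold(obs, cond, pc = 0.8)
  si <- sample(rep_len(c(1L, 2L), n))
  correct <- logical(n)
  for (i in seq_len(n)) {
    m1 <- white_noise(64, 0.32); m2 <- white_noise(64, 0.32)
    sig <- filtered_noise(cond$grid, cond$mask, contrast, rescale = "expected")
    if (si[i] == 1L) m1 <- m1 + sig else m2 <- m2 + sig
    correct[i] <- decide_2ifc(obs, power_spectrum(m1), power_spectrum(m2)) == si[i]
  }
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(mean(correct) - 0.8), 2.5 * se)
})

test_that("decisions show no interval bias", {
  set.seed(13)
  cond <- test_condition(48)
  obs <- ideal_template(cond$grid, cond$spec)
  contrast <- analytic_threshold(obs, cond)
  n <- 3000
  si <- rep(c(1L, 2L), each = n / 2)
  correct <- logical(n)
  for (i in seq_len(n)) {
    st <- oriband:::trial_stimuli(cond, contrast, si[i],
                                  sample.int(2147483646L, 3))
    correct[i] <- decide_2ifc(obs, st$Pstim1, st$Pstim2) == si[i]
  }
  p1 <- mean(correct[si == 1L]); p2 <- mean(correct[si == 2L])
  expect_gt(stats::prop.test(c(sum(correct[si == 1L]), sum(correct[si == 2L])),
                             c(n / 2, n / 2))$p.value, 0.001)
  expect_lt(abs(p1 - p2), 0.05)
})

test_that("closed-form efficiency is exact for scaled ideal templates and trivial cases", {
  g <- test_grid()
  sp <- filter_spec(5, 1, 0, 48)
  cond <- noise_condition(g, sp, envelope = FALSE)
  ideal <- ideal_template(g, sp)
  expect_equal(template_efficiency(ideal, cond), 1)
  # scaling a template cannot change its efficiency
  half <- template_observer(ideal$weights * 0.5)
  expect_equal(template_efficiency(half, cond), 1)
  # a template on half the band: eta = sqrt(N_half / N)
  sp2 <- filter_spec(5, 1, 0, 24)
  half_band <- ideal_template(g, sp2)
  expect_equal(template_efficiency(half_band, cond),
               sqrt(component_count(band_mask(g, sp2)) /
                      component_count(band_mask(g, sp))),
               tolerance = 1e-12)
})

test_that("internal-noise calibration hits the target percent correct", {
  g <- test_grid()
  sp <- filter_spec(5, 1, 0, 48)
  cond <- noise_condition(g, sp, envelope = FALSE)
  obs <- ideal_template(g, sp)
  c80 <- analytic_threshold(obs, cond, pc = 0.9)
  cal <- calibrate_internal_noise(obs, cond, c80, target_pc = 0.75)
  expect_gt(cal$internal_noise_sd, 0)
  expect_equal(analytic_proportion_correct(cal, cond, c80), 0.75,
               tolerance = 1e-6)
  expect_error(calibrate_internal_noise(obs, cond, c80, target_pc = 0.95),
               "exceeds")
})
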