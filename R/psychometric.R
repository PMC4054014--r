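#' Fit a cumulative-normal psychometric function
#'
#' Maximum-likelihood fit of a cumulative normal on log10 contrast to 2-IFC
#' trial data, with the lower asymptote anchored at the guessing rate (0.5)
#' and a fixed lapse rate (0 by default):
#' `p(x) = guess + (1 - guess - lapse) * pnorm((x - mu) / sigma)`.
#' The detection threshold is the RMS contrast at 75% correct; with guess
#' 0.5 and lapse 0 this is `10^mu`.
#'
#' @param trials A `trial_log` or any data frame with numeric `contrast` and
#'   logical `correct`.
#' @param guess Guessing rate (lower asymptote), fixed.
#' @param lapse Lapse rate, fixed.
#' @return Object of class `psychfit`: `coef` (`mu` on log10 contrast,
#'   `sigma`), `se` (delta-method SEs, may be `NA` if the information matrix
#'   is singular), `threshold` (75% point), `logLik`, `convergence`, `n`, and
#'   the data.
#' @export
fit_psychometric <- function(trials, guess = 0.5, lapse = 0) {
  stopifnot(is.data.frame(trials),
            all(c("contrast", "correct") %in% names(trials)))
  contrast <- trials$contrast
  correct <- as.logical(trials$correct)
  if (any(contrast <= 0)) stop("contrasts must be positive")
  if (length(unique(contrast)) < 2)
    stop("need at least 2 distinct contrast levels")
  if (all(correct) || all(!correct))
    stop("degenerate data: all responses ", if (all(correct)) "correct" else "incorrect")
  x <- log10(contrast)
  span <- 1 - guess - lapse
  # aggregate to binomial counts per contrast level; the log-likelihood is
  # identical up to a data-only constant and fits stay fast for long sessions
  lev <- sort(unique(x))
  kc <- as.vector(rowsum(as.numeric(correct), x))
  nc <- as.vector(rowsum(rep(1, length(x)), x))
  nll <- function(par) {
    p <- guess + span * stats::pnorm((lev - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(kc * log(p) + (nc - kc) * log(1 - p))
  }
  lower <- c(min(x) - 2, log(1e-3))
  upper <- c(max(x) + 2, log(3))
  best <- NULL
  for (mu0 in stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
    for (s0 in c(0.05, 0.15, 0.4)) {
      f <- tryCatch(
        stats::optim(c(mu0, log(s0)), nll, method = "L-BFGS-B",
                     lower = lower, upper = upper, hessian = FALSE,
                     control = list(factr = 1e5)),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
  if (is.null(best)) stop("psychometric fit failed to converge from all starts")
  h <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  se <- c(NA_real_, NA_real_)
  if (!is.null(h)) {
    v <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(v) && all(diag(v) > 0)) {
      se[1] <- sqrt(v[1, 1])
      se[2] <- sqrt(v[2, 2]) * exp(best$par[2])  # delta method for sigma
    }
  }
  mu <- best$par[1]; sigma <- exp(best$par[2])
  q75 <- (0.75 - guess) / span
  thr <- 10^(mu + sigma * stats::qnorm(pmin(pmax(q75, 1e-9), 1 - 1e-9)))
  structure(list(coef = c(mu = mu, sigma = sigma), se = se,
                 threshold = thr, logLik = -best$value,
                 convergence = best$convergence, n = length(x),
                 guess = guess, lapse = lapse,
                 data = data.frame(contrast = contrast, correct = correct)),
            class = "psychfit")
}

#' Threshold at an arbitrary percent-correct level
#'
#' @param fit A `psychfit`.
#' @param pc Proportion correct (must lie between the guess rate and
#'   `1 - lapse`).
#' @return RMS contrast at the requested performance level.
#' @export
detection_threshold <- function(fit, pc = 0.75) {
  stopifnot(inherits(fit, "psychfit"))
  span <- 1 - fit$guess - fit$lapse
  q <- (pc - fit$guess) / span
  if (q <= 0 || q >= 1) stop("'pc' outside the attainable range of the fit")
  10^(fit$coef[["mu"]] + fit$coef[["sigma"]] * stats::qnorm(q))
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Cumulative-normal psychometric fit (n = %d trials)\n", x$n))
  cat(sprintf("  mu = %.4f (SE %.4f) log10 contrast, sigma = %.4f\n",
              x$coef[["mu"]], x$se[1], x$coef[["sigma"]]))
  cat(sprintf("  75%%-correct threshold: %.5g RMS contrast\n", x$threshold))
  if (x$convergence != 0) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) object$coef

#' @export
predict.psychfit <- function(object, contrast = NULL, ...) {
  if (is.null(contrast)) contrast <- object$data$contrast
  span <- 1 - object$guess - object$lapse
  object$guess + span * stats::pnorm(
    (log10(contrast) - object$coef[["mu"]]) / object$coef[["sigma"]])
}

#' @export
plot.psychfit <- function(x, n_bins = 8, ...) {
  d <- x$data
  br <- stats::quantile(log10(d$contrast), seq(0, 1, length.out = n_bins + 1))
  g <- cut(log10(d$contrast), unique(br), include.lowest = TRUE)
  pc <- tapply(d$correct, g, mean)
  cc <- tapply(d$contrast, g, function(z) exp(mean(log(z))))
  graphics::plot(cc, pc, log = "x", ylim = c(0.4, 1), pch = 16,
                 xlab = "RMS contrast", ylab = "proportion correct", ...)
  cs <- 10^seq(min(log10(d$contrast)), max(log10(d$contrast)), length.out = 200)
  graphics::lines(cs, predict(x, cs), col = "blue")
  graphics::abline(h = 0.75, v = x$threshold, lty = 3)
  invisible(x)
}
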