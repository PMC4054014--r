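#' Noise-in-noise detection condition
#'
#' Bundles everything that defines one stimulus condition: the Fourier grid,
#' the signal band (or an unfiltered white-noise target), the white-noise
#' mask variance, and the signal contrast envelope. The component mask and
#' count, and the envelope, are precomputed.
#'
#' @param grid A [fourier_grid]. Defaults to the full-scale stimulus grid
#'   (512 px at 94.8 px/deg).
#' @param spec A [filter_spec] for the signal band, or `NULL` for an
#'   unfiltered white-noise target (all usable components).
#' @param mask_variance Contrast variance of the white-noise mask (0.32 in
#'   all conditions).
#' @param envelope_sd Gaussian contrast envelope SD in degrees (1.08);
#'   applied to the signal only.
#' @param envelope Logical; window the signal with the Gaussian envelope.
#' @param label Condition label; derived from the spec when omitted.
#' @return Object of class `noise_condition`.
#' @export
noise_condition <- function(grid = fourier_grid(512, 94.8), spec = NULL,
                            mask_variance = 0.32, envelope_sd = 1.08,
                            envelope = TRUE, label = NULL) {
  stopifnot(inherits(grid, "fourier_grid"))
  if (mask_variance < 0) stop("'mask_variance' must be non-negative")
  mask <- if (is.null(spec)) full_component_mask(grid) else band_mask(grid, spec)
  if (is.null(label))
    label <- if (is.null(spec)) "white" else
      sprintf("ori%g_sf%goct", spec$ori_bandwidth, spec$sf_bandwidth)
  structure(list(grid = grid, spec = spec, mask = mask,
                 n_components = component_count(mask),
                 mask_variance = mask_variance,
                 mask_sd = sqrt(mask_variance),
                 envelope = envelope, envelope_sd = envelope_sd,
                 env = if (envelope) gaussian_envelope(grid$size, envelope_sd,
                                                      grid$px_per_deg) else NULL,
                 label = label),
            class = "noise_condition")
}

#' @export
print.noise_condition <- function(x, ...) {
  cat(sprintf("Condition '%s': %d px grid, %d components, mask variance %.3g%s\n",
              x$label, x$grid$size, x$n_components, x$mask_variance,
              if (x$envelope) sprintf(", signal envelope SD %.3g deg", x$envelope_sd)
              else ", no envelope"))
  if (!is.null(x$spec)) print(x$spec)
  invisible(x)
}

# DFT of a white Gaussian pixel field with the given pixel SD, synthesized
# directly in the frequency domain: per-bin coefficients are independent
# complex Gaussians under Hermitian symmetry, with variance n^2 sd^2 (real
# self-conjugate bins included). Distributionally identical to
# fft(matrix(rnorm(n^2, 0, sd), n, n)) but cheaper, and lets sessions and
# classification-image replay skip the mask transforms entirely.
spectral_white_field <- function(n, sd) {
  s <- n * sd / sqrt(2)
  Z <- matrix(complex(real = stats::rnorm(n * n, 0, s),
                      imaginary = stats::rnorm(n * n, 0, s)), n, n)
  ci <- conjugate_index(n)
  (Z + Conj(Z[ci, ci])) / sqrt(2)
}

# Regenerate one trial's stimuli from its seeds. Generation order is fixed
# (mask 1, mask 2, signal) so stored seeds replay the session exactly.
# Spectra follow the power_spectrum normalization (|X|^2 / n^2).
trial_stimuli <- function(condition, contrast, signal_interval, seeds,
                          what = c("stimulus", "mask", "both")) {
  what <- match.arg(what)
  n <- condition$grid$size
  n2 <- n * n
  set.seed(seeds[1])
  M1 <- spectral_white_field(n, condition$mask_sd)
  set.seed(seeds[2])
  M2 <- spectral_white_field(n, condition$mask_sd)
  out <- list()
  if (what %in% c("mask", "both")) {
    out$Pmask1 <- Mod(M1)^2 / n2
    out$Pmask2 <- Mod(M2)^2 / n2
  }
  if (what %in% c("stimulus", "both")) {
    if (contrast > 0) {
      set.seed(seeds[3])
      S <- spectral_white_field(n, 1)
      S[!condition$mask] <- 0
      if (condition$envelope) {
        sig <- Re(stats::fft(S, inverse = TRUE)) / n2
        sig <- sig * (contrast / sqrt(mean(sig^2))) * condition$env
        S <- stats::fft(sig)
      } else {
        S <- S * (contrast / (sqrt(sum(Mod(S)^2)) / n2))  # Parseval: rms = sqrt(sum|S|^2)/n^2
      }
      if (signal_interval == 1L) M1 <- M1 + S else M2 <- M2 + S
    }
    out$Pstim1 <- Mod(M1)^2 / n2
    out$Pstim2 <- Mod(M2)^2 / n2
  }
  out
}
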