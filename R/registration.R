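# Cross-correlation drift registration for time-lapse AFM stacks.
#
# Thermal drift between frames is a slow, almost purely translational
# motion, so translation-only registration by phase/cross correlation is
# the appropriate model. Subpixel refinement uses a locally upsampled
# discrete Fourier transform of the cross-power spectrum (matrix-multiply
# DFT around the integer peak), so no large upsampled array is formed.

# Cross-correlation surface between equally sized matrices via FFT.
cross_corr_fft <- function(a, b) {
  A <- stats::fft(a - mean(a))
  B <- stats::fft(b - mean(b))
  R <- A * Conj(B)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(a)
  list(corr = r, spectrum = R)
}

# Evaluate the cross-correlation on a fine grid around (dr0, dc0) by a
# matrix-multiply DFT of the cross-power spectrum (Guizar-Sicairos style).
refine_peak_dft <- function(spectrum, dr0, dc0, upsample = 10, halfwidth = 1.5) {
  n <- dim(spectrum)
  kr <- c(0:(ceiling(n[1] / 2) - 1), -(floor(n[1] / 2)):-1)
  kc <- c(0:(ceiling(n[2] / 2) - 1), -(floor(n[2] / 2)):-1)
  us <- seq(dr0 - halfwidth, dr0 + halfwidth, by = 1 / upsample)
  vs <- seq(dc0 - halfwidth, dc0 + halfwidth, by = 1 / upsample)
  Er <- exp(2i * pi * outer(us, kr) / n[1])           # |us| x n1
  Ec <- exp(2i * pi * outer(kc, vs) / n[2])           # n2 x |vs|
  surf <- Re(Er %*% spectrum %*% Ec) / length(spectrum)
  pk <- which(surf == max(surf), arr.ind = TRUE)[1, ]
  c(us[pk[1]], vs[pk[2]])
}

# Estimate the (row, col) shift of b relative to a: b(x) ~ a(x - shift).
estimate_shift <- function(a, b, upsample = 10) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    return(list(shift = c(0, 0), failed = TRUE))
  cc <- cross_corr_fft(a, b)
  r <- cc$corr
  n <- dim(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  dr <- pk[1] - 1L; dc <- pk[2] - 1L
  if (dr > n[1] / 2) dr <- dr - n[1]
  if (dc > n[2] / 2) dc <- dc - n[2]
  # Peak-quality check: flag featureless images whose correlation surface
  # has no dominant peak anywhere. The exclusion zone around the peak is
  # generous because smooth structures (a fiber ridge) give a broad but
  # still unambiguous correlation maximum along their axis.
  peak <- max(r)
  hw1 <- max(3L, round(0.2 * n[1]))
  hw2 <- max(3L, round(0.2 * n[2]))
  away <- r
  rr <- ((pk[1] - 1L) + (-hw1):hw1) %% n[1] + 1L
  cc2 <- ((pk[2] - 1L) + (-hw2):hw2) %% n[2] + 1L
  away[rr, cc2] <- NA
  runner <- suppressWarnings(max(away, na.rm = TRUE))
  failed <- !is.finite(peak) || peak <= 0 ||
    (is.finite(runner) && runner > 0 && peak / runner < 1.01)
  shift <- c(dr, dc)
  if (!failed && upsample > 1)
    shift <- refine_peak_dft(cc$spectrum, dr, dc, upsample)
  list(shift = -shift, failed = failed)
}

# Integer translation with fill; positive dr moves content down/right.
translate_int <- function(m, dr, dc, fill = NA_real_) {
  n <- dim(m)
  out <- matrix(fill, n[1], n[2])
  src_r <- seq_len(n[1]) - dr
  src_c <- seq_len(n[2]) - dc
  ok_r <- src_r >= 1 & src_r <= n[1]
  ok_c <- src_c >= 1 & src_c <= n[2]
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register a frame stack against a reference frame
#'
#' Estimates the translational drift of every frame relative to a reference
#' frame by FFT cross-correlation of the height channel, with subpixel peak
#' refinement by a locally upsampled DFT. Frames are shifted back by the
#' rounded offsets and the stack is cropped to the region valid in all
#' frames, so downstream per-pixel comparisons act on the same material.
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @param reference_index index of the reference frame (default 1).
#' @param upsample subpixel upsampling factor (default 10); 1 disables
#'   refinement.
#' @return The registered, cropped \code{frame_stack}; \code{offsets} holds
#'   the estimated (row, col) drift of each frame relative to the reference
#'   and attribute \code{"registration_failed"} flags frames whose
#'   correlation peak was ambiguous (their offset is kept at zero).
#' @export
register_drift <- function(stack, reference_index = 1, upsample = 10) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- length(stack$frames)
  if (nf < 2L) stop("need at least 2 frames to register")
  # Sequential estimation: each frame is registered against its
  # predecessor (adjacent frames differ by one step of degradation and a
  # pixel or two of drift, giving a dominant correlation peak even late in
  # a run), and the per-step shifts are accumulated relative to the
  # reference frame.
  ref <- stack$frames[[reference_index]]$height
  step <- matrix(0, nf, 2)
  failed <- logical(nf)
  for (i in 2:nf) {
    est <- estimate_shift(stack$frames[[i - 1]]$height,
                          stack$frames[[i]]$height, upsample)
    failed[i] <- est$failed
    if (!est$failed) step[i, ] <- est$shift
  }
  cum <- apply(step, 2, cumsum)
  offsets <- sweep(cum, 2, cum[reference_index, ])
  # apply rounded corrections; the common valid rectangle follows from the
  # applied integer shifts
  int_off <- round(offsets)
  frames2 <- stack$frames
  for (i in seq_len(nf)) {
    dr <- -int_off[i, 1]; dc <- -int_off[i, 2]
    if (dr == 0 && dc == 0) next
    f <- frames2[[i]]
    f$height <- translate_int(f$height, dr, dc)
    f$modulus <- translate_int(f$modulus, dr, dc)
    if (!is.null(f$background_mask))
      f$background_mask <- translate_int(f$background_mask, dr, dc, FALSE) > 0
    if (!is.null(f$fiber_mask))
      f$fiber_mask <- translate_int(f$fiber_mask, dr, dc, FALSE) > 0
    frames2[[i]] <- f
  }
  n <- dim(ref)
  r1 <- 1 + max(0, max(-int_off[, 1]))
  r2 <- n[1] + min(0, min(-int_off[, 1]))
  c1 <- 1 + max(0, max(-int_off[, 2]))
  c2 <- n[2] + min(0, min(-int_off[, 2]))
  if (r1 > r2 || c1 > c2)
    stop("no common valid region after registration")
  keep_r <- r1:r2; keep_c <- c1:c2
  crop <- function(m) m[keep_r, keep_c, drop = FALSE]
  for (i in seq_len(nf)) {
    f <- frames2[[i]]
    f$height <- crop(f$height)
    f$modulus <- crop(f$modulus)
    if (!is.null(f$background_mask)) f$background_mask <- crop(f$background_mask)
    if (!is.null(f$fiber_mask)) f$fiber_mask <- crop(f$fiber_mask)
    frames2[[i]] <- f
  }
  out <- frame_stack(frames2, offsets = offsets)
  attr(out, "registration_failed") <- failed
  out
}
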