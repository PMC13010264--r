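#' Nanodomain-averaged normalized stiffness
#'
#' Arithmetic mean of local E* values over the fiber pixels inside a
#' region of interest. The mean is the appropriate summary because E*
#' distributions within a crystalline nanodomain are unimodal and
#' homogeneous, so local deviations are statistical noise rather than
#' mechanical subpopulations.
#'
#' @param frame a normalized [map_frame()] with a \code{fiber_mask}.
#' @param roi a [nanodomain_roi()] or \code{NULL} for the whole frame.
#' @param min_points minimum number of fiber pixels required (default 2500,
#'   i.e. 10,000 nm^2 at 2 nm/px); below it the value is flagged excluded.
#' @return Numeric E*_av (MPa) with attributes \code{n} (pixel count) and
#'   \code{excluded} (logical); \code{NA} when excluded.
#' @export
estar_av <- function(frame, roi = NULL, min_points = 2500) {
  stopifnot(inherits(frame, "map_frame"))
  if (is.null(frame$fiber_mask)) stop("frame has no fiber_mask; segment first")
  sel <- frame$fiber_mask & roi_mask(roi, dim(frame$height))
  n <- sum(sel)
  if (n < min_points) {
    out <- NA_real_
    attr(out, "n") <- n
    attr(out, "excluded") <- TRUE
    return(out)
  }
  out <- mean(frame$modulus[sel])
  attr(out, "n") <- n
  attr(out, "excluded") <- FALSE
  out
}

#' Distribution summary of E* over a nanodomain
#'
#' Histogram/density summary of the local E* values: mode (peak of a
#' kernel-smoothed density with Silverman bandwidth), mean, adjusted
#' Fisher-Pearson skewness, and a unimodality flag obtained by counting
#' prominent modes of the smoothed density. Domains with too few points or
#' irregular (multi-modal) distributions are flagged for exclusion.
#'
#' @param frame a normalized [map_frame()] with \code{fiber_mask}.
#' @param roi a [nanodomain_roi()] or \code{NULL}.
#' @param min_points minimum fiber pixel count (default 2500).
#' @param mode_prominence fraction of the maximum density a secondary peak
#'   must exceed (after the intervening dip) to count as a separate mode.
#' @return A list of class \code{"estar_summary"}: \code{mode}, \code{mean},
#'   \code{skewness}, \code{n}, \code{unimodal}, \code{excluded}.
#' @export
estar_distribution <- function(frame, roi = NULL, min_points = 2500,
                               mode_prominence = 0.15) {
  stopifnot(inherits(frame, "map_frame"))
  if (is.null(frame$fiber_mask)) stop("frame has no fiber_mask; segment first")
  sel <- frame$fiber_mask & roi_mask(roi, dim(frame$height))
  v <- frame$modulus[sel]
  n <- length(v)
  if (n < min_points)
    return(structure(list(mode = NA_real_, mean = NA_real_,
                          skewness = NA_real_, n = n, unimodal = NA,
                          excluded = TRUE), class = "estar_summary"))
  if (stats::sd(v) < 1e-12) {
    return(structure(list(mode = v[1], mean = v[1], skewness = 0, n = n,
                          unimodal = TRUE, excluded = FALSE),
                     class = "estar_summary"))
  }
  dens <- stats::density(v, bw = "nrd0")
  mode <- dens$x[which.max(dens$y)]
  nmodes <- count_modes(dens$y, mode_prominence)
  unimodal <- nmodes <= 1L
  structure(list(mode = mode, mean = mean(v),
                 skewness = e1071::skewness(v, type = 2),
                 n = n, unimodal = unimodal, excluded = !unimodal),
            class = "estar_summary")
}

# Count prominent modes of a density curve: local maxima separated from the
# running maximum by a dip of at least `prom` * max(y).
count_modes <- function(y, prom = 0.15) {
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  peaks <- which(is_max)
  if (!length(peaks)) return(0L)
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  ymax <- max(y)
  kept <- peaks[1]
  for (p in peaks[-1]) {
    # dip between this peak and every kept peak must be deep enough
    deep <- vapply(kept, function(k) {
      rng <- range(c(k, p))
      dip <- min(y[rng[1]:rng[2]])
      y[p] - dip >= prom * ymax
    }, logical(1))
    if (all(deep) && y[p] >= prom * ymax) kept <- c(kept, p)
  }
  length(kept)
}

#' Fiber volume from a leveled height map
#'
#' Integrates the height over the fiber mask:
#' \code{sum(height) * pixel_size^2}.
#'
#' @param frame a leveled [map_frame()].
#' @param mask logical matrix; defaults to the frame's \code{fiber_mask}.
#' @param check_level warn when the background median height is not ~0
#'   (frame not leveled).
#' @return Volume in nm^3 (non-negative).
#' @export
fiber_volume <- function(frame, mask = NULL, check_level = TRUE) {
  stopifnot(inherits(frame, "map_frame"))
  if (is.null(mask)) mask <- frame$fiber_mask
  if (is.null(mask)) stop("no fiber mask available")
  if (check_level && !is.null(frame$background_mask) &&
      any(frame$background_mask)) {
    med <- stats::median(frame$height[frame$background_mask])
    if (is.finite(med) && abs(med) > 0.5)
      warning("background median height is ", signif(med, 3),
              " nm; frame may not be leveled")
  }
  if (!any(mask)) return(0)
  max(sum(frame$height[mask]) * frame$pixel_size^2, 0)
}

#' Relative degradation activity from a frame stack
#'
#' The AFM-derived degradation rate: percent of the initial fiber material
#' (height pixel sum over the fiber mask) lost per minute,
#' \deqn{A(t_i) = 100 \, \frac{P(t_{i-1}) - P(t_i)}{P(t_0)\,(t_i - t_{i-1})}.}
#'
#' @param stack a registered, leveled [frame_stack()] whose frames carry
#'   fiber masks.
#' @param masks optional list of logical matrices overriding the per-frame
#'   fiber masks (e.g. a common mask).
#' @return A \code{data.frame} with columns \code{time} and \code{activity}
#'   (percent per min); the first frame has \code{NA} activity.
#' @export
relative_activity <- function(stack, masks = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- length(stack$frames)
  if (nf < 2L) stop("need at least 2 frames")
  P <- vapply(seq_len(nf), function(i) {
    f <- stack$frames[[i]]
    m <- if (is.null(masks)) f$fiber_mask else masks[[i]]
    if (is.null(m)) stop("frame ", i, " has no fiber mask")
    sum(f$height[m])
  }, numeric(1))
  if (P[1] <= 0) stop("initial pixel sum is zero; nothing to degrade")
  act <- c(NA_real_,
           100 * (P[-nf] - P[-1]) / (P[1] * diff(stack$times)))
  data.frame(time = stack$times, activity = act)
}

#' Linearly scale a series to 0-100 percent
#'
#' Used to put E*_av trajectories from different experiments on a common
#' scale: \code{(v - min) / (max - min) * 100}. Affine transformations of
#' the input leave the output unchanged.
#'
#' @param values numeric vector with \code{min < max}.
#' @return Scaled vector in \code{[0, 100]}. A constant series returns all
#'   \code{NA} with attribute \code{undefined_scale = TRUE} and a warning.
#' @export
scale_series <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) < .Machine$double.eps * 100) {
    warning("constant series: 0-100% scale undefined")
    out <- rep(NA_real_, length(values))
    attr(out, "undefined_scale") <- TRUE
    return(out)
  }
  (values - rng[1]) / diff(rng) * 100
}
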