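#' Per-nanodomain degradation trajectory
#'
#' Normalized time course of a degrading nanodomain: relative volume
#' \code{V(t)/V(0)}, nanodomain-averaged normalized stiffness (raw and
#' scaled 0-100 percent), and relative activity (percent of initial
#' material lost per minute).
#'
#' @param times frame times (min), strictly increasing.
#' @param volumes per-frame fiber volumes (nm^3).
#' @param estar_av per-frame E*_av values (MPa); \code{NA} where excluded.
#' @param excluded optional logical exclusion flags (insufficient points,
#'   irregular distribution, manual masking); flagged frames are dropped.
#' @return A \code{data.frame} of class \code{"degradation_trajectory"}
#'   with columns \code{time}, \code{rel_volume}, \code{estar_av},
#'   \code{estar_scaled}, \code{activity}.
#' @export
degradation_trajectory <- function(times, volumes, estar_av,
                                   excluded = NULL) {
  n <- length(times)
  stopifnot(length(volumes) == n, length(estar_av) == n)
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  excluded <- excluded | !is.finite(volumes) | !is.finite(estar_av)
  keep <- !excluded
  if (!any(keep)) stop("all frames excluded: empty trajectory")
  times <- times[keep]; volumes <- volumes[keep]; estar_av <- estar_av[keep]
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (volumes[1] <= 0) stop("initial volume must be positive")
  rel_v <- volumes / volumes[1]
  activity <- c(NA_real_, 100 * -diff(rel_v) / diff(times))
  scaled <- suppressWarnings(scale_series(estar_av))
  out <- data.frame(time = times, rel_volume = rel_v,
                    estar_av = estar_av, estar_scaled = scaled,
                    activity = activity)
  class(out) <- c("degradation_trajectory", "data.frame")
  out
}

#' Process a raw frame stack into per-frame degradation measurements
#'
#' The standard pipeline: plane-level every frame, register the stack
#' against the first frame, segment the fiber, normalize the modulus to the
#' HOPG background, and measure per-frame volume and E*_av.
#'
#' @param stack a raw [frame_stack()].
#' @param E_hopg_nominal nominal background modulus (MPa).
#' @param roi optional [nanodomain_roi()] restricting E*_av.
#' @param register run drift registration (default TRUE).
#' @param min_points minimum fiber pixels for a valid E*_av.
#' @param height_threshold segmentation threshold (nm) or \code{"auto"}.
#' @return A list with \code{per_frame} (data.frame: time, volume_nm3,
#'   estar_av, n_points, excluded), \code{activity} (from
#'   [relative_activity()]), \code{offsets}, and the processed
#'   \code{stack}.
#' @export
process_stack <- function(stack, E_hopg_nominal = 100, roi = NULL,
                          register = TRUE, min_points = 2500,
                          height_threshold = "auto") {
  stopifnot(inherits(stack, "frame_stack"))
  frames <- lapply(stack$frames, level_plane)
  st <- frame_stack(frames)
  offsets <- st$offsets
  if (register && length(frames) >= 2) {
    st <- register_drift(st)
    offsets <- st$offsets
  }
  st$frames <- lapply(st$frames, function(f) {
    f <- segment_fiber(f, height_threshold = height_threshold)
    # re-level against the refined background, then normalize stiffness
    f <- level_plane(f)
    normalize_modulus(f, E_hopg_nominal)
  })
  nf <- length(st$frames)
  vol <- numeric(nf); est <- numeric(nf); npts <- integer(nf)
  for (i in seq_len(nf)) {
    f <- st$frames[[i]]
    vol[i] <- if (any(f$fiber_mask)) fiber_volume(f, check_level = FALSE) else 0
    e <- estar_av(f, roi = roi, min_points = min_points)
    est[i] <- as.numeric(e)
    npts[i] <- attr(e, "n")
  }
  # activity from the pixel sum over a consistent region: the first
  # frame's fiber footprint, held fixed across the registered stack, so
  # residual material near the segmentation threshold still counts
  fixed_mask <- st$frames[[1]]$fiber_mask
  act <- relative_activity(st, masks = rep(list(fixed_mask), nf))
  list(per_frame = data.frame(time = st$times, volume_nm3 = vol,
                              estar_av = est, n_points = npts,
                              excluded = !is.finite(est)),
       activity = act, offsets = offsets, stack = st)
}

#' Build a degradation trajectory from processed stack output
#'
#' @param processed the list returned by [process_stack()].
#' @return A [degradation_trajectory()].
#' @export
build_trajectory <- function(processed) {
  pf <- processed$per_frame
  degradation_trajectory(pf$time, pf$volume_nm3, pf$estar_av,
                         excluded = pf$excluded)
}

#' Correlate degradation rate with substrate stiffness
#'
#' Pairs the same-frame relative activity with scaled E*_av and reports the
#' least-squares slope and the Spearman rank correlation. A strongly
#' negative correlation means the enzyme system slows down as the exposed
#' substrate stiffens (cellulase-like); a correlation near zero means the
#' activity is insensitive to the stiffness change (cellulosome-like).
#'
#' @param traj a [degradation_trajectory()].
#' @param lag integer frame lag applied to the stiffness series (default 0,
#'   same-frame pairing).
#' @return A list with \code{slope}, \code{intercept}, \code{spearman},
#'   \code{n}, \code{undefined} (TRUE when E*_av is constant).
#' @export
correlate_rate_stiffness <- function(traj, lag = 0L) {
  a <- traj$activity
  e <- traj$estar_scaled
  if (lag != 0L) {
    n <- length(e)
    e <- if (lag > 0) c(rep(NA, lag), e[seq_len(n - lag)])
         else c(e[(1 - lag):n], rep(NA, -lag))
  }
  ok <- is.finite(a) & is.finite(e)
  if (sum(ok) < 4L) stop("need at least 4 paired points")
  a <- a[ok]; e <- e[ok]
  if (stats::sd(e) < 1e-12)
    return(list(slope = NA_real_, intercept = NA_real_,
                spearman = NA_real_, n = length(a), undefined = TRUE))
  co <- unname(stats::coef(stats::lm(a ~ e)))
  rho <- if (stats::sd(a) < 1e-12) 0
         else stats::cor(a, e, method = "spearman")
  list(slope = co[2], intercept = co[1], spearman = rho, n = length(a),
       undefined = FALSE)
}

#' Classify a degradation pattern as continuous or biphasic
#'
#' Compares a single straight line against a continuous two-segment
#' piecewise-linear model of scaled E*_av versus percent volume loss, using
#' the small-sample corrected Akaike criterion (AICc). The trajectory is
#' labelled biphasic only when the two-segment model wins and its first
#' segment is nearly flat (initial lag with only minor modulus change,
#' followed by a sharp rise) — the fragmentation signature. A continuous
#' rise in parallel with degradation is the layer-by-layer signature.
#'
#' @param traj a [degradation_trajectory()] with at least 6 usable points.
#' @param flat_slope_threshold first-segment slope limit, as a fraction of
#'   the overall single-line slope (default 0.2).
#' @return An object of class \code{"pattern_result"}: \code{label}
#'   ("continuous" or "biphasic"), \code{breakpoint} (percent volume loss;
#'   NA for continuous), \code{slope1}, \code{slope2},
#'   \code{overall_slope}, \code{delta_aicc} (AICc(two-segment) -
#'   AICc(line); negative favours biphasic).
#' @export
classify_pattern <- function(traj, flat_slope_threshold = 0.2) {
  ok <- is.finite(traj$estar_scaled) & is.finite(traj$rel_volume)
  x <- (1 - traj$rel_volume[ok]) * 100       # percent volume loss
  y <- traj$estar_scaled[ok]
  n <- length(x)
  if (n < 6L)
    return(structure(list(label = NA_character_, breakpoint = NA_real_,
                          slope1 = NA_real_, slope2 = NA_real_,
                          overall_slope = NA_real_, delta_aicc = NA_real_,
                          insufficient_data = TRUE),
                     class = "pattern_result"))
  fit1 <- stats::lm(y ~ x)
  rss1 <- sum(stats::resid(fit1)^2)
  overall <- unname(stats::coef(fit1))[2]

  aicc <- function(rss, k) {
    penalty <- if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
    n * log(max(rss, 1e-12) / n) + 2 * k + penalty
  }
  # candidate breakpoints: interior x values (>= 2 points on either side),
  # then a continuous refinement between the neighbouring candidates
  fit_at <- function(bp) {
    xx <- pmax(x - bp, 0)
    f <- stats::lm(y ~ x + xx)
    list(rss = sum(stats::resid(f)^2), bp = bp,
         co = unname(stats::coef(f)),
         se1 = suppressWarnings(summary(f)$coefficients[2, 2]))
  }
  cand <- sort(unique(x))[-c(1, 2)]
  cand <- cand[cand < sort(x, decreasing = TRUE)[2]]
  fits <- lapply(cand, fit_at)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  i <- match(best$bp, cand)
  lo <- if (i > 1) cand[i - 1] else best$bp
  hi <- if (i < length(cand)) cand[i + 1] else best$bp
  if (hi > lo) {
    opt <- stats::optimize(function(b) fit_at(b)$rss, c(lo, hi))
    refined <- fit_at(opt$minimum)
    if (refined$rss <= best$rss) best <- refined
  }
  # k: line = 2 coefs + sigma; two-segment adds the second slope and the
  # breakpoint location
  a1 <- aicc(rss1, 3)
  a2 <- aicc(best$rss, 5)
  slope1 <- best$co[2]
  slope2 <- best$co[2] + best$co[3]
  two_wins <- is.finite(a2) && a2 < a1
  # The first segment counts as flat when its slope is minor relative to
  # the sharp second-segment rise (the overall-fit slope of a trajectory
  # with a long lag understates that contrast), or when it is
  # statistically indistinguishable from zero.
  flat_first <- is.finite(slope1) && is.finite(slope2) &&
    (abs(slope1) < flat_slope_threshold * abs(slope2) ||
     (is.finite(best$se1) && abs(slope1) < 2 * best$se1))
  label <- if (two_wins && flat_first) "biphasic" else "continuous"
  structure(list(label = label,
                 breakpoint = if (label == "biphasic") best$bp else NA_real_,
                 slope1 = slope1, slope2 = slope2, overall_slope = overall,
                 delta_aicc = a2 - a1, insufficient_data = FALSE),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  if (isTRUE(x$insufficient_data)) {
    cat("pattern: insufficient data\n"); return(invisible(x))
  }
  cat(sprintf("pattern: %s", x$label))
  if (x$label == "biphasic")
    cat(sprintf(" (breakpoint at %.1f%% volume loss)", x$breakpoint))
  cat(sprintf("\n  slopes: first %.3g, second %.3g, single-line %.3g\n",
              x$slope1, x$slope2, x$overall_slope))
  cat(sprintf("  delta AICc (two-segment - line): %.2f\n", x$delta_aicc))
  invisible(x)
}

#' Plot a degradation trajectory
#'
#' Relative volume and scaled E*_av against time on a common 0-1 / 0-100
#' axis pair, the standard way to display coupled volumetric and
#' nanomechanical evolution.
#'
#' @param x a [degradation_trajectory()].
#' @param ... passed to [plot()].
#' @return The trajectory, invisibly.
#' @export
plot.degradation_trajectory <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$rel_volume, type = "b", pch = 16,
                 ylim = c(0, 1.05), xlab = "time (min)",
                 ylab = "relative volume V/V0", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$time, x$estar_scaled, type = "b", pch = 17, col = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 105))
  graphics::axis(4, col.axis = 2)
  graphics::mtext("E*_av (scaled, %)", side = 4, line = 2.5, col = 2)
  invisible(x)
}
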