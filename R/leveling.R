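#' Plane-level a map frame against its background
#'
#' Fits a least-squares plane to the height of the background (substrate)
#' pixels and subtracts it, then removes the residual background median so
#' the substrate sits exactly at height zero. Tilt and slow vertical drift
#' of the scanner are removed without biasing the fiber topography, because
#' only background pixels enter the fit.
#'
#' @param frame a [map_frame()]. When it carries no \code{background_mask} a
#'   provisional one (pixels below median + 2 MAD) is used.
#' @param min_background_frac minimum fraction of pixels that must be
#'   background for the fit to be trusted.
#' @return The leveled \code{map_frame}; background median height is 0.
#' @export
level_plane <- function(frame, min_background_frac = 0.1) {
  stopifnot(inherits(frame, "map_frame"))
  h <- frame$height
  bg <- frame$background_mask
  if (is.null(bg)) {
    thr <- stats::median(h) + 2 * stats::mad(h)
    bg <- h <= thr
  }
  if (mean(bg) < min_background_frac)
    stop("background mask covers less than ",
         round(100 * min_background_frac), "% of pixels")
  idx <- which(bg, arr.ind = TRUE)
  df <- data.frame(z = h[bg], r = idx[, 1], c = idx[, 2])
  co <- stats::coef(stats::lm(z ~ r + c, data = df))
  rr <- row(h); cc <- col(h)
  plane <- co[1] + co[2] * rr + co[3] * cc
  h2 <- h - plane
  h2 <- h2 - stats::median(h2[bg])
  out <- frame
  out$height <- h2
  out$background_mask <- if (is.null(frame$background_mask)) NULL else frame$background_mask
  out
}

#' Segment fiber objects in a leveled height map
#'
#' Thresholds the leveled height map, labels connected components, and
#' keeps only objects that are large enough and elongated enough to be
#' fibril bundles. Small or non-elongated residual objects (detached
#' fragments, stray enzyme) are excluded from both masks so they never enter
#' quantitative analysis.
#'
#' @param frame a leveled [map_frame()].
#' @param height_threshold height cutoff in nm, or \code{"auto"} to use the
#'   background noise median + 5 sigma.
#' @param min_area_px minimum object area in pixels (default 100).
#' @param min_aspect minimum elongation (ratio of principal-axis standard
#'   deviations) for an object to count as fiber, default 3.
#' @return The frame with \code{fiber_mask}, \code{background_mask} and an
#'   \code{excluded_mask} attribute set. Warns when no fiber is found.
#' @export
segment_fiber <- function(frame, height_threshold = "auto",
                          min_area_px = 100, min_aspect = 3) {
  stopifnot(inherits(frame, "map_frame"))
  h <- frame$height
  if (identical(height_threshold, "auto")) {
    rough_bg <- h <= stats::median(h) + 2 * stats::mad(h)
    height_threshold <- stats::median(h[rough_bg]) + 5 * stats::sd(h[rough_bg])
  }
  above <- h > height_threshold
  out <- frame
  out$background_mask <- !above
  if (!any(above)) {
    warning("empty fiber mask: no pixels above the height threshold")
    out$fiber_mask <- above
    attr(out, "excluded_mask") <- above
    return(out)
  }
  lab <- EBImage::bwlabel(EBImage::Image(above * 1))
  lab <- EBImage::imageData(lab)
  fiber <- matrix(FALSE, nrow(h), ncol(h))
  excluded <- matrix(FALSE, nrow(h), ncol(h))
  for (id in seq_len(max(lab))) {
    px <- lab == id
    npx <- sum(px)
    keep <- npx >= min_area_px
    if (keep && npx >= 4) {
      idx <- which(px, arr.ind = TRUE)
      sv <- svd(scale(idx, scale = FALSE), nu = 0, nv = 0)$d
      aspect <- if (sv[2] < 1e-9) Inf else sv[1] / sv[2]
      keep <- aspect >= min_aspect
    }
    if (keep) fiber[px] <- TRUE else excluded[px] <- TRUE
  }
  if (!any(fiber)) warning("empty fiber mask: no object passed the filters")
  out$fiber_mask <- fiber
  attr(out, "excluded_mask") <- excluded
  out
}

#' Normalize a modulus map to the substrate reference
#'
#' Rescales the modulus map by a per-frame multiplicative gain so that the
#' mean background (HOPG) modulus equals a fixed nominal value. Because the
#' substrate modulus is constant in reality, this removes tip wear and laser
#' drift effects that inflate or deflate all moduli of a frame by a common
#' factor. The corrected map is the normalized stiffness E*, still in MPa.
#'
#' @param frame a [map_frame()] with a non-empty \code{background_mask}.
#' @param E_hopg_nominal nominal apparent modulus of the HOPG background
#'   (MPa). Only the per-frame ratio matters for trends; the default of
#'   100 MPa keeps cellulose E* in its usual 10-20 MPa range.
#' @return The frame with \code{modulus} replaced by E* and a
#'   \code{"gain"} attribute recording the applied factor.
#' @export
normalize_modulus <- function(frame, E_hopg_nominal = 100) {
  stopifnot(inherits(frame, "map_frame"))
  bg <- frame$background_mask
  if (is.null(bg) || !any(bg)) stop("background_mask is required")
  m_bg <- mean(frame$modulus[bg])
  if (!is.finite(m_bg) || m_bg <= 0)
    stop("background modulus mean must be positive")
  gain <- E_hopg_nominal / m_bg
  out <- frame
  out$modulus <- frame$modulus * gain
  attr(out, "gain") <- gain
  out
}

#' Rectangular nanodomain region of interest
#'
#' An analysis unit on the registered pixel grid. The minimum surface area
#' of about 10,000 nm^2 (2500 points at 2 nm/px) ensures enough force curves
#' for stable distribution statistics.
#'
#' @param rows,cols integer ranges (two-element vectors) of the rectangle.
#' @param pixel_size pixel size (nm) used to check the area constraint.
#' @param min_area_nm2 minimum area (nm^2).
#' @return An object of class \code{"nanodomain_roi"}.
#' @export
nanodomain_roi <- function(rows, cols, pixel_size = 2,
                           min_area_nm2 = 10000) {
  rows <- as.integer(round(rows)); cols <- as.integer(round(cols))
  stopifnot(length(rows) == 2L, length(cols) == 2L,
            rows[1] <= rows[2], cols[1] <= cols[2])
  npx <- (rows[2] - rows[1] + 1L) * (cols[2] - cols[1] + 1L)
  area <- npx * pixel_size^2
  if (area < min_area_nm2)
    stop("ROI area ", area, " nm^2 below the minimum of ", min_area_nm2)
  structure(list(rows = rows, cols = cols, n_px = npx, area_nm2 = area),
            class = "nanodomain_roi")
}

# Logical mask for an ROI on a matrix of dimension dm (NULL ROI = all TRUE).
roi_mask <- function(roi, dm) {
  m <- matrix(FALSE, dm[1], dm[2])
  if (is.null(roi)) return(!m)
  r <- pmin(pmax(roi$rows, 1L), dm[1])
  c <- pmin(pmax(roi$cols, 1L), dm[2])
  m[r[1]:r[2], c[1]:c[2]] <- TRUE
  m
}
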