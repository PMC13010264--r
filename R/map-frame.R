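#' Co-registered height/modulus map frame
#'
#' A single time point of a force-volume acquisition: a height map (nm) and
#' an elastic-modulus map (MPa) on the same pixel grid, with optional
#' background and fiber masks.
#'
#' @param height numeric matrix, heights in nm.
#' @param modulus numeric matrix, moduli in MPa; same dimensions as
#'   \code{height}.
#' @param pixel_size lateral pixel size in nm (> 0), default 2 nm.
#' @param time acquisition time in minutes.
#' @param background_mask,fiber_mask optional logical matrices; where both
#'   are defined they must be disjoint.
#' @return An object of class \code{"map_frame"}.
#' @export
map_frame <- function(height, modulus, pixel_size = 2, time = 0,
                      background_mask = NULL, fiber_mask = NULL) {
  stopifnot(is.matrix(height), is.matrix(modulus),
            all(dim(height) == dim(modulus)), pixel_size > 0)
  if (!is.null(background_mask))
    stopifnot(is.logical(background_mask),
              all(dim(background_mask) == dim(height)))
  if (!is.null(fiber_mask))
    stopifnot(is.logical(fiber_mask), all(dim(fiber_mask) == dim(height)))
  if (!is.null(background_mask) && !is.null(fiber_mask) &&
      any(background_mask & fiber_mask))
    stop("background_mask and fiber_mask must be disjoint")
  structure(list(height = height, modulus = modulus,
                 pixel_size = pixel_size, time = time,
                 background_mask = background_mask,
                 fiber_mask = fiber_mask),
            class = "map_frame")
}

#' @export
print.map_frame <- function(x, ...) {
  cat(sprintf("map_frame %dx%d px (%.3g nm/px) at t = %g min\n",
              nrow(x$height), ncol(x$height), x$pixel_size, x$time))
  if (!is.null(x$fiber_mask))
    cat(sprintf("  fiber pixels: %d\n", sum(x$fiber_mask)))
  invisible(x)
}

#' Time-ordered stack of registered map frames
#'
#' @param frames list of [map_frame()] objects with identical dimensions and
#'   strictly increasing times.
#' @param offsets optional n x 2 matrix of registration offsets
#'   (rows, cols) applied per frame.
#' @return An object of class \code{"frame_stack"}.
#' @export
frame_stack <- function(frames, offsets = NULL) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "map_frame")))
  dims <- vapply(frames, function(f) dim(f$height), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions")
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(offsets)) offsets <- matrix(0, length(frames), 2)
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  structure(list(frames = frames, times = times, offsets = offsets),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames, t = %g..%g min, %dx%d px\n",
              length(x$frames), min(x$times), max(x$times),
              nrow(x$frames[[1]]$height), ncol(x$frames[[1]]$height)))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Read a plain-text map matrix
#'
#' Reads the whitespace-separated, row-major ASCII matrix dialect produced
#' by common SPM export tools (comment lines starting with '#' ignored).
#'
#' @param path file path.
#' @return A numeric matrix.
#' @export
read_map_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("ragged matrix in ", path)
  matrix(unlist(rows), nrow = length(rows), ncol = ncols, byrow = TRUE)
}

#' Write a map matrix as plain text
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_map_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read paired height/modulus frames into a stack
#'
#' Builds a [frame_stack()] from per-frame plain-text matrices, or from
#' paired multi-page TIFF files when the \pkg{tiff} package is available.
#'
#' @param height_paths,modulus_paths character vectors of per-frame text
#'   matrix files (same length), or single multi-page TIFF paths.
#' @param frame_times frame acquisition times (min).
#' @param pixel_size pixel size (nm).
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(height_paths, modulus_paths, frame_times,
                             pixel_size = 2) {
  is_tiff <- length(height_paths) == 1L &&
    grepl("\\.tiff?$", height_paths, ignore.case = TRUE)
  if (is_tiff) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF stacks")
    hs <- tiff::readTIFF(height_paths, all = TRUE, as.is = TRUE)
    ms <- tiff::readTIFF(modulus_paths, all = TRUE, as.is = TRUE)
    drop1 <- function(m) if (length(dim(m)) == 3L) m[, , 1] else m
    hs <- lapply(hs, drop1)
    ms <- lapply(ms, drop1)
  } else {
    hs <- lapply(height_paths, read_map_txt)
    ms <- lapply(modulus_paths, read_map_txt)
  }
  stopifnot(length(hs) == length(ms), length(hs) == length(frame_times))
  frames <- Map(function(h, m, t) map_frame(h, m, pixel_size, t),
                hs, ms, frame_times)
  frame_stack(frames)
}
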