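#' Core-shell cellulose fibril phantom
#'
#' Renders a synthetic fibril bundle on a flat substrate: a rounded ridge
#' (half-elliptical cross-section) of given length, width and height, with a
#' layered mechanical structure — a compliant surface shell over a stiff
#' crystalline core — and softer segments recurring at regular intervals
#' along the fiber (twists, bends, fibril ends). The phantom carries its own
#' closed-form volume and a depth-indexed modulus profile, providing exact
#' ground truth for the image pipeline.
#'
#' @param length_nm fiber length (nm), >= 250.
#' @param width_nm fiber width (nm), typically 10-30.
#' @param height_nm ridge height (nm), about 20 for a hydrated bundle.
#' @param E_core core modulus (MPa); must exceed \code{E_shell}.
#' @param E_shell surface-shell modulus (MPa); default keeps the initial E*
#'   peak in the 10-20 MPa range.
#' @param shell_thickness_nm depth over which the modulus ramps from shell
#'   to core; must be less than half the ridge height.
#' @param soft_spacing_nm center-to-center spacing of the soft segments.
#' @param soft_width_nm width of each soft segment along the fiber.
#' @param soft_factor multiplicative modulus factor (< 1) inside soft
#'   segments.
#' @param E_substrate apparent substrate (HOPG) modulus (MPa).
#' @param pixel_size lateral pixel size (nm), default 2.
#' @param margin_nm substrate margin around the fiber.
#' @return An object of class \code{"fibril_phantom"}: height map
#'   \code{height0}, per-column soft-factor vector, geometry and mechanics
#'   parameters, and \code{volume_true} (closed form,
#'   \eqn{\pi L W H / 4}).
#' @export
gen_fibril_phantom <- function(length_nm = 1000, width_nm = 30,
                               height_nm = 20, E_core = 45, E_shell = 15,
                               shell_thickness_nm = 9,
                               soft_spacing_nm = 200, soft_width_nm = 30,
                               soft_factor = 0.6, E_substrate = 100,
                               pixel_size = 2, margin_nm = 40) {
  if (length_nm < 250) stop("fiber length must be >= 250 nm")
  if (E_core <= E_shell || E_shell <= 0)
    stop("need E_core > E_shell > 0")
  if (shell_thickness_nm >= height_nm / 2)
    stop("shell thickness must be below half the ridge height")
  if (soft_factor <= 0 || soft_factor >= 1)
    stop("soft_factor must be in (0, 1)")
  px <- pixel_size
  ny <- ceiling((width_nm + 2 * margin_nm) / px)
  nx <- ceiling((length_nm + 2 * margin_nm) / px)
  yc <- (seq_len(ny) - 0.5) * px - (width_nm / 2 + margin_nm)  # across
  xc <- (seq_len(nx) - 0.5) * px - margin_nm                   # along
  in_x <- xc >= 0 & xc <= length_nm
  prof <- ifelse(abs(yc) < width_nm / 2,
                 height_nm * sqrt(pmax(1 - (2 * yc / width_nm)^2, 0)), 0)
  height0 <- outer(prof, as.numeric(in_x))
  # soft segments: periodic bands along the fiber axis
  phase <- (xc - soft_spacing_nm / 2) %% soft_spacing_nm
  soft_cols <- in_x & (phase < soft_width_nm / 2 |
                       phase > soft_spacing_nm - soft_width_nm / 2)
  soft_col_factor <- ifelse(soft_cols, soft_factor, 1)
  structure(list(height0 = height0, soft_col_factor = soft_col_factor,
                 fiber_cols = which(in_x),
                 length_nm = length_nm, width_nm = width_nm,
                 height_nm = height_nm, E_core = E_core,
                 E_shell = E_shell,
                 shell_thickness_nm = shell_thickness_nm,
                 soft_spacing_nm = soft_spacing_nm,
                 soft_width_nm = soft_width_nm, soft_factor = soft_factor,
                 E_substrate = E_substrate, pixel_size = px,
                 volume_true = pi * length_nm * width_nm * height_nm / 4),
            class = "fibril_phantom")
}

#' Modulus at a given erosion depth of a core-shell fibril
#'
#' The depth-indexed modulus profile of the phantom: a linear ramp from the
#' shell modulus at the surface to the core modulus at the bottom of the
#' shell, constant (core) below. A ramp rather than a smooth sigmoid keeps
#' the exposed-surface stiffness strictly increasing throughout shell
#' removal, which is the continuous layer-by-layer signature the ablation
#' scenario must reproduce.
#'
#' @param phantom a [gen_fibril_phantom()] object.
#' @param depth erosion depth(s) in nm from the original surface.
#' @return Modulus value(s) in MPa (before any soft-segment factor).
#' @export
depth_modulus <- function(phantom, depth) {
  s <- pmin(pmax(depth / phantom$shell_thickness_nm, 0), 1)
  phantom$E_shell + (phantom$E_core - phantom$E_shell) * s
}

# True surface-modulus map: remaining material shows depth_modulus at its
# exposure depth (times the per-column soft factor); bare substrate shows
# E_substrate. `depth` is a matrix or scalar; `remaining` a logical matrix.
surface_modulus_map <- function(phantom, depth, remaining) {
  E <- depth_modulus(phantom, depth)
  if (!is.matrix(E)) E <- matrix(E, nrow(phantom$height0), ncol(phantom$height0))
  E <- sweep(E, 2, phantom$soft_col_factor, `*`)
  E[!remaining] <- phantom$E_substrate
  E
}
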