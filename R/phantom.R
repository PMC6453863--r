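#' Synthetic vessel phantom
#'
#' Builds a 3D vessel phantom: a centerline parameterized by arc length, a
#' lumen radius profile, side-branch landmarks, and segment bounds splitting
#' the vessel into proximal-native / scaffolded / distal-native ranges.
#' Phantoms are the ground truth against which pullback simulation,
#' reconstruction and mounting are validated.
#'
#' With `curvature = 0` the centerline is a straight line along z. With
#' `curvature > 0` it is a planar circular arc of radius `1/curvature` in the
#' x-z plane. Supplying `helix_radius_mm` and `helix_pitch_mm` instead builds
#' a helical centerline (used to exercise reconstruction with out-of-plane
#' geometry); `curvature` is then ignored.
#'
#' @param length_mm Total centerline arc length (mm).
#' @param radius_mm Lumen radius (mm), constant along the vessel.
#' @param curvature Centerline curvature (1/mm), >= 0.
#' @param seed Integer seed controlling landmark placement.
#' @param step_mm Arc-length sampling step of the stored centerline (mm).
#' @param native_margin_mm Length of each native (non-scaffolded) end segment.
#' @param helix_radius_mm,helix_pitch_mm Optional helix parameters (mm).
#' @return Object of class `vessel_phantom` with fields `centerline` (n x 3
#'   matrix, mm), `arc_length_mm`, `radius_profile` (data.frame), `landmarks`
#'   (data.frame with `arc_length_mm`, `angle_deg`), `segment_bounds` (list of
#'   2-vectors, mm) and the generating parameters.
#' @examples
#' ph <- vessel_phantom(14, 1.5, curvature = 0, seed = 1)
#' range(ph$arc_length_mm)
#' @export
vessel_phantom <- function(length_mm, radius_mm, curvature = 0, seed = 1L,
                           step_mm = 0.05, native_margin_mm = 2,
                           helix_radius_mm = NULL, helix_pitch_mm = NULL) {
  if (length_mm <= 0 || radius_mm <= 0 || curvature < 0 || step_mm <= 0) {
    stop("length_mm, radius_mm and step_mm must be > 0 and curvature >= 0",
         call. = FALSE)
  }
  if (2 * native_margin_mm >= length_mm) {
    stop("native margins leave no scaffolded segment", call. = FALSE)
  }
  s <- seq(0, length_mm, by = step_mm)
  if (s[length(s)] < length_mm) s <- c(s, length_mm)

  if (!is.null(helix_radius_mm)) {
    if (is.null(helix_pitch_mm)) stop("helix_pitch_mm required with helix_radius_mm",
                                      call. = FALSE)
    a <- helix_radius_mm
    b <- helix_pitch_mm / (2 * pi)
    cc <- sqrt(a^2 + b^2)
    t <- s / cc
    pts <- cbind(a * cos(t) - a, a * sin(t), b * t)
  } else if (curvature == 0) {
    pts <- cbind(0 * s, 0 * s, s)
  } else {
    rc <- 1 / curvature
    th <- s / rc
    pts <- cbind(rc * (1 - cos(th)), 0 * s, rc * sin(th))
  }
  colnames(pts) <- c("x", "y", "z")

  set.seed(as.integer(seed))
  # one side branch in the proximal native segment, seeded position/angle
  lm_s <- stats::runif(1, 0.2, 0.8) * native_margin_mm
  lm_a <- stats::runif(1, 0, 360)
  landmarks <- data.frame(arc_length_mm = lm_s, angle_deg = lm_a)

  structure(list(
    centerline = pts,
    arc_length_mm = s,
    radius_profile = data.frame(arc_length_mm = s, radius_mm = radius_mm),
    landmarks = landmarks,
    segment_bounds = list(
      proximal_native = c(0, native_margin_mm),
      scaffolded = c(native_margin_mm, length_mm - native_margin_mm),
      distal_native = c(length_mm - native_margin_mm, length_mm)),
    length_mm = length_mm, radius_mm = radius_mm,
    curvature = curvature, seed = as.integer(seed)
  ), class = "vessel_phantom")
}

#' @exportS3Method base::print
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("<vessel_phantom> %g mm long, lumen radius %g mm, curvature %g /mm\n",
              x$length_mm, x$radius_mm, x$curvature))
  cat(sprintf("  scaffolded segment: %.2f-%.2f mm; %d centerline points\n",
              x$segment_bounds$scaffolded[1], x$segment_bounds$scaffolded[2],
              nrow(x$centerline)))
  invisible(x)
}

#' Biplane orthographic projection of a phantom centerline
#'
#' Projects the 3D centerline onto two image planes defined by gantry
#' rotation angles about the patient (z) axis, emulating a biplane
#' angiographic acquisition. Projection is orthographic (parallel beam): a
#' point (x, y, z) maps to image coordinates
#' `u = x cos(angle) + y sin(angle)`, `v = z`.
#'
#' @param phantom A [vessel_phantom()].
#' @param angle_a,angle_b Gantry angles in degrees. The pair is degenerate
#'   (error) when the angles coincide modulo 180 degrees.
#' @param calibration_mm_per_px Pixel calibration carried as metadata.
#' @return Object of class `projection_pair`: polylines `polyline_a`,
#'   `polyline_b` (n x 2, mm, ordered proximal to distal), the two angles and
#'   the calibration.
#' @export
project_centerline <- function(phantom, angle_a, angle_b,
                               calibration_mm_per_px = 1) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  if (abs(sin((angle_a - angle_b) * pi / 180)) < 1e-9) {
    stop("degenerate projection pair: angles ", angle_a, " and ", angle_b,
         " view along the same axis", call. = FALSE)
  }
  proj1 <- function(ang) {
    r <- ang * pi / 180
    cbind(u = phantom$centerline[, 1] * cos(r) + phantom$centerline[, 2] * sin(r),
          v = phantom$centerline[, 3])
  }
  structure(list(polyline_a = proj1(angle_a), polyline_b = proj1(angle_b),
                 angle_a = angle_a, angle_b = angle_b,
                 calibration_mm_per_px = calibration_mm_per_px),
            class = "projection_pair")
}
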