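# Per-frame contour/strut geometry works in catheter-centered polar
# coordinates: a contour is a data.frame (angle_deg in [0, 360), radius_um),
# closed implicitly; a strut is one row of a pullback's `struts` table.

#' Extract one frame's lumen contour from a pullback
#'
#' @param pullback A `pullback`.
#' @param frame 0-based frame index.
#' @return data.frame with `angle_deg`, `radius_um`, ordered by angle.
#' @export
get_contour <- function(pullback, frame) {
  ct <- pullback$contours[pullback$contours$frame == frame,
                          c("angle_deg", "radius_um")]
  if (!nrow(ct)) stop("no contour for frame ", frame, call. = FALSE)
  ct[order(ct$angle_deg), ]
}

circ_dist <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# linear interpolation of contour radius at arbitrary angles (circular)
interp_contour_radius <- function(contour, angle) {
  ang <- contour$angle_deg
  rad <- contour$radius_um
  # wrap for circular interpolation
  ang2 <- c(ang, ang[1] + 360)
  rad2 <- c(rad, rad[1])
  a <- angle %% 360
  stats::approx(ang2, rad2, xout = ifelse(a < ang[1], a + 360, a))$y
}

#' Flow-area contour construction
#'
#' The flow area in a scaffolded frame is bounded by the adluminal side of
#' the struts and by the vessel wall between the struts. This replaces the
#' wall contour radius with the strut adluminal radius inside each strut's
#' angular span and leaves it untouched elsewhere.
#'
#' @param contour Wall contour data.frame (`angle_deg`, `radius_um`).
#' @param struts Strut rows for the same frame (may be empty / NULL).
#' @return A contour data.frame of the same shape.
#' @export
build_flow_area_contour <- function(contour, struts = NULL) {
  out <- contour
  if (is.null(struts) || !nrow(struts)) return(out)
  ctr <- struts$angle_center_deg
  half <- struts$angular_span_deg / 2
  if (nrow(struts) > 1) {
    for (i in seq_len(nrow(struts) - 1)) {
      for (j in (i + 1):nrow(struts)) {
        if (circ_dist(ctr[i], ctr[j]) < half[i] + half[j]) {
          stop("overlapping strut spans at ", ctr[i], " and ", ctr[j],
               " degrees", call. = FALSE)
        }
      }
    }
  }
  for (i in seq_len(nrow(struts))) {
    inside <- circ_dist(out$angle_deg, ctr[i]) <= half[i]
    wall_here <- contour$radius_um[inside]
    if (any(struts$adluminal_radius_um[i] > wall_here + 1e-9)) {
      stop("inverted geometry: adluminal radius exceeds wall radius inside ",
           "strut span at ", ctr[i], " degrees", call. = FALSE)
    }
    out$radius_um[inside] <- struts$adluminal_radius_um[i]
  }
  out
}

#' Polygon area of a polar contour (shoelace)
#'
#' @param contour data.frame (`angle_deg`, `radius_um`).
#' @return Enclosed area in um^2.
#' @export
contour_area <- function(contour) {
  th <- contour$angle_deg * pi / 180
  x <- contour$radius_um * cos(th)
  y <- contour$radius_um * sin(th)
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# wall radius across a strut footprint: linear interpolation between the
# contour values at the two span edges (samples flanking the hidden wall)
wall_radius_under_strut <- function(strut, contour) {
  half <- strut$angular_span_deg / 2
  a0 <- strut$angle_center_deg - half
  a1 <- strut$angle_center_deg + half
  # refuse when the contour sampling is coarser than the strut span
  dmax <- max(diff(sort(contour$angle_deg)))
  if (dmax > strut$angular_span_deg + 1e-9 && dmax > 360 / nrow(contour) * 2) {
    stop("contour gap (", round(dmax, 2), " deg) wider than strut span; ",
         "cannot interpolate wall radius", call. = FALSE)
  }
  w0 <- interp_contour_radius(contour, a0)
  w1 <- interp_contour_radius(contour, a1)
  (w0 + w1) / 2
}

#' Strut protrusion distance
#'
#' Protrusion is the radial distance between the wall (interpolated across
#' the strut footprint from the contour samples flanking the span) and the
#' strut's adluminal edge, floored at zero.
#'
#' @param strut One strut row (`angle_center_deg`, `angular_span_deg`,
#'   `adluminal_radius_um`, ...).
#' @param contour Wall contour of the strut's frame.
#' @return Protrusion distance in micron.
#' @export
protrusion_distance <- function(strut, contour) {
  wall <- wall_radius_under_strut(strut, contour)
  max(0, wall - strut$adluminal_radius_um)
}

#' Strut apposition classification
#'
#' A strut is malapposed when its abluminal (wall-facing) edge is detached
#' from the wall by strictly more than `tolerance_um` (default 20 um, about
#' the axial resolution of frequency-domain OCT); otherwise it is protruding
#' when its protrusion distance is positive and embedded when flush.
#'
#' @param strut One strut row.
#' @param contour Wall contour of the strut's frame.
#' @param tolerance_um Detachment tolerance in micron.
#' @return One of `"embedded"`, `"protruding"`, `"malapposed"`.
#' @export
classify_apposition <- function(strut, contour, tolerance_um = 20) {
  wall <- wall_radius_under_strut(strut, contour)
  gap <- wall - strut$abluminal_radius_um
  if (gap > tolerance_um) return("malapposed")
  if (protrusion_distance(strut, contour) > 0) "protruding" else "embedded"
}

#' Measure protrusion and apposition for every strut of a pullback
#'
#' @param pullback A `pullback`.
#' @param tolerance_um Malapposition tolerance in micron.
#' @return data.frame: one row per strut with `frame`, `axial_um`,
#'   `protrusion_um`, `apposition`.
#' @export
measure_protrusion <- function(pullback, tolerance_um = 20) {
  st <- pullback$struts
  if (!nrow(st)) {
    return(data.frame(frame = integer(), axial_um = numeric(),
                      protrusion_um = numeric(), apposition = character()))
  }
  out <- vector("list", length(unique(st$frame)))
  k <- 0
  for (f in unique(st$frame)) {
    ct <- get_contour(pullback, f)
    rows <- st[st$frame == f, ]
    prot <- numeric(nrow(rows))
    app <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      prot[i] <- protrusion_distance(rows[i, ], ct)
      app[i] <- classify_apposition(rows[i, ], ct, tolerance_um)
    }
    k <- k + 1
    out[[k]] <- data.frame(
      frame = f,
      axial_um = pullback$frames$axial_um[match(f, pullback$frames$frame)],
      protrusion_um = prot, apposition = app)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate protrusion statistics
#'
#' Summarizes apposed-strut protrusion over 200 um axial intervals,
#' cross-sections (frames) or the whole device. Malapposed struts are
#' excluded. Intervals are half-open, `[k*200, (k+1)*200)` um, 0-based from
#' the first scaffolded frame.
#'
#' @param pullback A `pullback`.
#' @param level `"interval_200um"`, `"cross_section"` or `"device"`.
#' @param interval_um Interval width for the interval level.
#' @param tolerance_um Malapposition tolerance passed to classification.
#' @return data.frame with `n_struts`, `mean_um`, `sd_um`,
#'   `protrusion_fraction_pct` (percent of strut thickness, integer) and
#'   `protrusion_to_lumen_ratio` (mean protrusion / mean lumen diameter),
#'   one row per group (or a single row at device level).
#' @export
aggregate_protrusion <- function(pullback,
                                 level = c("device", "cross_section", "interval_200um"),
                                 interval_um = 200, tolerance_um = 20) {
  level <- match.arg(level)
  meas <- measure_protrusion(pullback, tolerance_um)
  meas <- meas[meas$apposition != "malapposed", ]
  if (!nrow(meas)) stop("no apposed struts at the requested level", call. = FALSE)

  scaf_frames <- pullback$frames$frame[pullback$frames$segment == "scaffolded"]
  axial0 <- min(pullback$frames$axial_um[pullback$frames$frame %in% scaf_frames])
  meas$interval <- floor((meas$axial_um - axial0) / interval_um)

  # mean lumen diameter over scaffolded frames (um)
  scaf_ct <- pullback$contours[pullback$contours$frame %in% scaf_frames, ]
  mld_um <- 2 * mean(scaf_ct$radius_um)
  thick <- pullback$design$strut_thickness_um

  summarize_group <- function(d) {
    data.frame(n_struts = nrow(d),
               mean_um = mean(d$protrusion_um),
               sd_um = if (nrow(d) > 1) stats::sd(d$protrusion_um) else 0,
               protrusion_fraction_pct = protrusion_fraction(mean(d$protrusion_um), thick),
               protrusion_to_lumen_ratio = mean(d$protrusion_um) / mld_um)
  }
  if (level == "device") {
    res <- summarize_group(meas)
  } else {
    key <- if (level == "cross_section") meas$frame else meas$interval
    parts <- split(meas, key)
    res <- do.call(rbind, lapply(parts, summarize_group))
    res <- cbind(stats::setNames(data.frame(as.integer(names(parts))),
                                 if (level == "cross_section") "frame" else "interval"),
                 res)
  }
  rownames(res) <- NULL
  res
}

#' Protrusion as a percentage of strut thickness
#'
#' @param mean_protrusion_um Mean protrusion distance (micron).
#' @param strut_thickness_um Strut thickness (micron), > 0.
#' @return Integer percent (rounded for reporting).
#' @examples
#' protrusion_fraction(153, 157)  # 97
#' protrusion_fraction(84, 95)    # 88
#' @export
protrusion_fraction <- function(mean_protrusion_um, strut_thickness_um) {
  if (strut_thickness_um <= 0) stop("strut thickness must be > 0", call. = FALSE)
  round(100 * mean_protrusion_um / strut_thickness_um)
}
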