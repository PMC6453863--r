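#' Simulate an OCT-style pullback over a scaffolded phantom
#'
#' Generates per-frame lumen contours (1 degree angular resolution, catheter
#' centered polar coordinates) and per-strut annotations for a phantom
#' carrying a scaffold of the given design. Strut rings are laid out along
#' the scaffolded segment with a ring pitch equal to the design's clear
#' inter-strut distance plus the strut width; a frame intersecting a ring's
#' axial extent sees `struts_per_ring` struts.
#'
#' Each strut's adluminal (lumen-facing) edge sits at
#' `wall_radius - protrusion_fraction * strut_thickness`; its abluminal edge
#' one strut thickness further out. `protrusion_fraction > 1` therefore lifts
#' the abluminal edge off the wall, creating malapposed struts. Ground-truth
#' protrusion and malapposition are stored per strut for round-trip tests.
#'
#' @param phantom A [vessel_phantom()].
#' @param design A [scaffold_design()].
#' @param protrusion_fraction Protrusion depth as a fraction of strut
#'   thickness, in [0, 1.2].
#' @param frame_spacing_um Axial spacing between consecutive frames (micron).
#' @param seed Integer seed (per-strut protrusion jitter, if enabled).
#' @param protrusion_jitter_sd_um Per-strut Gaussian jitter of the protrusion
#'   depth (micron); default 0 gives exact geometry.
#' @return Object of class `pullback` with `contours` (frame, angle_deg,
#'   radius_um), `struts` (frame, angle_center_deg, angular_span_deg,
#'   adluminal_radius_um, abluminal_radius_um, truth_protrusion_um,
#'   truth_malapposed), `frames` (frame, axial_um, segment), plus the design
#'   and generation parameters.
#' @export
simulate_pullback <- function(phantom, design, protrusion_fraction,
                              frame_spacing_um = 200, seed = 1L,
                              protrusion_jitter_sd_um = 0) {
  stopifnot(inherits(phantom, "vessel_phantom"),
            inherits(design, "scaffold_design"))
  if (protrusion_fraction < 0 || protrusion_fraction > 1.2) {
    stop("protrusion_fraction must lie in [0, 1.2]", call. = FALSE)
  }
  if (frame_spacing_um <= 0) stop("frame_spacing_um must be > 0", call. = FALSE)
  if (protrusion_fraction * design$strut_thickness_um >=
      min(phantom$radius_profile$radius_mm) * 1000) {
    stop("protrusion deeper than the lumen radius", call. = FALSE)
  }
  set.seed(as.integer(seed))

  axial_um <- seq(0, phantom$length_mm * 1000, by = frame_spacing_um)
  n_frames <- length(axial_um)
  segs <- phantom$segment_bounds
  seg_of <- function(s_mm) {
    ifelse(s_mm < segs$scaffolded[1], "proximal_native",
           ifelse(s_mm >= segs$scaffolded[2], "distal_native", "scaffolded"))
  }
  frames <- data.frame(frame = seq_len(n_frames) - 1L, axial_um = axial_um,
                       segment = seg_of(axial_um / 1000))

  wall_um <- stats::approx(phantom$radius_profile$arc_length_mm,
                           phantom$radius_profile$radius_mm * 1000,
                           xout = axial_um / 1000, rule = 2)$y

  angles <- 0:359
  contours <- data.frame(
    frame = rep(frames$frame, each = length(angles)),
    angle_deg = rep(angles, n_frames),
    radius_um = rep(wall_um, each = length(angles)))

  # strut ring layout: pitch = clear gap + strut width, centered rings
  pitch_um <- design$inter_strut_distance_mm * 1000 + design$strut_width_um
  scaf_um <- segs$scaffolded * 1000
  ring_centers <- seq(scaf_um[1] + design$strut_width_um / 2, scaf_um[2],
                      by = pitch_um)
  ring_centers <- ring_centers[seq_len(min(length(ring_centers), design$n_rings))]

  struts_list <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    z <- axial_um[i]
    hit <- which(abs(z - ring_centers) <= design$strut_width_um / 2)
    if (!length(hit)) next
    k <- hit[1]  # rings never overlap (pitch > width)
    wall <- wall_um[i]
    span_deg <- design$strut_width_um / wall * 180 / pi
    offset <- ((k - 1) %% 2) * 180 / design$struts_per_ring
    centers <- (offset + (0:(design$struts_per_ring - 1)) *
                  360 / design$struts_per_ring) %% 360
    prot <- protrusion_fraction * design$strut_thickness_um
    if (protrusion_jitter_sd_um > 0) {
      prot <- prot + stats::rnorm(length(centers), 0, protrusion_jitter_sd_um)
      prot <- pmax(prot, 0)
    } else {
      prot <- rep(prot, length(centers))
    }
    adl <- wall - prot
    abl <- adl + design$strut_thickness_um
    struts_list[[i]] <- data.frame(
      frame = frames$frame[i], angle_center_deg = centers,
      angular_span_deg = span_deg,
      adluminal_radius_um = adl, abluminal_radius_um = abl,
      truth_protrusion_um = prot,
      truth_malapposed = (wall - abl) > 0)
  }
  struts <- do.call(rbind, struts_list)
  if (is.null(struts)) {
    struts <- data.frame(frame = integer(), angle_center_deg = numeric(),
                         angular_span_deg = numeric(),
                         adluminal_radius_um = numeric(),
                         abluminal_radius_um = numeric(),
                         truth_protrusion_um = numeric(),
                         truth_malapposed = logical())
  }
  rownames(struts) <- NULL

  structure(list(contours = contours, struts = struts, frames = frames,
                 design = design, frame_spacing_um = frame_spacing_um,
                 protrusion_fraction = protrusion_fraction,
                 ring_centers_um = ring_centers,
                 seed = as.integer(seed)),
            class = "pullback")
}

#' @exportS3Method base::print
print.pullback <- function(x, ...) {
  cat(sprintf("<pullback> %d frames at %g um spacing, %d strut observations (%s)\n",
              nrow(x$frames), x$frame_spacing_um, nrow(x$struts), x$design$name))
  invisible(x)
}

#' Write / read a pullback as CSV + JSON
#'
#' The on-disk dialect is plain text so exports from real contour-tracing
#' software can be hand-edited into it: `contours.csv` (one row per contour
#' point), `struts.csv` (one row per strut), `frames.csv`, and
#' `pullback.json` (metadata: design, spacing, protrusion fraction, seed).
#'
#' @param pb A `pullback`.
#' @param dir Directory to create/write into.
#' @return `write_pullback` returns `dir` invisibly; `read_pullback` returns
#'   a `pullback` (without ground-truth columns absent from the files).
#' @export
write_pullback <- function(pb, dir) {
  stopifnot(inherits(pb, "pullback"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pb$contours, file.path(dir, "contours.csv"), row.names = FALSE)
  utils::write.csv(pb$struts, file.path(dir, "struts.csv"), row.names = FALSE)
  utils::write.csv(pb$frames, file.path(dir, "frames.csv"), row.names = FALSE)
  meta <- list(design = unclass(pb$design),
               frame_spacing_um = pb$frame_spacing_um,
               protrusion_fraction = pb$protrusion_fraction,
               ring_centers_um = pb$ring_centers_um,
               seed = pb$seed)
  jsonlite::write_json(meta, file.path(dir, "pullback.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_pullback
#' @export
read_pullback <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pullback.json"),
                              simplifyVector = TRUE)
  design <- validate_scaffold_design(
    structure(as.list(meta$design), class = "scaffold_design"))
  structure(list(
    contours = utils::read.csv(file.path(dir, "contours.csv")),
    struts = utils::read.csv(file.path(dir, "struts.csv")),
    frames = utils::read.csv(file.path(dir, "frames.csv")),
    design = design,
    frame_spacing_um = meta$frame_spacing_um,
    protrusion_fraction = meta$protrusion_fraction,
    ring_centers_um = meta$ring_centers_um,
    seed = meta$seed), class = "pullback")
}
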