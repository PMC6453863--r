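polyline_arclen <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(d))
}

resample_polyline <- function(xy, s, s_out) {
  cbind(stats::approx(s, xy[, 1], xout = s_out)$y,
        stats::approx(s, xy[, 2], xout = s_out)$y)
}

#' Reconstruct a 3D centerline from two angiographic projections
#'
#' Recovers the 3D luminal centerline from a pair of 2D projections taken at
#' least 25 degrees apart. Because both views share the axial image
#' coordinate, the epipolar curves of this geometry are the horizontal image
#' lines: when both polylines are monotone in `v`, points are put in
#' correspondence on a common `v` grid (exact pairing); otherwise the pairing
#' falls back to normalized arc length. Each matched pair is back-projected
#' by solving the 2 x 2 linear system of the two orthographic view
#' equations. The result is resampled to a uniform arc-length step.
#'
#' @param pair A [project_centerline()] `projection_pair`.
#' @param step_mm Arc-length resampling step of the output (mm).
#' @param n_match Number of corresponded points before resampling.
#' @return Object of class `centerline3d`: `points` (n x 3, mm),
#'   `arc_length_mm`, and `residual_mm` (mean reprojection distance);
#'   frames are added by [compute_local_frames()].
#' @export
reconstruct_centerline_3d <- function(pair, step_mm = 0.1, n_match = 400) {
  stopifnot(inherits(pair, "projection_pair"))
  dang <- abs(pair$angle_a - pair$angle_b) %% 360
  dang <- min(dang, 360 - dang)
  if (dang < 25) {
    stop("projection angles only ", dang, " degrees apart; at least 25 ",
         "degrees are required for reconstruction", call. = FALSE)
  }
  sa <- polyline_arclen(pair$polyline_a)
  sb <- polyline_arclen(pair$polyline_b)
  la <- sa[length(sa)]; lb <- sb[length(sb)]
  if (abs(la - lb) / max(la, lb) > 0.2) {
    stop("projected polylines differ in length by more than 20% (",
         round(la, 2), " vs ", round(lb, 2), " mm)", call. = FALSE)
  }
  mono <- function(v) all(diff(v) > 0) || all(diff(v) < 0)
  va <- pair$polyline_a[, 2]; vb <- pair$polyline_b[, 2]
  if (mono(va) && mono(vb)) {
    # exact epipolar pairing on the shared axial image coordinate
    v0 <- max(min(va), min(vb)); v1 <- min(max(va), max(vb))
    vg <- seq(v0, v1, length.out = n_match)
    ua <- stats::approx(va, pair$polyline_a[, 1], xout = vg)$y
    ub <- stats::approx(vb, pair$polyline_b[, 1], xout = vg)$y
    pa <- cbind(ua, vg); pb <- cbind(ub, vg)
  } else {
    t <- seq(0, 1, length.out = n_match)
    pa <- resample_polyline(pair$polyline_a, sa / la, t)
    pb <- resample_polyline(pair$polyline_b, sb / lb, t)
  }

  ra <- pair$angle_a * pi / 180; rb <- pair$angle_b * pi / 180
  m <- matrix(c(cos(ra), sin(ra), cos(rb), sin(rb)), 2, 2, byrow = TRUE)
  xy <- t(solve(m, rbind(pa[, 1], pb[, 1])))
  pts <- cbind(xy, (pa[, 2] + pb[, 2]) / 2)

  s <- cumsum(c(0, sqrt(rowSums(diff(pts)^2))))
  s_out <- seq(0, s[length(s)], by = step_mm)
  pts_u <- cbind(stats::approx(s, pts[, 1], xout = s_out)$y,
                 stats::approx(s, pts[, 2], xout = s_out)$y,
                 stats::approx(s, pts[, 3], xout = s_out)$y)
  colnames(pts_u) <- c("x", "y", "z")

  # reprojection residual: mean distance of the re-projected recovery to the
  # original image polylines
  dist_to_polyline <- function(p, poly) {
    d2 <- rep(Inf, nrow(p))
    for (k in seq_len(nrow(poly) - 1)) {
      a <- poly[k, ]; b <- poly[k + 1, ]
      ab <- b - a
      tt <- pmin(pmax(((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) /
                        sum(ab^2), 0), 1)
      d2 <- pmin(d2, (p[, 1] - (a[1] + tt * ab[1]))^2 +
                   (p[, 2] - (a[2] + tt * ab[2]))^2)
    }
    sqrt(d2)
  }
  reproj <- function(p, ang) {
    cbind(p[, 1] * cos(ang * pi / 180) + p[, 2] * sin(ang * pi / 180), p[, 3])
  }
  res_a <- mean(dist_to_polyline(reproj(pts_u, pair$angle_a), pair$polyline_a))
  res_b <- mean(dist_to_polyline(reproj(pts_u, pair$angle_b), pair$polyline_b))

  structure(list(points = pts_u, arc_length_mm = s_out,
                 residual_mm = mean(c(res_a, res_b)), frames = NULL),
            class = "centerline3d")
}

#' Rotation-minimizing local frames along a centerline
#'
#' Computes unit tangents (central differences) and propagates a
#' normal/binormal pair along the centerline with the double-reflection
#' method, which minimizes twist: consecutive frames never flip, and for a
#' straight line the frame is constant.
#'
#' @param centerline A `centerline3d` (or a bare n x 3 point matrix).
#' @return The centerline with a `frames` field: list of `tangent`,
#'   `normal`, `binormal` (each n x 3, unit rows).
#' @export
compute_local_frames <- function(centerline) {
  pts <- if (inherits(centerline, "centerline3d")) centerline$points else centerline
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 centerline points", call. = FALSE)
  if (any(rowSums(diff(pts)^2) == 0)) {
    stop("duplicate consecutive centerline points", call. = FALSE)
  }
  tg <- rbind(pts[2, ] - pts[1, ],
              pts[3:n, ] - pts[1:(n - 2), ],
              pts[n, ] - pts[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))

  nrm <- matrix(0, n, 3)
  # initial normal: any unit vector orthogonal to t1
  t1 <- tg[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n0 <- ref - sum(ref * t1) * t1
  nrm[1, ] <- n0 / sqrt(sum(n0^2))
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1^2)
    rl <- nrm[i, ] - (2 / c1) * sum(v1 * nrm[i, ]) * v1
    tl <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1, ] - tl
    c2 <- sum(v2^2)
    nrm[i + 1, ] <- if (c2 < 1e-30) rl else rl - (2 / c2) * sum(v2 * rl) * v2
  }
  bn <- cbind(tg[, 2] * nrm[, 3] - tg[, 3] * nrm[, 2],
              tg[, 3] * nrm[, 1] - tg[, 1] * nrm[, 3],
              tg[, 1] * nrm[, 2] - tg[, 2] * nrm[, 1])
  if (inherits(centerline, "centerline3d")) {
    centerline$frames <- list(tangent = tg, normal = nrm, binormal = bn)
    centerline
  } else {
    structure(list(points = pts,
                   arc_length_mm = c(0, cumsum(sqrt(rowSums(diff(pts)^2)))),
                   residual_mm = NA_real_,
                   frames = list(tangent = tg, normal = nrm, binormal = bn)),
              class = "centerline3d")
  }
}

# circular mean of angle differences, degrees
circ_mean_deg <- function(a) {
  (atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi) %% 360
}

#' Mount OCT flow-area contours onto a 3D centerline
#'
#' Places each frame's flow-area contour in the plane normal to the
#' centerline tangent at its axial position, rotated about the tangent by a
#' single global angle chosen from side-branch landmarks (OCT angle vs
#' angiographic angle); consecutive contours are joined into a closed
#' triangle strip. Contours are resampled by interpolation to a 100 um
#' axial spacing in the scaffolded segment and 400 um in the native
#' segments.
#'
#' @param pullback A `pullback`.
#' @param centerline A `centerline3d` (frames are computed if absent).
#' @param landmarks Optional data.frame with `oct_angle_deg` and
#'   `angio_angle_deg`; without it the rotation defaults to 0 with a warning.
#' @param scaffold_spacing_um,native_spacing_um Mounting spacings.
#' @return Object of class `lumen_surface`: `vertices` (mm), `triangles`
#'   (1-based index triples), per-vertex `labels` (`native`,
#'   `inter_strut_wall`, `strut_adluminal`), `axial_um`, `sector_angle_deg`,
#'   `radius_mm`, `rotation_deg`, `watertight`.
#' @export
mount_contours <- function(pullback, centerline, landmarks = NULL,
                           scaffold_spacing_um = 100, native_spacing_um = 400) {
  stopifnot(inherits(pullback, "pullback"), inherits(centerline, "centerline3d"))
  if (is.null(centerline$frames)) centerline <- compute_local_frames(centerline)
  frames <- pullback$frames
  cl_len_um <- max(centerline$arc_length_mm) * 1000
  if (max(frames$axial_um) > cl_len_um + 1e-6) {
    stop("pullback axial extent (", max(frames$axial_um) / 1000,
         " mm) exceeds centerline arc length (", cl_len_um / 1000, " mm)",
         call. = FALSE)
  }
  if (pullback$frame_spacing_um / min(scaffold_spacing_um, native_spacing_um) > 4) {
    stop("requested contour spacing is finer than the available frames by ",
         "more than 4x; interpolation refused", call. = FALSE)
  }
  rot <- 0
  if (!is.null(landmarks) && nrow(landmarks)) {
    rot <- circ_mean_deg(landmarks$angio_angle_deg - landmarks$oct_angle_deg)
  } else {
    warning("no landmarks: absolute orientation defaults to rotation 0",
            call. = FALSE)
  }

  # target axial stations per segment
  seg_targets <- function(seg, spacing) {
    fr <- frames[frames$segment == seg, ]
    if (!nrow(fr)) return(numeric())
    seq(min(fr$axial_um), max(fr$axial_um), by = spacing)
  }
  targets <- sort(unique(c(seg_targets("proximal_native", native_spacing_um),
                           seg_targets("scaffolded", scaffold_spacing_um),
                           seg_targets("distal_native", native_spacing_um))))
  seg_of <- function(z) {
    sc <- range(frames$axial_um[frames$segment == "scaffolded"])
    ifelse(z < sc[1], "proximal_native",
           ifelse(z > sc[2], "distal_native", "scaffolded"))
  }

  # flow-area contour radius matrix: frames x 360 angles
  angles <- sort(unique(pullback$contours$angle_deg))
  na <- length(angles)
  fc <- matrix(NA_real_, nrow(frames), na)
  strut_mask <- matrix(FALSE, nrow(frames), na)
  for (k in seq_len(nrow(frames))) {
    f <- frames$frame[k]
    ct <- get_contour(pullback, f)
    st <- pullback$struts[pullback$struts$frame == f, ]
    flow <- build_flow_area_contour(ct, st)
    fc[k, ] <- flow$radius_um[match(angles, flow$angle_deg)]
    if (nrow(st)) {
      for (q in seq_len(nrow(st))) {
        strut_mask[k, circ_dist(angles, st$angle_center_deg[q]) <=
                     st$angular_span_deg[q] / 2] <- TRUE
      }
    }
  }

  nt <- length(targets)
  verts <- matrix(0, nt * na, 3)
  labels <- character(nt * na)
  axial <- numeric(nt * na)
  sect <- numeric(nt * na)
  radii <- numeric(nt * na)
  cl_s <- centerline$arc_length_mm * 1000
  for (k in seq_len(nt)) {
    z <- targets[k]
    # interpolate contour radii between flanking frames
    r_um <- vapply(seq_len(na), function(a) {
      stats::approx(frames$axial_um, fc[, a], xout = z, rule = 2)$y
    }, numeric(1))
    # centerline position and frame at arc length z (linear interp + renorm)
    ip <- function(mat) {
      vapply(1:3, function(d) stats::approx(cl_s, mat[, d], xout = z, rule = 2)$y,
             numeric(1))
    }
    cpt <- ip(centerline$points)
    nn <- ip(centerline$frames$normal); nn <- nn / sqrt(sum(nn^2))
    tb <- ip(centerline$frames$tangent); tb <- tb / sqrt(sum(tb^2))
    bb <- c(tb[2] * nn[3] - tb[3] * nn[2], tb[3] * nn[1] - tb[1] * nn[3],
            tb[1] * nn[2] - tb[2] * nn[1])
    phi <- (angles + rot) * pi / 180
    idx <- (k - 1) * na + seq_len(na)
    verts[idx, ] <- matrix(cpt, na, 3, byrow = TRUE) +
      (r_um / 1000) * (outer(cos(phi), nn) + outer(sin(phi), bb))
    seg <- seg_of(z)
    near <- which.min(abs(frames$axial_um - z))
    on_strut <- strut_mask[near, ] &
      abs(frames$axial_um[near] - z) <= pullback$design$strut_width_um / 2
    labels[idx] <- ifelse(seg != "scaffolded", "native",
                          ifelse(on_strut, "strut_adluminal", "inter_strut_wall"))
    axial[idx] <- z
    sect[idx] <- (angles + rot) %% 360
    radii[idx] <- r_um / 1000
  }

  tri <- vector("list", nt - 1)
  for (k in seq_len(nt - 1)) {
    i0 <- (k - 1) * na; i1 <- k * na
    a <- seq_len(na); b <- c(2:na, 1)
    tri[[k]] <- rbind(cbind(i0 + a, i0 + b, i1 + a),
                      cbind(i0 + b, i1 + b, i1 + a))
  }
  structure(list(vertices = verts, triangles = do.call(rbind, tri),
                 labels = labels, axial_um = axial, sector_angle_deg = sect,
                 radius_mm = radii, rotation_deg = rot, n_stations = nt,
                 n_angles = na, watertight = TRUE),
            class = "lumen_surface")
}

#' @exportS3Method base::print
print.lumen_surface <- function(x, ...) {
  cat(sprintf("<lumen_surface> %d vertices (%d stations x %d angles), %d triangles, rotation %.1f deg\n",
              nrow(x$vertices), x$n_stations, x$n_angles, nrow(x$triangles),
              x$rotation_deg))
  invisible(x)
}

#' Export a lumen surface as ASCII PLY
#'
#' Writes vertices (with label, axial position and sector angle as scalar
#' properties) and triangles in the plain-text PLY dialect.
#'
#' @param surface A `lumen_surface`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_surface_ply <- function(surface, path) {
  lab <- match(surface$labels, c("native", "inter_strut_wall", "strut_adluminal")) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(surface$vertices)),
               "property float x", "property float y", "property float z",
               "property int label", "property float axial_um",
               "property float sector_deg",
               paste("element face", nrow(surface$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(cbind(format(surface$vertices, digits = 7), lab,
                           surface$axial_um, surface$sector_angle_deg),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, surface$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
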