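test_that("a straight line reconstructs exactly from any valid pair", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  cl <- reconstruct_centerline_3d(project_centerline(ph, 0, 90))
  expect_true(all(abs(cl$points[, 1:2]) < 1e-9))
  expect_lt(cl$residual_mm, 1e-9)
})

test_that("a helix is recovered to under 1% of segment length", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1,
                       helix_radius_mm = 2, helix_pitch_mm = 10)
  cl <- reconstruct_centerline_3d(project_centerline(ph, 0, 90))
  err <- vapply(seq_len(nrow(cl$points)), function(i) {
    min(sqrt(colSums((t(ph$centerline) - cl$points[i, ])^2)))
  }, numeric(1))
  expect_lt(max(err), 0.01 * 14)
  expect_lt(cl$residual_mm, 0.01)
})

test_that("projection pairs under 25 degrees apart are rejected", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  expect_error(reconstruct_centerline_3d(project_centerline(ph, 0, 20)),
               "25")
})

test_that("local frames are constant on a line and planar on an arc", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  cl <- compute_local_frames(reconstruct_centerline_3d(project_centerline(ph, 0, 90)))
  tg <- cl$frames$tangent
  expect_true(all(abs(tg[, 1]) < 1e-9 & abs(tg[, 2]) < 1e-9))
  expect_lt(max(apply(cl$frames$normal, 2, function(v) diff(range(v)))), 1e-9)

  # planar arc in the x-z plane: binormal constant and orthogonal to it
  arc <- vessel_phantom(14, 1.5, curvature = 0.05, seed = 1)
  fr <- compute_local_frames(arc$centerline)$frames
  expect_lt(max(abs(abs(fr$binormal[, 2]) - 1)), 1e-6)
  expect_lt(max(apply(fr$binormal, 2, stats::sd)), 1e-6)
})

test_that("rotation-minimizing frames drift from Frenet frames at the torsion rate", {
  a <- 2; pitch <- 10; b <- pitch / (2 * pi)
  ph <- vessel_phantom(14, 1.5, 0, seed = 1,
                       helix_radius_mm = a, helix_pitch_mm = pitch, step_mm = 0.02)
  fr <- compute_local_frames(ph$centerline)$frames
  s <- ph$arc_length_mm
  t_par <- s / sqrt(a^2 + b^2)
  frenet_n <- -cbind(cos(t_par), sin(t_par), 0)   # principal normal of a helix
  # signed angle between RMF normal and Frenet normal about the tangent
  ang <- vapply(seq_along(s), function(i) {
    n1 <- fr$normal[i, ]; n2 <- frenet_n[i, ]; tg <- fr$tangent[i, ]
    atan2(sum(tg * c(n1[2] * n2[3] - n1[3] * n2[2],
                     n1[3] * n2[1] - n1[1] * n2[3],
                     n1[1] * n2[2] - n1[2] * n2[1])), sum(n1 * n2))
  }, numeric(1))
  ang <- ang - ang[1]
  ang_un <- cumsum(c(0, ((diff(ang) + pi) %% (2 * pi)) - pi))  # unwrap
  twist_rate <- abs(stats::coef(stats::lm(ang_un ~ s))[2])
  torsion <- b / (a^2 + b^2)
  expect_lt(abs(twist_rate - torsion) / torsion, 0.02)
  # no flips: consecutive normals stay aligned
  dots <- rowSums(fr$normal[-1, ] * fr$normal[-nrow(fr$normal), ])
  expect_true(all(dots > 0))
})

test_that("frame computation rejects degenerate polylines", {
  expect_error(compute_local_frames(matrix(0, 2, 3)), "3")
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1), c(0, 0, 2))
  expect_error(compute_local_frames(pts), "duplicate")
})

test_that("mounting circular contours on a straight centerline gives a cylinder", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0, seed = 1)    # flush struts: pure cylinder
  cl <- compute_local_frames(reconstruct_centerline_3d(project_centerline(ph, 0, 90)))
  lm <- data.frame(oct_angle_deg = 30, angio_angle_deg = 90)
  surf <- mount_contours(pb, cl, lm)
  expect_equal(surf$rotation_deg, 60)   # one-landmark closed form
  r <- sqrt(surf$vertices[, 1]^2 + surf$vertices[, 2]^2)
  expect_lt(max(abs(r - 1.5)), 1e-9)
  expect_warning(mount_contours(pb, cl), "landmark")
})

test_that("mounting preserves contour perimeter (rigid placement)", {
  ph <- vessel_phantom(10, 1.5, 0, seed = 5)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0.97, seed = 5)
  cl <- compute_local_frames(reconstruct_centerline_3d(project_centerline(ph, 10, 60)))
  surf <- suppressWarnings(mount_contours(pb, cl))
  # perimeter of the first mounted station vs its polar contour
  na <- surf$n_angles
  v1 <- surf$vertices[seq_len(na), ]
  per_mounted <- sum(sqrt(rowSums((v1[c(2:na, 1), ] - v1)^2)))
  r_um <- surf$radius_mm[seq_len(na)] * 1000
  th <- (seq_len(na) - 1) * 2 * pi / na
  xy <- cbind(r_um * cos(th), r_um * sin(th)) / 1000
  per_contour <- sum(sqrt(rowSums((xy[c(2:na, 1), ] - xy)^2)))
  expect_equal(per_mounted, per_contour, tolerance = 1e-9)
})

test_that("mounting refuses interpolation finer than 4x the frame spacing", {
  ph <- vessel_phantom(10, 1.5, 0, seed = 1)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0.5, frame_spacing_um = 500, seed = 1)
  cl <- compute_local_frames(reconstruct_centerline_3d(project_centerline(ph, 0, 90)))
  expect_error(suppressWarnings(mount_contours(pb, cl, scaffold_spacing_um = 100)),
               "refused")
})

test_that("phantom round trip: simulate, project, reconstruct, mount", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 2)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0.97, seed = 3)
  cl <- compute_local_frames(reconstruct_centerline_3d(project_centerline(ph, 30, 120)))
  # centerline error against the analytic phantom
  cerr <- vapply(seq_len(nrow(cl$points)), function(i) {
    min(sqrt(colSums((t(ph$centerline) - cl$points[i, ])^2)))
  }, numeric(1))
  expect_lt(max(cerr), 0.01 * 14)
  surf <- mount_contours(pb, cl, data.frame(oct_angle_deg = 0, angio_angle_deg = 0))
  # distance oracle against the analytic flow surface: wall cylinder, except
  # the adluminal cylinder across each ring's axial extent
  r <- sqrt(surf$vertices[, 1]^2 + surf$vertices[, 2]^2)
  adl <- 1.5 - 0.97 * 157 / 1000
  d <- abs(r - 1.5)
  in_ring <- rowSums(outer(surf$axial_um, pb$ring_centers_um,
                           function(z, c) abs(z - c) <= ab$strut_width_um / 2)) > 0
  d[in_ring] <- pmin(d[in_ring], abs(r[in_ring] - adl))
  expect_lt(mean(d) * 1000, 50)
})

test_that("PLY export writes a parseable ASCII mesh", {
  ph <- vessel_phantom(6, 1.5, 0, seed = 1, native_margin_mm = 1)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0, seed = 1)
  cl <- compute_local_frames(reconstruct_centerline_3d(project_centerline(ph, 0, 90)))
  surf <- suppressWarnings(mount_contours(pb, cl, native_spacing_um = 400))
  f <- withr::local_tempfile(fileext = ".ply")
  write_surface_ply(surf, f)
  hdr <- readLines(f, n = 20)
  expect_equal(hdr[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", hdr, value = TRUE)))
  expect_equal(nv, nrow(surf$vertices))
})
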