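test_that("flow-area contour replaces wall with adluminal edges inside spans", {
  ct <- circle_contour(1500)
  expect_identical(build_flow_area_contour(ct, NULL), ct)

  st <- strut_row(90, 20, 1405)
  flow <- build_flow_area_contour(ct, st)
  inside <- abs(flow$angle_deg - 90) <= 10
  expect_true(all(flow$radius_um[inside] == 1405))
  expect_true(all(flow$radius_um[!inside] == 1500))

  # polygon-area oracle (shoelace computed inline, independent of contour_area)
  th <- flow$angle_deg * pi / 180
  x <- flow$radius_um * cos(th); y <- flow$radius_um * sin(th)
  i2 <- c(seq_along(x)[-1], 1)
  shoelace <- abs(sum(x * y[i2] - x[i2] * y)) / 2
  expect_equal(contour_area(flow), shoelace)
  expect_lt(contour_area(flow), contour_area(ct))

  # full-circumference ring collapses to the adluminal circle
  ring <- strut_row(180, 360, 1405)
  full <- build_flow_area_contour(ct, ring)
  expect_true(all(full$radius_um == 1405))
})

test_that("flow-area construction rejects impossible strut layouts", {
  ct <- circle_contour(1500)
  expect_error(build_flow_area_contour(ct, rbind(strut_row(90, 20, 1405),
                                                 strut_row(100, 20, 1405))),
               "overlap")
  expect_error(build_flow_area_contour(ct, strut_row(90, 20, 1600)),
               "inverted")
})

test_that("protrusion distance interpolates the wall across the strut span", {
  ct <- circle_contour(1500)
  expect_equal(protrusion_distance(strut_row(90, 20, 1405), ct), 95)
  expect_equal(protrusion_distance(strut_row(90, 20, 1500), ct), 0)

  # wall varying linearly 1480 -> 1520 um across a 20-degree span at 90:
  # linear-interpolation oracle gives mean wall 1500
  ct2 <- circle_contour(1500)
  ramp <- ct2$angle_deg >= 80 & ct2$angle_deg <= 100
  ct2$radius_um[ramp] <- 1480 + (ct2$angle_deg[ramp] - 80) * 2
  expect_equal(protrusion_distance(strut_row(90, 20, 1400), ct2), 100)
})

test_that("apposition classification uses a strict detachment tolerance", {
  ct <- circle_contour(1500)
  # abluminal edge on the wall: protruding, never malapposed
  expect_equal(classify_apposition(strut_row(90, 20, 1405, 1500), ct, 20),
               "protruding")
  expect_equal(classify_apposition(strut_row(90, 20, 1500, 1657), ct, 20),
               "embedded")
  expect_equal(classify_apposition(strut_row(90, 20, 1285, 1380), ct, 20),
               "malapposed")     # gap 120 > 20
  # gap exactly equal to the tolerance is not malapposed (strict >)
  expect_equal(classify_apposition(strut_row(90, 20, 1385, 1480), ct, 20),
               "protruding")
})

test_that("protrusion round-trips from generator ground truth within 1 um", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  for (preset in c("absorb_like", "arteriosorb_like")) {
    d <- scaffold_design(preset)
    pf <- if (preset == "absorb_like") 0.97 else 0.88
    pb <- simulate_pullback(ph, d, pf, seed = 4, protrusion_jitter_sd_um = 3)
    meas <- measure_protrusion(pb)
    apposed <- meas$apposition != "malapposed"
    expect_true(all(abs(meas$protrusion_um[apposed] -
                          pb$struts$truth_protrusion_um[apposed]) < 1))
  }
})

test_that("protrusion aggregation respects levels and interval partition", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  ar <- scaffold_design("arteriosorb_like")
  pb <- simulate_pullback(ph, ar, 84 / 95, seed = 1)   # all struts at 84 um
  for (lev in c("device", "cross_section", "interval_200um")) {
    agg <- aggregate_protrusion(pb, lev)
    expect_true(all(abs(agg$mean_um - 84) < 1e-9))
    expect_true(all(agg$sd_um < 1e-9))
  }
  dev <- aggregate_protrusion(pb, "device")
  expect_equal(dev$protrusion_fraction_pct, 88)
  # every apposed strut contributes to exactly one 200 um interval
  iv <- aggregate_protrusion(pb, "interval_200um")
  expect_equal(sum(iv$n_struts), nrow(pb$struts))
  expect_equal(dev$n_struts, sum(iv$n_struts))
})

test_that("device mean of two equally sized intervals is the balanced average", {
  ph <- vessel_phantom(6, 1.5, 0, seed = 1, native_margin_mm = 1)
  d <- scaffold_design("custom", strut_thickness_um = 100,
                       strut_width_um = 170, inter_strut_distance_mm = 1.4,
                       coverage_ratio = 0.3, n_rings = 2)
  pb <- simulate_pullback(ph, d, 0.8, seed = 1)
  frames_with <- unique(pb$struts$frame)
  expect_gte(length(frames_with), 2)
  f1 <- frames_with[1]; f2 <- frames_with[2]
  pb$struts <- pb$struts[pb$struts$frame %in% c(f1, f2), ]
  wall <- 1500
  pb$struts$adluminal_radius_um <- ifelse(pb$struts$frame == f1,
                                          wall - 80, wall - 88)
  pb$struts$abluminal_radius_um <- pb$struts$adluminal_radius_um + 100
  expect_equal(aggregate_protrusion(pb, "device")$mean_um, 84)
})

test_that("protrusion fraction matches the published percentages and scales", {
  expect_equal(protrusion_fraction(153, 157), 97)
  expect_equal(protrusion_fraction(84, 95), 88)
  expect_equal(protrusion_fraction(0, 157), 0)
  # scale invariance
  expect_equal(protrusion_fraction(306, 314), protrusion_fraction(153, 157))
  expect_error(protrusion_fraction(100, 0))
})

test_that("flow-area never exceeds wall area; equal only without protrusion", {
  ph <- vessel_phantom(6, 1.5, 0, seed = 2, native_margin_mm = 1)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0.9, seed = 2)
  f <- unique(pb$struts$frame)[1]
  ct <- get_contour(pb, f)
  st <- pb$struts[pb$struts$frame == f, ]
  expect_lt(contour_area(build_flow_area_contour(ct, st)), contour_area(ct))
  flush <- simulate_pullback(ph, ab, 0, seed = 2)
  stf <- flush$struts[flush$struts$frame == f, ]
  expect_equal(contour_area(build_flow_area_contour(ct, stf)),
               contour_area(ct))
})
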