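test_that("zero-curvature phantom is a straight cylinder of the stated length", {
  ph <- vessel_phantom(14, 1.5, curvature = 0, seed = 1)
  expect_true(all(abs(ph$centerline[, 1:2]) < 1e-12))
  expect_true(all(ph$radius_profile$radius_mm == 1.5))
  expect_true(all(diff(ph$arc_length_mm) > 0))
  # polyline-length oracle for the arc length
  len <- sum(sqrt(rowSums(diff(ph$centerline)^2)))
  expect_lt(abs(len - 14) / 14, 0.001)
})

test_that("curved phantom has the stated arc length and is seed-deterministic", {
  p1 <- vessel_phantom(14, 1.5, curvature = 0.02, seed = 1)
  p2 <- vessel_phantom(14, 1.5, curvature = 0.02, seed = 1)
  expect_identical(p1, p2)
  len <- sum(sqrt(rowSums(diff(p1$centerline)^2)))
  expect_lt(abs(len - 14) / 14, 0.001)
  expect_error(vessel_phantom(-1, 1.5, 0, 1))
  expect_error(vessel_phantom(14, 0, 0, 1))
})

test_that("projections are orthographic and reject degenerate angle pairs", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  pr <- project_centerline(ph, 0, 90)
  # projection of a straight axial line is a straight vertical line
  expect_true(all(abs(pr$polyline_a[, 1]) < 1e-12))
  expect_true(all(abs(pr$polyline_b[, 1]) < 1e-12))
  expect_error(project_centerline(ph, 30, 30), "degenerate")
  expect_error(project_centerline(ph, 0, 180), "degenerate")
})

test_that("pullback strut placement follows the protrusion fraction", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  ab <- scaffold_design("absorb_like")

  flush <- simulate_pullback(ph, ab, 0, seed = 1)
  expect_true(all(flush$struts$truth_protrusion_um == 0))
  expect_false(any(flush$struts$truth_malapposed))

  deep <- simulate_pullback(ph, ab, 0.97, seed = 1)
  expect_equal(mean(deep$struts$truth_protrusion_um), 0.97 * 157,
               tolerance = 1e-10)
  expect_false(any(deep$struts$truth_malapposed))

  mal <- simulate_pullback(ph, ab, 1.1, seed = 1)
  expect_true(all(mal$struts$truth_malapposed))
  # abluminal edge clear of the wall: geometric oracle
  wall <- 1500
  expect_true(all(mal$struts$abluminal_radius_um < wall))

  expect_error(simulate_pullback(ph, ab, 1.3, seed = 1))
  thick <- scaffold_design("custom", strut_thickness_um = 1300,
                           strut_width_um = 170,
                           inter_strut_distance_mm = 1.4,
                           coverage_ratio = 0.3)
  expect_error(simulate_pullback(ph, thick, 1.2, seed = 1), "lumen")
})

test_that("pullback generation is bit-identical for equal seeds", {
  ph <- vessel_phantom(14, 1.5, 0, seed = 1)
  ab <- scaffold_design("absorb_like")
  a <- simulate_pullback(ph, ab, 0.97, seed = 7, protrusion_jitter_sd_um = 3)
  b <- simulate_pullback(ph, ab, 0.97, seed = 7, protrusion_jitter_sd_um = 3)
  expect_identical(a, b)
})

test_that("pullback survives a CSV/JSON round trip", {
  ph <- vessel_phantom(6, 1.5, 0, seed = 1, native_margin_mm = 1)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0.5, seed = 2)
  dir <- withr::local_tempdir()
  write_pullback(pb, dir)
  back <- read_pullback(dir)
  expect_equal(back$contours, pb$contours)
  expect_equal(back$struts$adluminal_radius_um, pb$struts$adluminal_radius_um)
  expect_equal(back$design$strut_thickness_um, 157)
})

test_that("hierarchical generator reduces to a pure shift when noise is off", {
  spec <- hierarchy_spec(sd_animal = 0, sd_scaffold = 0, sd_cross_section = 0,
                         sd_sector = 0, fixed_effect_delta = 0.79, seed = 3)
  recs <- simulate_hierarchical_ess(spec)
  ab <- recs$ess[recs$scaffold_type == "absorb_like"]
  ar <- recs$ess[recs$scaffold_type == "arteriosorb_like"]
  expect_true(all(ab == 0.73))
  expect_true(all(ar == 0.73 + 0.79))
})

test_that("hierarchical generator moments match the spec at large n", {
  spec <- hierarchy_spec(n_animals = 2, scaffolds_per_animal = 1,
                         cross_sections_per_scaffold = 70,
                         sd_animal = 0, sd_scaffold = 0, sd_cross_section = 0,
                         sd_sector = 1, fixed_effect_delta = 0, seed = 11)
  recs <- simulate_hierarchical_ess(spec)
  expect_gte(nrow(recs), 1e4)
  expect_lt(abs(sd(recs$ess) - 1), 0.05)
  expect_lt(abs(mean(recs$ess) - 0.73), 0.05)
  # seeded reproducibility
  expect_identical(recs, simulate_hierarchical_ess(spec))
})
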