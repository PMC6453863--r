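test_that("contrast-transit flow estimation is unit-consistent and linear", {
  v <- estimate_inlet_velocity(10, 15, 100, 7.07)
  expect_equal(v, (100 * 15 / 10) / 7.07 / 1000, tolerance = 1e-12)
  expect_equal(v, 0.0212, tolerance = 0.001)
  expect_equal(estimate_inlet_velocity(10, 30, 100, 7.07), 2 * v)
  expect_error(estimate_inlet_velocity(0, 15, 100, 7.07))
  # the largest in-vivo velocity scale is reachable with plausible inputs
  v_max <- estimate_inlet_velocity(5, 15, 100 * 0.181 / 0.0212 / 2.85, 7.07)
  expect_gt(v_max, 0.0212)
})

test_that("mesh targets one fifth of the strut thickness", {
  m95 <- axisym_mesh(4, 1.5, 95, coarsening = 1)
  expect_equal(m95$target_edge_um, 19)
  m157 <- axisym_mesh(4, 1.5, 157, coarsening = 1)
  expect_equal(m157$target_edge_um, 31.4)
  expect_lt(abs(m157$achieved_edge_um - 31.4) / 31.4, 0.05)
  expect_message(axisym_mesh(4, 1.5, 157, coarsening = 2), "coarsening")
  # 2D axisymmetric discretization: cell count grows ~(1/edge)^2
  m2 <- suppressMessages(axisym_mesh(4, 1.5, 157, coarsening = 2))
  ratio <- (m157$nz * m157$nr) / (m2$nz * m2$nr)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
  # explicit failure when the cell budget is exceeded, no silent degrade
  expect_error(axisym_mesh(40, 1.5, 157, coarsening = 1, max_cells = 1e4),
               "budget")
})

test_that("strut-free cylinder reproduces Poiseuille wall shear stress", {
  sol <- poiseuille_solution()
  expect_true(sol$converged)
  w <- compute_wss(sol)
  tau <- mean(w$wss_pa[abs(w$z_mm - 4) < 1])
  expect_lt(abs(tau - 1.4) / 1.4, 0.05)   # tau = 4*mu*v/R = 1.4 Pa
  # axial velocity profile at mid-length matches Poiseuille within 3%
  m <- sol$mesh
  i <- round(m$nz / 2)
  r <- (seq_len(m$nr) - 0.5) * m$dr
  u_exact <- 2 * 0.15 * (1 - (r / m$radius_m)^2)
  expect_lt(max(abs(sol$u[i, ] - u_exact)) / (2 * 0.15), 0.03)
})

test_that("WSS on the strut-free cylinder converges monotonically with the mesh", {
  errs <- vapply(c(6, 3, 1.5), function(cf) {
    m <- suppressMessages(axisym_mesh(4, 1.5, 157, coarsening = cf))
    s <- solve_steady_flow(m, flow_conditions(0.15), max_iter = 3000)
    w <- compute_wss(s)
    abs(mean(w$wss_pa[abs(w$z_mm - 2.5) < 0.6]) - 1.4) / 1.4
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("mass is conserved through every cross-section", {
  sol <- poiseuille_solution()
  expect_lt(attr(flux_profile(sol), "max_rel_error"), 0.01)
})

test_that("Stokes-regime solutions scale linearly with inlet velocity", {
  m <- suppressMessages(axisym_mesh(4, 1.5, 157, coarsening = 3))
  s1 <- solve_steady_flow(m, flow_conditions(1e-4), max_iter = 2000)
  expect_lt(s1$reynolds, 1)
  s2 <- solve_steady_flow(m, flow_conditions(2e-4), max_iter = 2000)
  w1 <- compute_wss(s1); w2 <- compute_wss(s2)
  expect_lt(max(abs(w2$wss_pa - 2 * w1$wss_pa) / max(w2$wss_pa)), 0.01)
})

test_that("flat inlet profile develops into Poiseuille over the entrance length", {
  m <- suppressMessages(axisym_mesh(3, 1.5, 157, coarsening = 3))
  cond <- flow_conditions(0.01, inlet_profile = "flat")
  sol <- solve_steady_flow(m, cond, max_iter = 3000)
  w <- compute_wss(sol)
  tau_ref <- 4 * 0.0035 * 0.01 / 0.0015
  expect_lt(abs(mean(w$wss_pa[abs(w$z_mm - 1.5) < 0.5]) - tau_ref) / tau_ref,
            0.05)
})

test_that("a protruding strut ring causes downstream recirculation", {
  d <- scaffold_design("absorb_like")
  rings <- data.frame(z_center_mm = 3, width_um = 176, protrusion_um = 100)
  m <- suppressMessages(axisym_mesh(6, 1.5, 157, rings = rings, coarsening = 2))
  sol <- solve_steady_flow(m, flow_conditions(0.15), max_iter = 4000)
  expect_true(sol$converged)
  w <- compute_wss(sol)
  down <- w[w$z_mm > 3.1 & w$z_mm < 3.6 & !w$on_strut, ]
  expect_true(any(down$u_near_wall_ms < 0))
  expect_lt(attr(flux_profile(sol), "max_rel_error"), 0.01)
  # no-slip: velocity inside the solid mask is identically zero
  expect_true(all(sol$u[cbind(which(m$solid, arr.ind = TRUE))] == 0))
})

test_that("turbulent-regime inputs are rejected", {
  m <- suppressMessages(axisym_mesh(4, 1.5, 157, coarsening = 4))
  expect_error(solve_steady_flow(m, flow_conditions(3)), "Reynolds")
  expect_error(flow_conditions(0))
})

test_that("mean inter-strut WSS is non-increasing in protrusion depth", {
  taus <- vapply(c(0, 50, 100, 150), function(prot) {
    rings <- data.frame(z_center_mm = seq(1.5, 8.5, by = 1.176),
                        width_um = 176, protrusion_um = prot)
    if (prot == 0) rings <- NULL
    m <- suppressMessages(axisym_mesh(10, 1.5, 157, rings = rings,
                                      coarsening = 3))
    s <- solve_steady_flow(m, flow_conditions(0.15), max_iter = 4000)
    w <- compute_wss(s)
    mean(w$wss_pa[!w$on_strut & w$z_mm > 1.5 & w$z_mm < 8.5])
  }, numeric(1))
  # non-increasing: stair-step masking can tie neighboring depths at desk
  # resolution, but the trend must never invert
  expect_true(all(diff(taus) < 1e-10))
  expect_lt(taus[4], 0.9 * taus[1])
})

test_that("meshes derive from pullbacks and mounted surfaces", {
  ph <- vessel_phantom(10, 1.5, 0, seed = 1)
  ab <- scaffold_design("absorb_like")
  pb <- simulate_pullback(ph, ab, 0.97, seed = 2)
  m <- suppressMessages(generate_mesh(pb, coarsening = 3))
  expect_s3_class(m, "flow_mesh")
  expect_equal(m$radius_m, 1.5e-3, tolerance = 1e-6)
  expect_equal(m$length_m, 10e-3, tolerance = 1e-3)
  # derived rings carry the measured protrusion depth
  expect_equal(mean(m$rings$protrusion_um), 0.97 * 157, tolerance = 0.01)
  expect_true(any(m$solid))

  cl <- compute_local_frames(reconstruct_centerline_3d(project_centerline(ph, 0, 90)))
  surf <- suppressWarnings(mount_contours(pb, cl))
  ms <- suppressMessages(generate_mesh(surf, coarsening = 3,
                                       strut_thickness_um = 157))
  expect_true(any(ms$solid))   # strut indentations carved into the mask
  broken <- surf
  broken$watertight <- FALSE
  expect_error(generate_mesh(broken, strut_thickness_um = 157), "watertight")
})
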