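#' Flow boundary conditions and fluid properties
#'
#' Blood is modeled as a homogeneous Newtonian fluid; defaults are a
#' viscosity of 0.0035 Pa.s and a density of 1050 kg/m^3. The outlet is held
#' at zero (reference) pressure and the wall is rigid with no-slip.
#'
#' @param inlet_mean_velocity Mean inlet velocity (m/s), > 0.
#' @param viscosity Dynamic viscosity (Pa.s).
#' @param density Density (kg/m^3).
#' @param inlet_profile `"parabolic"` (fully developed) or `"flat"`; a flat
#'   profile gets an entrance length of 10 diameters prepended at solve time.
#' @param outlet_pressure Outlet reference pressure (Pa).
#' @return Object of class `flow_conditions`.
#' @export
flow_conditions <- function(inlet_mean_velocity, viscosity = 0.0035,
                            density = 1050,
                            inlet_profile = c("parabolic", "flat"),
                            outlet_pressure = 0) {
  inlet_profile <- match.arg(inlet_profile)
  if (viscosity <= 0 || density <= 0 || inlet_mean_velocity <= 0) {
    stop("viscosity, density and inlet_mean_velocity must be > 0", call. = FALSE)
  }
  structure(list(inlet_mean_velocity = inlet_mean_velocity,
                 viscosity = viscosity, density = density,
                 inlet_profile = inlet_profile,
                 outlet_pressure = outlet_pressure),
            class = "flow_conditions")
}

#' Inlet velocity from contrast transit
#'
#' Estimates volumetric flow from the number of cine frames the contrast
#' agent needs to traverse the reconstructed segment: `Q = volume *
#' frame_rate / n_frames`, and mean inlet velocity as `Q / inlet_area`.
#'
#' @param n_frames Frames for contrast to pass inlet to outlet.
#' @param frame_rate_fps Cine frame rate (frames/s).
#' @param segment_volume_mm3 Volume of the reconstructed segment (mm^3).
#' @param inlet_area_mm2 Inlet cross-sectional area (mm^2).
#' @return Mean inlet velocity in m/s.
#' @examples
#' estimate_inlet_velocity(10, 15, 100, 7.07)  # ~0.0212 m/s
#' @export
estimate_inlet_velocity <- function(n_frames, frame_rate_fps,
                                    segment_volume_mm3, inlet_area_mm2) {
  if (any(c(n_frames, frame_rate_fps, segment_volume_mm3, inlet_area_mm2) <= 0)) {
    stop("all flow-estimation inputs must be > 0", call. = FALSE)
  }
  q_mm3_s <- segment_volume_mm3 * frame_rate_fps / n_frames
  (q_mm3_s / inlet_area_mm2) / 1000   # mm/s -> m/s
}

#' Strut ring layout for an axisymmetric flow model
#'
#' Lays scaffold strut rings along `[start_mm, end_mm]` with a ring pitch of
#' clear inter-strut distance + strut width (matching the pullback
#' generator), each ring protruding `protrusion_fraction` of the strut
#' thickness into the lumen.
#'
#' @param design A [scaffold_design()].
#' @param start_mm,end_mm Scaffolded range (mm).
#' @param protrusion_fraction Fraction of strut thickness protruding.
#' @param n_rings Cap on the number of rings (default: design's `n_rings`).
#' @return data.frame with `z_center_mm`, `width_um`, `protrusion_um`.
#' @export
scaffold_rings <- function(design, start_mm, end_mm, protrusion_fraction,
                           n_rings = design$n_rings) {
  pitch_mm <- design$inter_strut_distance_mm + design$strut_width_um / 1000
  centers <- seq(start_mm + design$strut_width_um / 2000, end_mm, by = pitch_mm)
  centers <- centers[seq_len(min(length(centers), n_rings))]
  data.frame(z_center_mm = centers, width_um = design$strut_width_um,
             protrusion_um = protrusion_fraction * design$strut_thickness_um)
}

#' Axisymmetric finite-volume mesh
#'
#' Builds a uniform staggered (z, r) grid over a straight vessel segment with
#' scaffold strut rings as immersed rectangular solid obstacles attached to
#' the wall. The target cell edge is one fifth of the strut thickness times
#' `coarsening`; `coarsening = 1` reproduces the near-strut density used for
#' full-scale simulations, `coarsening >= 2` is the desk-scale default (a
#' message notes the relaxed density).
#'
#' @param length_mm Segment length (mm).
#' @param radius_mm Lumen radius (mm).
#' @param strut_thickness_um Strut thickness setting the edge target (um).
#' @param rings Optional data.frame from [scaffold_rings()] (`z_center_mm`,
#'   `width_um`, `protrusion_um`); NULL for a strut-free cylinder.
#' @param coarsening Edge-coarsening factor (>= 1).
#' @param max_cells Explicit cell budget; exceeding it is an error, never a
#'   silent coarsening.
#' @return Object of class `flow_mesh`: grid dimensions and spacings (SI),
#'   the solid mask, the ring table and achieved edge length.
#' @export
axisym_mesh <- function(length_mm, radius_mm, strut_thickness_um,
                        rings = NULL, coarsening = 2, max_cells = 2e6) {
  if (coarsening < 1) stop("coarsening must be >= 1", call. = FALSE)
  edge_um <- strut_thickness_um / 5 * coarsening
  if (coarsening > 1) {
    message(sprintf("mesh coarsening %g: near-strut edge %.1f um (full density %.1f um)",
                    coarsening, edge_um, strut_thickness_um / 5))
  }
  nr <- max(8L, as.integer(round(radius_mm * 1000 / edge_um)))
  nz <- max(10L, as.integer(round(length_mm * 1000 / edge_um)))
  if (as.double(nz) * nr > max_cells) {
    stop("mesh of ", nz, " x ", nr, " cells exceeds the cell budget (",
         max_cells, "); refusing rather than degrading resolution", call. = FALSE)
  }
  dz <- length_mm / 1000 / nz
  dr <- radius_mm / 1000 / nr
  z_cell <- (seq_len(nz) - 0.5) * dz
  r_cell <- (seq_len(nr) - 0.5) * dr
  solid <- matrix(FALSE, nz, nr)
  if (!is.null(rings) && nrow(rings)) {
    for (k in seq_len(nrow(rings))) {
      zi <- which(abs(z_cell - rings$z_center_mm[k] / 1000) <= rings$width_um[k] / 2 * 1e-6)
      if (!length(zi)) next
      rmin <- radius_mm / 1000 - rings$protrusion_um[k] * 1e-6
      solid[zi, r_cell > rmin] <- TRUE
    }
  }
  structure(list(nz = nz, nr = nr, dz = dz, dr = dr,
                 length_m = length_mm / 1000, radius_m = radius_mm / 1000,
                 z_cell_m = z_cell, r_cell_m = r_cell, solid = solid,
                 rings = rings, strut_thickness_um = strut_thickness_um,
                 coarsening = coarsening,
                 target_edge_um = edge_um,
                 achieved_edge_um = mean(c(dz, dr)) * 1e6,
                 inlet_offset_m = 0),
            class = "flow_mesh")
}

#' Volume mesh from a pipeline object
#'
#' `generate_mesh()` derives an axisymmetric [axisym_mesh()] from a mounted
#' [mount_contours()] surface (mean contour radius per axial station, flow
#' contour indentations included via the solid mask) or from a `pullback`
#' (wall radius from contours, strut rings from the strut annotations).
#'
#' @param x A `lumen_surface` or `pullback`.
#' @param coarsening Edge-coarsening factor.
#' @param ... Passed to [axisym_mesh()].
#' @return A `flow_mesh`.
#' @export
generate_mesh <- function(x, coarsening = 2, ...) UseMethod("generate_mesh")

#' @rdname generate_mesh
#' @export
generate_mesh.pullback <- function(x, coarsening = 2, ...) {
  frames <- x$frames
  wall_um <- tapply(x$contours$radius_um, x$contours$frame, mean)
  radius_mm <- mean(wall_um) / 1000
  length_mm <- max(frames$axial_um) / 1000
  rings <- NULL
  if (nrow(x$struts)) {
    st <- x$struts
    st$axial_um <- frames$axial_um[match(st$frame, frames$frame)]
    ring_of <- vapply(st$axial_um, function(z) {
      which.min(abs(z - x$ring_centers_um))
    }, integer(1))
    prot <- tapply(wall_um[as.character(st$frame)] - st$adluminal_radius_um,
                   ring_of, mean)
    rings <- data.frame(
      z_center_mm = x$ring_centers_um[as.integer(names(prot))] / 1000,
      width_um = x$design$strut_width_um,
      protrusion_um = as.numeric(prot))
  }
  axisym_mesh(length_mm, radius_mm, x$design$strut_thickness_um,
              rings = rings, coarsening = coarsening, ...)
}

#' @rdname generate_mesh
#' @param strut_thickness_um Strut thickness for the edge target (required
#'   for surfaces, which carry no design).
#' @export
generate_mesh.lumen_surface <- function(x, coarsening = 2,
                                        strut_thickness_um, ...) {
  if (!isTRUE(x$watertight)) {
    stop("lumen surface is not watertight between inlet and outlet rings",
         call. = FALSE)
  }
  # axisymmetrize each station conservatively by its minimum (adluminal)
  # radius: struts cover only part of the circumference, so a mean would
  # wash their indentation out of the ring-symmetric surrogate
  ax <- sort(unique(x$axial_um))
  rad_mm <- vapply(ax, function(a) {
    min(x$radius_mm[x$axial_um == a])
  }, numeric(1))
  radius_mm <- max(rad_mm)
  length_mm <- max(ax) / 1000
  m <- axisym_mesh(length_mm, radius_mm, strut_thickness_um, rings = NULL,
                   coarsening = coarsening, ...)
  # carve the wall profile (including strut indentations) into the mask
  prof <- stats::approx(ax * 1e-6, rad_mm / 1000, xout = m$z_cell_m, rule = 2)$y
  for (i in seq_len(m$nz)) m$solid[i, m$r_cell_m > prof[i]] <- TRUE
  m
}

#' Solve steady incompressible Newtonian flow
#'
#' Runs the axisymmetric SIMPLE finite-volume solver on a [axisym_mesh()]:
#' first-order upwind convection, no-slip walls and strut faces, prescribed
#' inlet profile, zero-gradient mass-conserving outlet at reference pressure
#' 0. Convergence requires the normalized momentum + continuity residual to
#' drop below `tol`; non-convergence is reported with the residual history,
#' never silently accepted.
#'
#' @param mesh A `flow_mesh`.
#' @param conditions A [flow_conditions()].
#' @param tol Residual tolerance.
#' @param max_iter Outer iteration cap.
#' @param relax_u,relax_p Velocity / pressure under-relaxation factors.
#' @param sweeps_uv,sweeps_p Inner Gauss-Seidel sweeps per outer iteration.
#' @param omega_p SOR factor of the pressure-correction sweeps.
#' @return Object of class `flow_solution`: velocity fields `u` (axial,
#'   (nz+1) x nr) and `v` (radial), pressure `p`, residuals, convergence
#'   flag, the mesh and conditions.
#' @export
solve_steady_flow <- function(mesh, conditions, tol = 1e-6, max_iter = 4000,
                              relax_u = 0.7, relax_p = 0.3,
                              sweeps_uv = 2, sweeps_p = 40, omega_p = 1.7) {
  stopifnot(inherits(mesh, "flow_mesh"), inherits(conditions, "flow_conditions"))
  vbar <- conditions$inlet_mean_velocity
  re <- conditions$density * vbar * 2 * mesh$radius_m / conditions$viscosity
  if (re > 2000) {
    stop("Reynolds number ", round(re), " outside laminar validity (> 2000)",
         call. = FALSE)
  }
  solid <- mesh$solid
  nz <- mesh$nz
  inlet_offset <- 0
  if (conditions$inlet_profile == "flat") {
    # prepend an entrance length of 10 diameters of strut-free tube
    n_ext <- as.integer(ceiling(10 * 2 * mesh$radius_m / mesh$dz))
    solid <- rbind(matrix(FALSE, n_ext, mesh$nr), solid)
    nz <- nz + n_ext
    inlet_offset <- n_ext * mesh$dz
  }
  r_cell <- (seq_len(mesh$nr) - 0.5) * mesh$dr
  u_in <- if (conditions$inlet_profile == "parabolic") {
    2 * vbar * (1 - (r_cell / mesh$radius_m)^2)
  } else {
    rep(vbar, mesh$nr)
  }
  fit <- simple_axisym_cpp(nz, mesh$nr, mesh$dz, mesh$dr, solid, u_in,
                           conditions$viscosity, conditions$density,
                           relax_u, relax_p, tol, max_iter,
                           sweeps_uv, sweeps_p, omega_p)
  if (!fit$converged) {
    warning(sprintf("flow solver did not converge in %d iterations (residual %.3g)",
                    fit$iterations, fit$residual), call. = FALSE)
  }
  structure(list(u = fit$u, v = fit$v,
                 p = fit$p + conditions$outlet_pressure,
                 converged = fit$converged, iterations = fit$iterations,
                 residual = fit$residual,
                 residual_history = fit$residual_history,
                 reynolds = re, mesh = mesh, conditions = conditions,
                 solid = solid, nz_total = nz,
                 inlet_offset_m = inlet_offset),
            class = "flow_solution")
}

#' @exportS3Method base::print
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d x %d cells, Re = %.0f, %s after %d iterations (residual %.2g)\n",
              x$nz_total, x$mesh$nr, x$reynolds,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

#' Wall shear stress extraction
#'
#' ESS on the lumen boundary is the product of blood viscosity and the
#' velocity gradient at the wall, evaluated one-sided into the fluid: for
#' each axial station the topmost fluid cell (below the wall or a strut
#' face) gives `tau = mu * u_centre / (dr/2)`. The magnitude is reported as
#' `wss_pa`; the signed near-wall axial velocity is kept for recirculation
#' diagnostics.
#'
#' @param solution A `flow_solution`.
#' @param conditions Optional override of the solution's conditions.
#' @return data.frame: `z_mm` (axial position, entrance length excluded),
#'   `axial_um`, `wss_pa`, `on_strut` (station under a strut ring),
#'   `u_near_wall_ms`, `wall_radius_mm`.
#' @export
compute_wss <- function(solution, conditions = solution$conditions) {
  mu <- conditions$viscosity
  mesh <- solution$mesh
  solid <- solution$solid
  nz <- solution$nz_total
  out <- vector("list", nz)
  for (i in seq_len(nz)) {
    fluid <- which(!solid[i, ])
    if (!length(fluid)) next
    jt <- max(fluid)
    uc <- 0.5 * (solution$u[i, jt] + solution$u[i + 1, jt])
    out[[i]] <- data.frame(
      z_m = (i - 0.5) * mesh$dz - solution$inlet_offset_m,
      wss_pa = mu * abs(uc) / (mesh$dr / 2),
      on_strut = jt < mesh$nr,
      u_near_wall_ms = uc,
      wall_radius_mm = jt * mesh$dr * 1000)
  }
  res <- do.call(rbind, out)
  res <- res[res$z_m >= 0, ]
  res$z_mm <- res$z_m * 1000
  res$axial_um <- res$z_m * 1e6
  rownames(res) <- NULL
  res[, c("z_mm", "axial_um", "wss_pa", "on_strut", "u_near_wall_ms",
          "wall_radius_mm")]
}

#' Cross-sectional volume flux profile
#'
#' Integrates the axial velocity over every cross-section (axial face) of
#' the solution; used for the mass-conservation invariant.
#'
#' @param solution A `flow_solution`.
#' @return data.frame with `z_mm` (face position) and `flux_mm3_s`, plus
#'   attribute `max_rel_error`: the largest relative deviation of any
#'   section flux from the inlet flux.
#' @export
flux_profile <- function(solution) {
  mesh <- solution$mesh
  solid <- solution$solid
  nz <- solution$nz_total
  r <- (seq_len(mesh$nr) - 0.5) * mesh$dr
  q <- numeric(nz + 1)
  for (i in seq_len(nz + 1)) {
    open <- if (i == 1) !solid[1, ] else if (i == nz + 1) !solid[nz, ] else
      !(solid[i - 1, ] | solid[i, ])
    q[i] <- sum(solution$u[i, open] * 2 * pi * r[open] * mesh$dr) * 1e9
  }
  out <- data.frame(z_mm = (seq_len(nz + 1) - 1) * mesh$dz * 1000 -
                      solution$inlet_offset_m * 1000,
                    flux_mm3_s = q)
  attr(out, "max_rel_error") <- max(abs(q - q[1])) / abs(q[1])
  out
}
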