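# shared fixture builders; everything is generated in code

circle_contour <- function(radius_um, n = 360) {
  data.frame(angle_deg = seq(0, 360 - 360 / n, length.out = n),
             radius_um = radius_um)
}

strut_row <- function(center_deg, span_deg, adluminal_um,
                      abluminal_um = adluminal_um + 157, frame = 0L) {
  data.frame(frame = frame, angle_center_deg = center_deg,
             angular_span_deg = span_deg, adluminal_radius_um = adluminal_um,
             abluminal_radius_um = abluminal_um)
}

# short strut-free cylinder solve shared by several flow tests
poiseuille_solution <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- suppressMessages(axisym_mesh(8, 1.5, 157, rings = NULL,
                                        coarsening = 2))
      cache <<- solve_steady_flow(m, flow_conditions(0.15), max_iter = 3000)
    }
    cache
  }
})
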