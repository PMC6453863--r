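#' Scaffold design presets
#'
#' Construct a `scaffold_design` object describing the strut geometry of a
#' bioresorbable scaffold family. Two presets mirror the quadratic-strut
#' devices compared throughout this package: an Absorb-like design
#' (157 um thick, 176 um wide struts, 1.0 mm maximum inter-strut distance,
#' 27% vessel coverage) and an ArterioSorb-like design (95 um thick, 170 um
#' wide, 1.4 mm inter-strut distance, 29% coverage). `preset = "custom"`
#' requires all geometric parameters explicitly.
#'
#' The inter-strut distance is the clear axial gap between the edges of
#' consecutive strut rings: the lumen wall exposed to flow between struts.
#'
#' @param preset One of `"absorb_like"`, `"arteriosorb_like"`, `"custom"`.
#' @param strut_thickness_um Radial strut thickness in micron (custom only).
#' @param strut_width_um Axial strut width in micron (custom only).
#' @param inter_strut_distance_mm Maximum clear inter-strut distance in mm
#'   (custom only).
#' @param n_rings Number of strut rings along the scaffold.
#' @param struts_per_ring Struts visible per cross-section.
#' @param coverage_ratio Fraction of the vessel surface covered by struts.
#' @param name Label for the design; defaults to the preset name.
#' @return An object of class `scaffold_design`: a list with fields `name`,
#'   `strut_thickness_um`, `strut_width_um`, `inter_strut_distance_mm`,
#'   `n_rings`, `struts_per_ring`, `coverage_ratio`.
#' @examples
#' scaffold_design("absorb_like")
#' scaffold_design("arteriosorb_like")$strut_thickness_um
#' @export
scaffold_design <- function(preset = c("absorb_like", "arteriosorb_like", "custom"),
                            strut_thickness_um = NULL,
                            strut_width_um = NULL,
                            inter_strut_distance_mm = NULL,
                            n_rings = NULL,
                            struts_per_ring = 8L,
                            coverage_ratio = NULL,
                            name = NULL) {
  preset <- match.arg(preset)
  if (preset == "absorb_like") {
    d <- list(name = name %||% "absorb_like",
              strut_thickness_um = 157, strut_width_um = 176,
              inter_strut_distance_mm = 1.0,
              n_rings = n_rings %||% 12L, struts_per_ring = struts_per_ring,
              coverage_ratio = 0.27)
  } else if (preset == "arteriosorb_like") {
    d <- list(name = name %||% "arteriosorb_like",
              strut_thickness_um = 95, strut_width_um = 170,
              inter_strut_distance_mm = 1.4,
              n_rings = n_rings %||% 9L, struts_per_ring = struts_per_ring,
              coverage_ratio = 0.29)
  } else {
    if (is.null(strut_thickness_um) || is.null(strut_width_um) ||
        is.null(inter_strut_distance_mm) || is.null(coverage_ratio)) {
      stop("custom design requires strut_thickness_um, strut_width_um, ",
           "inter_strut_distance_mm and coverage_ratio", call. = FALSE)
    }
    d <- list(name = name %||% "custom",
              strut_thickness_um = strut_thickness_um,
              strut_width_um = strut_width_um,
              inter_strut_distance_mm = inter_strut_distance_mm,
              n_rings = n_rings %||% 10L, struts_per_ring = struts_per_ring,
              coverage_ratio = coverage_ratio)
  }
  validate_scaffold_design(structure(d, class = "scaffold_design"))
}

validate_scaffold_design <- function(d) {
  stopifnot(inherits(d, "scaffold_design"))
  if (d$strut_thickness_um <= 0) stop("strut_thickness_um must be > 0", call. = FALSE)
  if (d$strut_width_um <= 0) stop("strut_width_um must be > 0", call. = FALSE)
  if (d$inter_strut_distance_mm * 1000 <= d$strut_width_um) {
    stop("inter-strut distance (", d$inter_strut_distance_mm * 1000,
         " um) must exceed the strut width (", d$strut_width_um, " um)",
         call. = FALSE)
  }
  if (d$coverage_ratio <= 0 || d$coverage_ratio >= 1) {
    stop("coverage_ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  if (d$n_rings < 1 || d$struts_per_ring < 1) {
    stop("n_rings and struts_per_ring must be >= 1", call. = FALSE)
  }
  d
}

#' @exportS3Method base::print
print.scaffold_design <- function(x, ...) {
  cat(sprintf("<scaffold_design> %s\n", x$name))
  cat(sprintf("  strut: %g um thick x %g um wide, %d struts/ring, %d rings\n",
              x$strut_thickness_um, x$strut_width_um,
              x$struts_per_ring, x$n_rings))
  cat(sprintf("  inter-strut distance: %g mm; coverage ratio: %g\n",
              x$inter_strut_distance_mm, x$coverage_ratio))
  invisible(x)
}

#' Inter-strut flow-recovery design rule
#'
#' Checks the rule of thumb that the inter-strut distance should be at least
#' six times the strut thickness so that laminar flow (and hence wall shear
#' stress) can recover between consecutive strut rings.
#'
#' @param design A [scaffold_design()].
#' @return List with `pass` (logical) and `margin_um`, the inter-strut
#'   distance minus six strut thicknesses in micron (negative on failure).
#' @examples
#' interstrut_recovery_check(scaffold_design("absorb_like"))
#' @export
interstrut_recovery_check <- function(design) {
  stopifnot(inherits(design, "scaffold_design"))
  spacing_um <- design$inter_strut_distance_mm * 1000
  required_um <- 6 * design$strut_thickness_um
  list(pass = spacing_um >= required_um, margin_um = spacing_um - required_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
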