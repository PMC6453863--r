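#' Hierarchical ESS data generator
#'
#' `hierarchy_spec()` parameterizes a generative twin of the three-level
#' structure of an in-vivo scaffold study: animals carry scaffolds, scaffolds
#' carry cross-sections, and each cross-section is read out in 72 sectors of
#' 5 degrees. `simulate_hierarchical_ess()` draws sector-level ESS values
#'
#' \deqn{ess = \mu + \delta \cdot [type = thin] + a_{animal} + s_{scaffold} +
#'   c_{cross-section} + \epsilon_{sector}}
#'
#' with independent Gaussian random intercepts at each level, so that
#' mixed-model fitting can be validated by parameter recovery against known
#' truth.
#'
#' The default layout mirrors a 9-animal study with 12 scaffolds: six animals
#' carry one thick-strut (absorb-like) scaffold each and three animals carry
#' two thin-strut (arteriosorb-like) scaffolds each, so scaffold type varies
#' between animals. The default grand mean (0.73 Pa) and type effect
#' (0.79 Pa) reproduce in-scaffold mean ESS of 0.73 Pa (thick) and 1.52 Pa
#' (thin) in expectation.
#'
#' @param n_animals Number of animals.
#' @param scaffolds_per_animal Scalar or length-`n_animals` vector.
#' @param cross_sections_per_scaffold Cross-sections per scaffold.
#' @param sectors_per_cross_section Sectors per cross-section (72 = 5 degree).
#' @param sd_animal,sd_scaffold,sd_cross_section,sd_sector Random-effect and
#'   residual standard deviations (Pa).
#' @param fixed_effect_delta Scaffold-type effect (Pa), added for the
#'   thin-strut (`arteriosorb_like`) type.
#' @param grand_mean Intercept (Pa) for the thick-strut type.
#' @param csa_mean,csa_sd Cross-sectional-area distribution (mm^2).
#' @param csa_effect Fixed CSA slope (Pa per mm^2), default 0.
#' @param types Optional explicit scaffold-type vector (one per scaffold);
#'   by default animals with a single scaffold get `absorb_like` and animals
#'   with several get `arteriosorb_like`.
#' @param seed Integer seed.
#' @return `hierarchy_spec` object / long-format data.frame of class
#'   `ess_records` with columns `animal_id`, `scaffold_id`,
#'   `cross_section_id`, `sector_id`, `scaffold_type`,
#'   `cross_sectional_area`, `ess`, carrying the ground-truth parameters in
#'   `attr(, "truth")`.
#' @export
hierarchy_spec <- function(n_animals = 9, scaffolds_per_animal = c(1, 1, 1, 1, 1, 1, 2, 2, 2),
                           cross_sections_per_scaffold = 8,
                           sectors_per_cross_section = 72,
                           sd_animal = 0.2, sd_scaffold = 0.1,
                           sd_cross_section = 0.1, sd_sector = 0.5,
                           fixed_effect_delta = 0.79, grand_mean = 0.73,
                           csa_mean = 7.5, csa_sd = 1, csa_effect = 0,
                           types = NULL, seed = 1L) {
  if (length(scaffolds_per_animal) == 1) {
    scaffolds_per_animal <- rep(scaffolds_per_animal, n_animals)
  }
  stopifnot(length(scaffolds_per_animal) == n_animals)
  if (any(c(sd_animal, sd_scaffold, sd_cross_section, sd_sector) < 0)) {
    stop("random-effect standard deviations must be >= 0", call. = FALSE)
  }
  if (n_animals < 1 || any(scaffolds_per_animal < 1) ||
      cross_sections_per_scaffold < 1 || sectors_per_cross_section < 1) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  structure(list(n_animals = n_animals,
                 scaffolds_per_animal = scaffolds_per_animal,
                 cross_sections_per_scaffold = cross_sections_per_scaffold,
                 sectors_per_cross_section = sectors_per_cross_section,
                 sd_animal = sd_animal, sd_scaffold = sd_scaffold,
                 sd_cross_section = sd_cross_section, sd_sector = sd_sector,
                 fixed_effect_delta = fixed_effect_delta,
                 grand_mean = grand_mean, csa_mean = csa_mean, csa_sd = csa_sd,
                 csa_effect = csa_effect, types = types,
                 seed = as.integer(seed)),
            class = "hierarchy_spec")
}

#' @rdname hierarchy_spec
#' @param spec A `hierarchy_spec`.
#' @export
simulate_hierarchical_ess <- function(spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  set.seed(spec$seed)
  n_scaffolds <- sum(spec$scaffolds_per_animal)
  animal_of_scaffold <- rep(seq_len(spec$n_animals), spec$scaffolds_per_animal)
  types <- spec$types %||%
    ifelse(spec$scaffolds_per_animal[animal_of_scaffold] == 1,
           "absorb_like", "arteriosorb_like")
  stopifnot(length(types) == n_scaffolds)

  a_eff <- stats::rnorm(spec$n_animals, 0, spec$sd_animal)
  s_eff <- stats::rnorm(n_scaffolds, 0, spec$sd_scaffold)

  recs <- vector("list", n_scaffolds)
  for (j in seq_len(n_scaffolds)) {
    ncs <- spec$cross_sections_per_scaffold
    nsec <- spec$sectors_per_cross_section
    csa <- stats::rnorm(ncs, spec$csa_mean, spec$csa_sd)
    c_eff <- stats::rnorm(ncs, 0, spec$sd_cross_section)
    mu <- spec$grand_mean +
      spec$fixed_effect_delta * (types[j] == "arteriosorb_like") +
      spec$csa_effect * csa + a_eff[animal_of_scaffold[j]] + s_eff[j] + c_eff
    eps <- stats::rnorm(ncs * nsec, 0, spec$sd_sector)
    recs[[j]] <- data.frame(
      animal_id = sprintf("A%02d", animal_of_scaffold[j]),
      scaffold_id = sprintf("S%02d", j),
      cross_section_id = rep(sprintf("S%02d.C%03d", j, seq_len(ncs)), each = nsec),
      sector_id = rep(seq_len(nsec), ncs),
      scaffold_type = types[j],
      cross_sectional_area = rep(csa, each = nsec),
      ess = rep(mu, each = nsec) + eps)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "truth") <- list(grand_mean = spec$grand_mean,
                             fixed_effect_delta = spec$fixed_effect_delta,
                             csa_effect = spec$csa_effect,
                             sd_animal = spec$sd_animal,
                             sd_scaffold = spec$sd_scaffold,
                             sd_cross_section = spec$sd_cross_section,
                             sd_sector = spec$sd_sector,
                             animal_effects = a_eff, scaffold_effects = s_eff)
  class(out) <- c("ess_records", "data.frame")
  out
}
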