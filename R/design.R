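#' Measurement design specification
#'
#' Describes the fully crossed measurement design: every individual of every
#' population of every species is measured by every measurer in every repeat
#' round.  The defaults reproduce the reference design of 3 species x 3
#' sampling sites x 30 individuals x 3 measurers x 3 repeats, which yields
#' 2430 records per method and hence 26,730 stored values for an 11-landmark
#' method, 17,010 for a 7-landmark method and 38,880 for a 16-variable
#' distance method.
#'
#' @param n_species number of species.
#' @param n_populations number of populations (sampling sites) per species.
#' @param n_individuals number of individuals per population.
#' @param n_measurers number of measurers.
#' @param n_repeats number of repeated measurement rounds per measurer.
#' @param n_landmarks_body landmarks digitized on the body image (default 11).
#' @param n_landmarks_scale landmarks digitized on the scale image (default 7).
#' @param n_distance_vars linear measurements per specimen for distance-based
#'   methods (default 16).
#' @param seed master seed for data generation.
#' @return an object of class `"design_spec"`.
#' @seealso [effect_spec()], [generate_landmarks()], [generate_distances()]
#' @export
#' @examples
#' d <- design_spec()
#' n_records(d)        # 2430
#' n_records(d) * d$n_landmarks_body  # 26730 stored landmark values
design_spec <- function(n_species = 3, n_populations = 3, n_individuals = 30,
                        n_measurers = 3, n_repeats = 3,
                        n_landmarks_body = 11, n_landmarks_scale = 7,
                        n_distance_vars = 16, seed = 1L) {
  counts <- c(n_species = n_species, n_populations = n_populations,
              n_individuals = n_individuals, n_measurers = n_measurers,
              n_repeats = n_repeats, n_landmarks_body = n_landmarks_body,
              n_landmarks_scale = n_landmarks_scale,
              n_distance_vars = n_distance_vars)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("invalid design: all counts must be integers >= 1 (got ",
         paste(names(counts)[counts < 1 | counts != round(counts)], collapse = ", "),
         ")", call. = FALSE)
  structure(c(as.list(counts), list(seed = as.integer(seed))),
            class = "design_spec")
}

#' Number of records implied by a design
#'
#' One record is one configuration or one measurement row: the product of
#' species, populations, individuals, measurers and repeats.
#'
#' @param design a [design_spec()].
#' @return integer record count.
#' @export
n_records <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  with(design, n_species * n_populations * n_individuals *
         n_measurers * n_repeats)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Crossed measurement design:",
      sprintf("%d species x %d sites x %d individuals x %d measurers x %d repeats",
              x$n_species, x$n_populations, x$n_individuals,
              x$n_measurers, x$n_repeats), "\n")
  cat(sprintf("  records per method: %d\n", n_records(x)))
  cat(sprintf("  landmarks: body %d, scale %d; distance variables: %d; seed %d\n",
              x$n_landmarks_body, x$n_landmarks_scale, x$n_distance_vars,
              x$seed))
  invisible(x)
}

#' Effect-size specification for the synthetic generator
#'
#' Magnitudes of the biological and observational effects that the generator
#' superimposes on the species templates.  Landmark effects are in shape
#' units, i.e. displacements of unit-centroid-size configurations; distance
#' effects are coefficients of variation on the log scale (a value of 0.02
#' means roughly 2% multiplicative noise).  Bias terms are drawn once per
#' measurer and held fixed across all of that measurer's records; repeat
#' noise is drawn independently for every record.
#'
#' The scale-image method inherits the landmark magnitudes inflated by
#' `scale_noise_inflation`/`scale_bias_inflation` (scale margins are harder to
#' place than body landmarks), and the caliper method inherits the distance
#' magnitudes inflated by `caliper_noise_inflation`/`caliper_bias_inflation`
#' (the fish is re-handled and re-positioned at every caliper measurement).
#' The resulting default method-error ordering is
#' caliper >> truss ~ scale landmarks >> body landmarks.
#'
#' @param population_shift mean-shape displacement per population, shape
#'   units.
#' @param individual_sd per-coordinate SD of individual shape variation,
#'   shape units.
#' @param measurer_bias per-coordinate SD of the fixed per-measurer landmark
#'   offset, shape units.  The measurer effect has two parts, both scaled by
#'   this knob: a systematic offset shared by all of a measurer's records
#'   (visible as centroid "ghosting" in ordinations) and a
#'   measurer-by-individual interpretation component of SD
#'   `measurer_bias * bias_interaction` — each measurer reads each image in
#'   their own consistent way — which is what separates reproducibility from
#'   repeatability, since a purely constant offset cancels in within-dataset
#'   distance matrices.  `measurer_bias = 0` switches both parts off.
#' @param bias_interaction ratio of the measurer-by-individual SD to the
#'   systematic offset SD (applies to landmark and distance methods alike).
#' @param repeat_noise per-coordinate SD of per-record digitization noise,
#'   shape units.
#' @param scale_noise_inflation,scale_bias_inflation multipliers applied to
#'   `repeat_noise`/`measurer_bias` for the scale-landmark method.
#' @param population_cv,individual_cv,measurer_cv,repeat_cv log-scale effect
#'   magnitudes for distance variables (population shift, individual
#'   variation, fixed measurer bias, per-record noise).
#' @param caliper_noise_inflation,caliper_bias_inflation multipliers applied
#'   to `repeat_cv`/`measurer_cv` in caliper mode (must be >= 0; defaults > 1).
#' @param allometry_b power-law exponent relating linear measurements to
#'   standard length (1 = isometry).
#' @param sl_range numeric length-2, min and max standard length in mm;
#'   individual SL is drawn log-uniformly within it.
#' @return an object of class `"effect_spec"`.
#' @export
#' @examples
#' effect_spec()                       # study-condition defaults
#' effect_spec(repeat_noise = 0)       # noise-free digitization
effect_spec <- function(population_shift = 0.035,
                        individual_sd = 0.010,
                        measurer_bias = 0.004,
                        repeat_noise = 0.004,
                        bias_interaction = 0.5,
                        scale_noise_inflation = 1.4,
                        scale_bias_inflation = 3,
                        population_cv = 0.02,
                        individual_cv = 0.05,
                        measurer_cv = 0.02,
                        repeat_cv = 0.035,
                        caliper_noise_inflation = 2,
                        caliper_bias_inflation = 6,
                        allometry_b = 1.1,
                        sl_range = c(60, 135)) {
  nn <- c(population_shift = population_shift, individual_sd = individual_sd,
          measurer_bias = measurer_bias, repeat_noise = repeat_noise,
          bias_interaction = bias_interaction,
          scale_noise_inflation = scale_noise_inflation,
          scale_bias_inflation = scale_bias_inflation,
          population_cv = population_cv, individual_cv = individual_cv,
          measurer_cv = measurer_cv, repeat_cv = repeat_cv,
          caliper_noise_inflation = caliper_noise_inflation,
          caliper_bias_inflation = caliper_bias_inflation)
  if (any(!is.finite(nn)) || any(nn < 0))
    stop("effect magnitudes and inflation factors must be finite and >= 0",
         call. = FALSE)
  if (length(sl_range) != 2 || any(sl_range <= 0) || sl_range[1] >= sl_range[2])
    stop("sl_range must be positive with min < max", call. = FALSE)
  if (!is.finite(allometry_b)) stop("allometry_b must be finite", call. = FALSE)
  structure(c(as.list(nn), list(allometry_b = allometry_b,
                                sl_range = as.numeric(sl_range))),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Synthetic effect magnitudes\n")
  cat(sprintf("  shape units: population shift %.3g, individual %.3g, measurer bias %.3g, repeat noise %.3g\n",
              x$population_shift, x$individual_sd, x$measurer_bias,
              x$repeat_noise))
  cat(sprintf("  scale-method inflation: noise x%.3g, bias x%.3g\n",
              x$scale_noise_inflation, x$scale_bias_inflation))
  cat(sprintf("  distance CVs: population %.3g, individual %.3g, measurer %.3g, repeat %.3g\n",
              x$population_cv, x$individual_cv, x$measurer_cv, x$repeat_cv))
  cat(sprintf("  caliper inflation: noise x%.3g, bias x%.3g\n",
              x$caliper_noise_inflation, x$caliper_bias_inflation))
  cat(sprintf("  allometry exponent b = %.3g; SL range %.1f-%.1f mm\n",
              x$allometry_b, x$sl_range[1], x$sl_range[2]))
  invisible(x)
}
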