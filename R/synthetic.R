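#' Generate a synthetic landmark dataset under the crossed design
#'
#' Emulates repeated landmark digitization of the same specimens by several
#' measurers.  Each individual has a fixed true shape: the species template,
#' displaced along a population-specific direction in shape space
#' (`population_shift`), plus isotropic individual variation
#' (`individual_sd`).  Each measurer adds a fixed offset vector drawn once
#' (`measurer_bias`) plus a per-individual interpretation vector fixed
#' across that measurer's repeats (see [effect_spec()]); each record adds
#' independent digitization noise (`repeat_noise`).  Coordinates are then scaled by the individual's
#' standard length (drawn log-uniformly within `sl_range`) and placed in the
#' image with an individual-specific rotation and translation — one photograph
#' per fish, digitized by every measurer in every repeat — so records of one
#' individual are bit-identical when noise and bias are zero.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @param template `"body"` (default, `n_landmarks_body` landmarks) or
#'   `"scale"` (`n_landmarks_scale` landmarks; repeat noise and measurer bias
#'   are inflated by the scale inflation factors of `effects`).
#' @param characteristic logical, recycled to `n_species`: species whose
#'   scales have a characteristic (high-curvature) shape.  Their template is
#'   the high-curvature variant and their landmarks are better defined, so
#'   the scale noise inflation is halved (never below 1).  Ignored for the
#'   body template.
#' @return a [landmark_dataset()] with `n_records(design)` configurations.
#' @seealso [generate_distances()]
#' @export
#' @examples
#' d <- design_spec(n_species = 1, n_individuals = 5)
#' x <- generate_landmarks(d, effect_spec())
#' nrow(x)  # 1 * 3 * 5 * 3 * 3 = 135
generate_landmarks <- function(design, effects,
                               template = c("body", "scale"),
                               characteristic = FALSE) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  template <- match.arg(template)
  k <- if (template == "body") design$n_landmarks_body else
    design$n_landmarks_scale
  S <- design$n_species; P <- design$n_populations
  I <- design$n_individuals; M <- design$n_measurers; Rp <- design$n_repeats
  characteristic <- rep_len(as.logical(characteristic), S)

  bias_sd <- effects$measurer_bias *
    (if (template == "scale") effects$scale_bias_inflation else 1)
  noise_base <- effects$repeat_noise
  noise_sd_species <- vapply(seq_len(S), function(s) {
    if (template == "scale") {
      infl <- effects$scale_noise_inflation * (if (characteristic[s]) 0.5 else 1)
      noise_base * max(infl, 1)
    } else noise_base
  }, numeric(1))

  with_seed(stage_seed(design$seed, paste0("landmarks/", template)), {
    # species templates: base configuration plus a species-level deformation
    templates <- lapply(seq_len(S), function(s) {
      base <- if (template == "body") body_template(k) else
        scale_template(k, characteristic = characteristic[s])
      base + matrix(stats::rnorm(2 * k, sd = 3 * effects$population_shift),
                    k, 2)
    })
    # population displacement directions: orthonormal in the 2K shape space
    popdirs <- lapply(seq_len(S), function(s) {
      q <- qr.Q(qr(matrix(stats::rnorm(2 * k * P), 2 * k, P)))
      lapply(seq_len(P), function(p) matrix(q[, p], k, 2))
    })

    nind <- S * P * I
    true_shape <- vector("list", nind)
    sl <- numeric(nind); theta <- numeric(nind)
    trans <- matrix(0, nind, 2)
    idx <- 0L
    lr <- log(effects$sl_range)
    for (s in seq_len(S)) for (p in seq_len(P)) for (i in seq_len(I)) {
      idx <- idx + 1L
      mu <- templates[[s]] + effects$population_shift * popdirs[[s]][[p]]
      true_shape[[idx]] <- mu + matrix(stats::rnorm(2 * k,
                                                    sd = effects$individual_sd),
                                       k, 2)
      sl[idx] <- exp(stats::runif(1, lr[1], lr[2]))
      theta[idx] <- stats::runif(1, -pi / 18, pi / 18)
      trans[idx, ] <- stats::runif(2, 10, 60)
    }
    bias <- lapply(seq_len(M), function(m)
      matrix(stats::rnorm(2 * k, sd = bias_sd), k, 2))
    # measurer-by-individual interpretation: fixed across that measurer's
    # repeats, zero whenever measurer_bias is zero
    inter_sd <- bias_sd * effects$bias_interaction
    inter <- lapply(seq_len(nind), function(i)
      lapply(seq_len(M), function(m)
        if (inter_sd > 0) matrix(stats::rnorm(2 * k, sd = inter_sd), k, 2)
        else matrix(0, k, 2)))

    n <- nind * M * Rp
    coords <- matrix(0, n, 2 * k)
    labels <- data.frame(species = character(n), site = character(n),
                         individual = character(n), measurer = character(n),
                         "repeat" = integer(n), check.names = FALSE,
                         stringsAsFactors = FALSE)
    row <- 0L; idx <- 0L
    for (s in seq_len(S)) for (p in seq_len(P)) for (i in seq_len(I)) {
      idx <- idx + 1L
      rot <- matrix(c(cos(theta[idx]), sin(theta[idx]),
                      -sin(theta[idx]), cos(theta[idx])), 2, 2)
      for (m in seq_len(M)) for (r in seq_len(Rp)) {
        row <- row + 1L
        eps <- if (noise_sd_species[s] > 0)
          matrix(stats::rnorm(2 * k, sd = noise_sd_species[s]), k, 2)
        else matrix(0, k, 2)
        shape <- true_shape[[idx]] + bias[[m]] + inter[[idx]][[m]] + eps
        y <- sl[idx] * (shape %*% t(rot))
        y <- sweep(y, 2, trans[idx, ], "+")
        coords[row, ] <- as.vector(t(y))  # x1,y1,x2,y2,...
        labels$species[row] <- sprintf("sp%d", s)
        labels$site[row] <- sprintf("site%d", p)
        labels$individual[row] <- sprintf("ind%02d", i)
        labels$measurer[row] <- sprintf("M%d", m)
        labels[["repeat"]][row] <- r
      }
    }
    nm <- if (template == "body" && k == 11) .body_landmark_names
          else if (template == "scale" && k == 7) .scale_landmark_names
          else paste0("lm", seq_len(k))
    landmark_dataset(labels, coords, landmark_names = nm, template = template)
  })
}

#' Generate a synthetic linear-distance dataset under the crossed design
#'
#' Emulates truss-network or caliper measurement of the same specimens.  Each
#' variable `v` has a base proportion `a_v` of body size and scales with
#' standard length as `a_v * SL^b` (`b = allometry_b`; `b = 0` makes
#' variables independent of SL).  Population, individual, measurer and repeat
#' effects act multiplicatively (log-normal with the CVs of `effects`);
#' measurer bias is drawn once per (measurer, variable), the
#' measurer-by-individual interpretation once per (measurer, individual,
#' variable), and repeat noise independently per record.  In `"caliper"` mode the fish is re-positioned at
#' every measurement, so repeat noise and measurer bias are inflated by the
#' caliper inflation factors; with both inflation factors at 1 the two modes
#' are statistically identical.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @param mode `"truss"` (image-based distances) or `"caliper"`.
#' @return a [distance_dataset()] with `n_records(design)` records,
#'   `n_distance_vars` measurement columns and an `SL` column.
#' @export
#' @examples
#' d <- design_spec(n_species = 1, n_individuals = 5)
#' x <- generate_distances(d, effect_spec(), mode = "truss")
#' n_measurements(x)  # 135 * 16
generate_distances <- function(design, effects, mode = c("truss", "caliper")) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  mode <- match.arg(mode)
  S <- design$n_species; P <- design$n_populations
  I <- design$n_individuals; M <- design$n_measurers; Rp <- design$n_repeats
  V <- design$n_distance_vars
  noise_cv <- effects$repeat_cv *
    (if (mode == "caliper") effects$caliper_noise_inflation else 1)
  bias_cv <- effects$measurer_cv *
    (if (mode == "caliper") effects$caliper_bias_inflation else 1)
  b <- effects$allometry_b

  with_seed(stage_seed(design$seed, paste0("distances/", mode)), {
    a <- stats::runif(V, 0.08, 0.9)            # base proportion of SL
    delta <- array(stats::rnorm(S * P * V, sd = effects$population_cv),
                   c(S, P, V))                 # population shift per variable
    nind <- S * P * I
    gamma <- matrix(stats::rnorm(nind * V, sd = effects$individual_cv),
                    nind, V)                   # individual true proportions
    lr <- log(effects$sl_range)
    sl <- exp(stats::runif(nind, lr[1], lr[2]))
    beta <- matrix(stats::rnorm(M * V, sd = bias_cv), M, V)
    # image-reading idiosyncrasy persists across repeats of image-based
    # measurement; re-handling the specimen (caliper mode) washes it out in
    # proportion to the extra per-record noise, so the two modes coincide
    # when the caliper inflation factors are 1
    inter_cv <- effects$measurer_cv * effects$bias_interaction /
      (if (mode == "caliper") max(effects$caliper_noise_inflation, 1) else 1)
    beta_im <- if (inter_cv > 0)
      array(stats::rnorm(nind * M * V, sd = inter_cv), c(nind, M, V))
    else array(0, c(nind, M, V))

    n <- nind * M * Rp
    vals <- matrix(0, n, V)
    SL <- numeric(n)
    labels <- data.frame(species = character(n), site = character(n),
                         individual = character(n), measurer = character(n),
                         "repeat" = integer(n), check.names = FALSE,
                         stringsAsFactors = FALSE)
    row <- 0L; idx <- 0L
    for (s in seq_len(S)) for (p in seq_len(P)) for (i in seq_len(I)) {
      idx <- idx + 1L
      base <- a * sl[idx]^b * exp(delta[s, p, ] + gamma[idx, ])
      for (m in seq_len(M)) for (r in seq_len(Rp)) {
        row <- row + 1L
        eps <- if (noise_cv > 0) stats::rnorm(V, sd = noise_cv) else
          numeric(V)
        vals[row, ] <- base * exp(beta[m, ] + beta_im[idx, m, ] + eps)
        SL[row] <- sl[idx]
        labels$species[row] <- sprintf("sp%d", s)
        labels$site[row] <- sprintf("site%d", p)
        labels$individual[row] <- sprintf("ind%02d", i)
        labels$measurer[row] <- sprintf("M%d", m)
        labels[["repeat"]][row] <- r
      }
    }
    distance_dataset(labels, SL, vals, mode = mode)
  })
}
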