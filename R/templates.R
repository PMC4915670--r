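# Mean-shape templates used as the base configurations of the generator.
# Coordinates are nominal image units; generator output is centred and
# scaled internally, so only the relative geometry matters.

.body_landmark_names <- c(
  "tip_of_snout", "occiput", "dorsal_fin_base", "upper_caudal_base",
  "lower_caudal_base", "anal_fin_base", "pelvic_fin_base",
  "pectoral_fin_base", "lower_head", "opercle_posterior", "eye_centre")

.scale_landmark_names <- c(
  "left_cranial_edge", "cranial_end", "right_cranial_edge",
  "left_caudal_edge", "focus", "right_caudal_edge", "caudal_peak")

#' Landmark templates for the synthetic generator
#'
#' `body_template()` is a stylized lateral fish outline carrying the 11
#' standard body landmarks (snout tip, occiput, fin bases, caudal bases,
#' opercle, eye).  `scale_template()` is a cycloid-scale polygon carrying the
#' 7 standard scale landmarks (cranial edges and apex, caudal edges and peak,
#' focus); `characteristic = TRUE` returns a higher-curvature variant with a
#' pronounced caudal peak, emulating species whose scales have a distinctive
#' shape.  For landmark counts other than the canonical 11/7 an elliptic
#' polygon with matching point count is returned so non-default designs stay
#' usable.
#'
#' @param k number of landmarks.
#' @param characteristic logical; use the high-curvature scale variant.
#' @return a `k x 2` matrix, centred with unit centroid size; row names are
#'   landmark names.
#' @export
body_template <- function(k = 11) {
  if (k == 11) {
    m <- matrix(c(
      0.00,  0.00,   # tip of snout
      0.25,  0.12,   # occiput
      0.45,  0.16,   # base of dorsal fin
      0.88,  0.06,   # upper base of caudal fin
      0.88, -0.05,   # lower base of caudal fin
      0.62, -0.12,   # base of anal fin
      0.40, -0.14,   # base of pelvic fin
      0.20, -0.10,   # base of pectoral fin
      0.08, -0.08,   # lower part of head
      0.22,  0.00,   # posterior point of opercle
      0.08,  0.04),  # middle point of eye
      ncol = 2, byrow = TRUE,
      dimnames = list(.body_landmark_names, c("x", "y")))
  } else {
    m <- .ellipse_template(k, aspect = 0.35)
  }
  .normalize_template(m)
}

#' @rdname body_template
#' @export
scale_template <- function(k = 7, characteristic = FALSE) {
  if (k == 7) {
    m <- matrix(c(
      -0.50,  0.35,  # left cranial edge
       0.00,  0.55,  # cranial end
       0.50,  0.35,  # right cranial edge
      -0.45, -0.25,  # left caudal edge
       0.00,  0.10,  # focus
       0.45, -0.25,  # right caudal edge
       0.00, -0.55), # caudal peak
      ncol = 2, byrow = TRUE,
      dimnames = list(.scale_landmark_names, c("x", "y")))
    if (characteristic) {
      # deeper caudal field and flared cranial corners
      m[7, 2] <- -0.85
      m[c(1, 3), 2] <- 0.45
      m[5, 2] <- -0.05
    }
  } else {
    m <- .ellipse_template(k, aspect = 0.9)
  }
  .normalize_template(m)
}

.ellipse_template <- function(k, aspect) {
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  m <- cbind(x = cos(th), y = aspect * sin(th))
  rownames(m) <- paste0("lm", seq_len(k))
  m
}

# centre and scale to unit centroid size
.normalize_template <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / centroid_size(m)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid.
#'
#' @param m a `k x 2` coordinate matrix.
#' @return positive scalar (zero only for fully coincident landmarks).
#' @export
centroid_size <- function(m) {
  m <- as.matrix(m)
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}
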