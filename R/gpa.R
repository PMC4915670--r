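#' Generalized Procrustes superimposition with tangent projection
#'
#' Removes position, scale and orientation from a set of landmark
#' configurations: each configuration is centred, scaled to unit centroid
#' size, and iteratively rotated onto the current consensus by orthogonal
#' least squares until the consensus stabilizes; the aligned shapes are then
#' projected orthogonally onto the tangent plane at the consensus so that
#' subsequent linear statistics are valid.  Reflections are disallowed by
#' default (all specimens are digitized from the same side; allowing
#' reflections would silently absorb digitization inversions).
#'
#' Centroid size is computed on the raw input coordinates before any
#' scaling; its natural logarithm (`logCS`) is the size covariate used by
#' [regress_out_size()].
#'
#' @param data a [landmark_dataset()] with at least 2 specimens and 3
#'   landmarks.
#' @param allow_reflection logical; permit improper rotations.
#' @param tol convergence tolerance on the Frobenius change of the consensus
#'   between iterations.
#' @param max_iter maximum number of alignment sweeps.
#' @return an object of class `"procrustes_fit"` with components
#'   \describe{
#'     \item{aligned}{n x 2K matrix of tangent-projected shape coordinates.}
#'     \item{aligned_sphere}{the aligned coordinates before tangent
#'       projection (unit centroid size).}
#'     \item{centroid_size, logCS}{per-specimen size and its log.}
#'     \item{mean_shape}{the 2K consensus (unit centroid size).}
#'     \item{labels}{the label columns of `data`.}
#'     \item{objective}{sum of squared distances to the consensus per
#'       iteration (non-increasing).}
#'   }
#' @references Rohlf, F.J. & Slice, D. (1990) Extensions of the Procrustes
#'   method for the optimal superimposition of landmarks. Systematic Zoology
#'   39, 40-59.
#' @export
#' @examples
#' x <- generate_landmarks(design_spec(n_species = 1, n_individuals = 4),
#'                         effect_spec())
#' fit <- procrustes_fit(x)
#' fit
procrustes_fit <- function(data, allow_reflection = FALSE, tol = 1e-8,
                           max_iter = 100) {
  stopifnot(inherits(data, "landmark_dataset"))
  coords <- lm_coords(data)
  n <- nrow(coords); k <- ncol(coords) / 2
  if (n < 2) stop("need at least 2 specimens", call. = FALSE)
  if (k < 3) stop("need at least 3 landmarks", call. = FALSE)

  configs <- lapply(seq_len(n), function(i)
    matrix(coords[i, ], k, 2, byrow = TRUE))
  cs <- vapply(configs, centroid_size, numeric(1))
  scale_ref <- max(cs)
  bad <- which(cs <= 1e-12 * scale_ref)
  if (length(bad))
    stop("degenerate specimen(s) with coincident landmarks: ",
         paste(.specimen_id(data)[bad], collapse = ", "), call. = FALSE)

  # centre and scale to unit centroid size
  z <- lapply(seq_len(n), function(i) {
    m <- sweep(configs[[i]], 2, colMeans(configs[[i]]))
    m / cs[i]
  })

  mean_cfg <- z[[1]]
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    z <- lapply(z, .rotate_onto, target = mean_cfg,
                allow_reflection = allow_reflection)
    new_mean <- Reduce(`+`, z) / n
    new_mean <- new_mean / centroid_size(new_mean)
    change <- sqrt(sum((new_mean - mean_cfg)^2))
    mean_cfg <- new_mean
    objective <- c(objective,
                   sum(vapply(z, function(m) sum((m - mean_cfg)^2),
                              numeric(1))))
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("Procrustes fit did not converge in %d iterations (last consensus change %.3g)",
                 max_iter, change), call. = FALSE)
  # final alignment to the converged consensus
  z <- lapply(z, .rotate_onto, target = mean_cfg,
              allow_reflection = allow_reflection)

  # canonical orientation: rotate the consensus onto its principal axes
  # (proper rotation only), so the fit is invariant to a common rotation of
  # the input sample
  rot_c <- .principal_rotation(mean_cfg)
  mean_cfg <- mean_cfg %*% rot_c
  z <- lapply(z, function(m) m %*% rot_c)

  m_vec <- as.vector(t(mean_cfg))            # x1,y1,... ordering
  x_mat <- do.call(rbind, lapply(z, function(m) as.vector(t(m))))
  # orthogonal projection onto the tangent plane at the consensus:
  # aligned_i = m + (I - m m') x_i, residuals orthogonal to m
  proj <- x_mat - tcrossprod(x_mat %*% m_vec, m_vec) / sum(m_vec^2)
  aligned <- sweep(proj, 2, m_vec, "+")
  colnames(aligned) <- colnames(coords)
  colnames(x_mat) <- colnames(coords)

  structure(list(aligned = aligned, aligned_sphere = x_mat,
                 centroid_size = cs, logCS = log(cs),
                 mean_shape = stats::setNames(m_vec, colnames(coords)),
                 labels = as.data.frame(data)[.label_cols],
                 landmark_names = attr(data, "landmark_names"),
                 iterations = it, objective = objective,
                 allow_reflection = allow_reflection, tol = tol),
            class = "procrustes_fit")
}

# proper rotation taking a centred configuration onto its principal axes,
# with a deterministic sign convention (largest-|x| landmark points in +x)
.principal_rotation <- function(m) {
  e <- eigen(crossprod(m), symmetric = TRUE)
  v <- e$vectors
  if (det(v) < 0) v[, 2] <- -v[, 2]
  r <- v
  mx <- m %*% r
  i <- which.max(abs(mx[, 1]))
  if (mx[i, 1] < 0) r <- -r          # rotation by pi keeps det = +1
  r
}

# optimal rotation of m onto target (both centred); orthogonal least squares
.rotate_onto <- function(m, target, allow_reflection = FALSE) {
  s <- svd(crossprod(m, target))
  r <- s$u %*% t(s$v)
  if (!allow_reflection && det(r) < 0) {
    u <- s$u; u[, 2] <- -u[, 2]
    r <- u %*% t(s$v)
  }
  m %*% r
}

.specimen_id <- function(data) {
  do.call(paste, c(as.data.frame(data)[.label_cols], list(sep = ":")))
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Generalized Procrustes fit: %d specimens, %d landmarks\n",
              nrow(x$aligned), length(x$mean_shape) / 2))
  cat(sprintf("  converged in %d iteration(s); residual SS %.4g\n",
              x$iterations, utils::tail(x$objective, 1)))
  cat(sprintf("  centroid size: %.3g - %.3g (logCS %.3g - %.3g)\n",
              min(x$centroid_size), max(x$centroid_size),
              min(x$logCS), max(x$logCS)))
  invisible(x)
}

#' @export
plot.procrustes_fit <- function(x, ...) {
  k <- length(x$mean_shape) / 2
  xi <- x$aligned[, seq(1, 2 * k, 2)]
  yi <- x$aligned[, seq(2, 2 * k, 2)]
  graphics::plot(xi, yi, pch = ".", col = "grey50", asp = 1,
                 xlab = "x (shape units)", ylab = "y (shape units)", ...)
  graphics::points(x$mean_shape[seq(1, 2 * k, 2)],
                   x$mean_shape[seq(2, 2 * k, 2)], pch = 19, col = "red")
  invisible(x)
}

#' Regress shape on log centroid size and keep the residuals
#'
#' Ordinary least squares of every tangent-space shape coordinate on
#' `logCS`, fitted separately within each pooling group (by default per
#' species, pooled across sites, measurers and repeats).  The residuals are
#' the size-free shape variables used in all downstream comparisons.  Groups
#' whose `logCS` is (numerically) constant get a zero slope with a warning,
#' or an error when `strict = TRUE`.
#'
#' @param fit a [procrustes_fit()].
#' @param pooling character vector of label columns defining the regression
#'   groups (default `"species"`).
#' @param strict logical; error instead of warn on constant `logCS`.
#' @return an object of class `"shape_residuals"`: `labels`, `variables`
#'   (n x 2K residual matrix), per-group `slope` and `intercept` matrices,
#'   and the `logCS` used.
#' @export
regress_out_size <- function(fit, pooling = "species", strict = FALSE) {
  stopifnot(inherits(fit, "procrustes_fit"))
  stopifnot(all(pooling %in% .label_cols))
  grp <- interaction(fit$labels[pooling], drop = TRUE, sep = ":")
  y <- fit$aligned
  res <- y * NA_real_
  p <- ncol(y)
  slopes <- matrix(NA_real_, p, nlevels(grp),
                   dimnames = list(colnames(y), levels(grp)))
  intercepts <- slopes
  for (g in levels(grp)) {
    i <- which(grp == g)
    if (length(i) < 3)
      stop(sprintf("pooling group '%s' has fewer than 3 specimens", g),
           call. = FALSE)
    xg <- fit$logCS[i]
    vx <- stats::var(xg)
    if (!is.finite(vx) || vx < 1e-20) {
      if (strict)
        stop(sprintf("logCS is constant within pooling group '%s'", g),
             call. = FALSE)
      warning(sprintf("logCS constant within group '%s'; slope set to 0", g),
              call. = FALSE)
      sl <- rep(0, p)
    } else {
      xc <- xg - mean(xg)
      sl <- as.vector(crossprod(xc, y[i, , drop = FALSE])) / sum(xc^2)
    }
    mu <- colMeans(y[i, , drop = FALSE])
    ic <- mu - sl * mean(xg)
    res[i, ] <- y[i, , drop = FALSE] -
      (matrix(1, length(i), 1) %*% ic + outer(xg, sl))
    slopes[, g] <- sl
    intercepts[, g] <- ic
  }
  structure(list(labels = fit$labels, variables = res, slope = slopes,
                 intercept = intercepts, logCS = fit$logCS,
                 pooling = pooling,
                 landmark_names = fit$landmark_names),
            class = "shape_residuals")
}

#' @export
print.shape_residuals <- function(x, ...) {
  cat(sprintf("Size-free shape residuals: %d specimens x %d coordinates\n",
              nrow(x$variables), ncol(x$variables)))
  cat(sprintf("  shape ~ logCS regression pooled by %s (%d group(s))\n",
              paste(x$pooling, collapse = ":"), ncol(x$slope)))
  invisible(x)
}
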