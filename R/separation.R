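# Separative power and measurer subjectivity: random-repeat selection,
# canonical variate analysis with permutation-based population detachment,
# and two-way crossed PERMANOVA on Euclidean distances.

#' Select one random repeat per (individual, measurer)
#'
#' Builds the analysis matrix for separative-power and subjectivity tests:
#' for every individual and measurer one of the available repeats is chosen
#' uniformly at random (deterministically under `seed`).  With the default
#' crossed design this yields `n_sites * n_individuals * n_measurers` rows
#' per species (270 for 3 sites x 30 individuals x 3 measurers).
#'
#' @param x a `shape_residuals` or standardized `distance_dataset` (or
#'   `list(labels, values)`) covering a complete design.
#' @param seed optional integer seed for the selection.
#' @return an object of class `"analysis_matrix"`: `labels` (with the chosen
#'   repeat recorded in column `repeat`) and `values`.
#' @export
select_random_repeat <- function(x, seed = NULL) {
  af <- .analysis_frame(x)
  lab <- af$labels
  .check_complete(lab)
  cellkey <- do.call(paste, c(lab[c("species", "site", "individual",
                                    "measurer")], list(sep = "|")))
  cells <- !duplicated(cellkey)
  keys <- cellkey[cells]
  keys <- sort(keys)
  pick <- with_seed(seed, {
    vapply(keys, function(k) {
      rows <- which(cellkey == k)
      reps <- sort(lab[["repeat"]][rows])
      chosen <- if (length(reps) == 1) reps else
        reps[sample.int(length(reps), 1)]
      rows[lab[["repeat"]][rows] == chosen][1]
    }, integer(1))
  })
  structure(list(labels = lab[pick, , drop = FALSE],
                 values = af$values[pick, , drop = FALSE]),
            class = "analysis_matrix")
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat(sprintf("Analysis matrix: %d specimens x %d variables (one random repeat per individual and measurer)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# project onto principal components with non-negligible variance; guards the
# CVA eigenproblem against the rank deficiency of shape residuals
.pc_reduce <- function(xc, tol = 1e-10) {
  s <- svd(xc)
  d2 <- s$d^2
  keep <- d2 > tol * max(d2, 1e-300)
  list(scores = xc %*% s$v[, keep, drop = FALSE],
       rotation = s$v[, keep, drop = FALSE])
}

#' Canonical variate analysis with permutation-based group detachment
#'
#' Finds the linear axes maximizing between-group relative to within-group
#' variance, via the generalized eigenproblem on the between-group and
#' pooled within-group covariance matrices after projecting onto principal
#' components with non-negligible variance (shape residuals are rank
#' deficient by construction).  At most `groups - 1` axes are retained; the
#' per-axis percentage of the among-group variance sums to 100.  Axis signs
#' are fixed by making the largest-magnitude loading positive.
#'
#' Pairwise group separation ("detachment") is tested by two-group one-way
#' PERMANOVA on the Euclidean distance matrix, uncorrected at `alpha`; for
#' three groups the count of significant pairs maps to the detachment
#' classes `"all-three"`, `"two-of-three"`, `"one"`, `"none"`.
#'
#' @param x an `analysis_matrix` (see [select_random_repeat()]), or any
#'   input accepted by it after repeat selection; alternatively a plain
#'   matrix together with `grouping` as a factor.
#' @param grouping label column name (default `"site"`) or a factor of
#'   length `nrow`.
#' @param n_perm permutations for the pairwise detachment tests.
#' @param seed optional integer seed.
#' @param alpha significance level of the detachment classification.
#' @return an object of class `"cva"`: `scores`, `eigenvalues`,
#'   `percent_variance`, `centroids`, `loadings`, `grouping`, `pairwise`
#'   (data frame with F and p per group pair), `n_significant_pairs` and
#'   `detachment_class`.
#' @export
cva <- function(x, grouping = "site", n_perm = 9999, seed = NULL,
                alpha = 0.05) {
  if (inherits(x, "analysis_matrix")) {
    vals <- x$values
    grp <- if (is.character(grouping) && length(grouping) == 1)
      factor(x$labels[[grouping]]) else factor(grouping)
  } else {
    vals <- as.matrix(x)
    if (is.character(grouping) && length(grouping) == 1)
      stop("with a plain matrix, grouping must be a factor", call. = FALSE)
    grp <- factor(grouping)
  }
  grp <- droplevels(grp)
  k <- nlevels(grp)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(grp) < 2))
    stop("every group needs more than 1 specimen", call. = FALSE)
  n <- nrow(vals)

  xc <- sweep(vals, 2, colMeans(vals))
  red <- .pc_reduce(xc)
  y <- red$scores
  p <- ncol(y)
  gm <- rowsum(y, grp) / as.vector(table(grp))
  yw <- y - gm[grp, , drop = FALSE]
  W <- crossprod(yw) / (n - k)
  B <- crossprod(sweep(gm, 2, colMeans(y)) * sqrt(as.vector(table(grp)))) /
    (k - 1)
  ew <- eigen(W, symmetric = TRUE)
  pos <- ew$values > 1e-10 * max(ew$values)
  w_isqrt <- ew$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(ew$values[pos]), sum(pos)) %*%
    t(ew$vectors[, pos, drop = FALSE])
  M <- w_isqrt %*% B %*% w_isqrt
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(k - 1, sum(eg$values > 1e-10 * max(eg$values, 1e-300)))
  if (n_axes == 0) {
    axes <- matrix(0, p, 0); evals <- numeric(0)
  } else {
    axes <- w_isqrt %*% eg$vectors[, seq_len(n_axes), drop = FALSE]
    evals <- eg$values[seq_len(n_axes)]
  }
  loadings <- red$rotation %*% axes      # back in original variable space
  # reproducible axis orientation
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]; axes[, j] <- -axes[, j]
    }
  }
  scores <- y %*% axes
  colnames(scores) <- paste0("CV", seq_len(ncol(scores)))
  centroids <- rowsum(scores, grp) / as.vector(table(grp))
  pct <- if (length(evals)) 100 * evals / sum(evals) else numeric(0)

  # pairwise detachment by two-group one-way PERMANOVA
  pw <- t(utils::combn(levels(grp), 2))
  pf <- numeric(nrow(pw)); pp <- numeric(nrow(pw))
  for (i in seq_len(nrow(pw))) {
    sel <- grp %in% pw[i, ]
    pm <- permanova(vals[sel, , drop = FALSE],
                    factors = list(group = droplevels(grp[sel])),
                    n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else
                      stage_seed(seed, paste("detach", pw[i, 1], pw[i, 2])))
    pf[i] <- pm$table$F[1]; pp[i] <- pm$table$p[1]
  }
  nsig <- sum(pp < alpha)
  detach <- if (k == 3)
    c("none", "one", "two-of-three", "all-three")[nsig + 1L]
  else sprintf("%d-of-%d pairs", nsig, nrow(pw))

  structure(list(scores = scores, eigenvalues = evals,
                 percent_variance = pct, centroids = centroids,
                 loadings = loadings, grouping = grp,
                 pairwise = data.frame(group_a = pw[, 1], group_b = pw[, 2],
                                       F = pf, p = pp),
                 n_significant_pairs = nsig, detachment_class = detach,
                 alpha = alpha),
            class = "cva")
}

#' @export
print.cva <- function(x, ...) {
  cat(sprintf("Canonical variate analysis: %d groups, %d axes\n",
              nlevels(x$grouping), length(x$eigenvalues)))
  if (length(x$percent_variance))
    cat("  % variance per axis:",
        paste(sprintf("%.1f", x$percent_variance), collapse = ", "), "\n")
  cat(sprintf("  detachment (alpha = %.2f): %s (%d significant pair(s))\n",
              x$alpha, x$detachment_class, x$n_significant_pairs))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Centroid plot of a canonical variate analysis
#'
#' Group centroids on the first two canonical axes with whiskers spanning
#' the per-group score range, in the style of the morphometric
#' method-comparison scatterplots.
#'
#' @param x a `cva` object.
#' @param col,pch per-group colours and symbols (recycled).
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.cva <- function(x, col = NULL, pch = NULL, ...) {
  if (ncol(x$scores) < 2)
    stop("need at least two canonical axes to plot", call. = FALSE)
  g <- x$grouping
  if (is.null(col)) col <- seq_len(nlevels(g))
  if (is.null(pch)) pch <- rep(19, nlevels(g))
  col <- rep_len(col, nlevels(g)); pch <- rep_len(pch, nlevels(g))
  lab <- sprintf("CV%d (%.1f%%)", 1:2, x$percent_variance[1:2])
  graphics::plot(x$centroids[, 1], x$centroids[, 2], col = col, pch = pch,
                 cex = 1.5, xlab = lab[1], ylab = lab[2],
                 xlim = range(x$scores[, 1]), ylim = range(x$scores[, 2]),
                 ...)
  for (i in seq_len(nlevels(g))) {
    s <- x$scores[g == levels(g)[i], , drop = FALSE]
    graphics::segments(min(s[, 1]), x$centroids[i, 2], max(s[, 1]),
                       x$centroids[i, 2], col = col[i])
    graphics::segments(x$centroids[i, 1], min(s[, 2]), x$centroids[i, 1],
                       max(s[, 2]), col = col[i])
  }
  graphics::legend("topright", legend = levels(g), col = col, pch = pch,
                   bty = "n")
  invisible(x)
}

#' Permutational multivariate analysis of variance on Euclidean distances
#'
#' Partitions the sum of squared inter-point Euclidean distances among the
#' terms of a one-way or two-way crossed balanced design (main effects,
#' interaction, residual), computes pseudo-F statistics against the residual
#' mean square, and obtains p-values by unrestricted permutation of the
#' specimen rows, recomputing every pseudo-F for each permutation.  The
#' partition uses the centred inner-product (Gower) matrix of the distance
#' matrix, so `SS_site + SS_measurer + SS_interaction + SS_residual =
#' SS_total` holds to numerical precision; for Euclidean distances on raw
#' variables the pseudo-F of a one-way univariate layout equals the
#' classical ANOVA F.
#'
#' @param x an `analysis_matrix`, or a numeric matrix of variables.
#' @param factors for an `analysis_matrix`, character vector of label
#'   columns (default `c("site", "measurer")`); otherwise a named list of
#'   1 or 2 factors of length `nrow`.
#' @param n_perm number of permutations (values below 99 trigger a
#'   warning).
#' @param seed optional integer seed.
#' @return an object of class `"permanova"` whose `table` component has one
#'   row per source (`factors`, `interaction` when two-way, `residual`,
#'   `total`) with columns `SS`, `df`, `MS`, `F`, `p`.
#' @references Anderson, M.J. (2001) A new method for non-parametric
#'   multivariate analysis of variance. Austral Ecology 26, 32-46.
#' @export
#' @examples
#' d <- design_spec(n_species = 1, n_individuals = 8, seed = 3)
#' x <- generate_landmarks(d, effect_spec())
#' res <- regress_out_size(procrustes_fit(x))
#' am <- select_random_repeat(res, seed = 1)
#' permanova(am, n_perm = 99, seed = 1)
permanova <- function(x, factors = c("site", "measurer"), n_perm = 9999,
                      seed = NULL) {
  if (inherits(x, "analysis_matrix")) {
    vals <- x$values
    stopifnot(is.character(factors))
    fl <- lapply(factors, function(f) factor(x$labels[[f]]))
    names(fl) <- factors
  } else {
    vals <- as.matrix(x)
    stopifnot(is.list(factors), length(factors) %in% 1:2)
    fl <- lapply(factors, factor)
    if (is.null(names(fl))) names(fl) <- paste0("factor_", seq_along(fl))
  }
  fl <- lapply(fl, droplevels)
  n <- nrow(vals)
  if (any(vapply(fl, length, integer(1)) != n))
    stop("factor length must match the number of rows", call. = FALSE)
  two_way <- length(fl) == 2 && nlevels(fl[[2]]) > 1
  if (!two_way) fl <- fl[1]
  if (n_perm < 99)
    warning("n_perm < 99 gives a very coarse p-value", call. = FALSE)

  cell <- if (two_way) interaction(fl[[1]], fl[[2]], drop = FALSE)
  else fl[[1]]
  if (two_way) {
    counts <- table(fl[[1]], fl[[2]])
    if (length(unique(as.vector(counts))) != 1 || any(counts == 0))
      stop("unbalanced or incomplete crossed design", call. = FALSE)
  }

  d <- euclidean_distance_matrix(vals)
  g <- -0.5 * d^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))        # doubly centred Gower matrix

  # orthogonal projectors of the balanced design (dense, n x n)
  pj <- function(f) {
    z <- stats::model.matrix(~ f - 1)
    z %*% (t(z) / colSums(z))          # projection onto group means
  }
  one <- matrix(1 / n, n, n)
  if (two_way) {
    ha <- pj(fl[[1]]) - one
    hb <- pj(fl[[2]]) - one
    hcells <- pj(cell) - one
    hint <- hcells - ha - hb
    hres <- diag(n) - one - hcells
    H <- list(ha, hb, hint)
    df <- c(nlevels(fl[[1]]) - 1, nlevels(fl[[2]]) - 1,
            (nlevels(fl[[1]]) - 1) * (nlevels(fl[[2]]) - 1))
    df_res <- n - nlevels(cell)
    src <- c(names(fl), "interaction")
  } else {
    ha <- pj(fl[[1]]) - one
    hres <- diag(n) - one - ha
    H <- list(ha)
    df <- nlevels(fl[[1]]) - 1
    df_res <- n - nlevels(fl[[1]])
    src <- names(fl)[1]
  }
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)

  ss_stat <- function(gp) {
    ss <- vapply(H, function(h) sum(h * gp), numeric(1))
    c(ss, sum(hres * gp))
  }
  ss <- ss_stat(g)
  ss_terms <- ss[seq_along(H)]; ss_res <- ss[length(ss)]
  ss_total <- sum(diag(g))
  ms <- ss_terms / df
  ms_res <- ss_res / df_res
  f_obs <- ms / ms_res

  p <- with_seed(seed, {
    exceed <- rep(0L, length(H))
    for (i in seq_len(n_perm)) {
      pr <- sample.int(n)
      sp <- ss_stat(g[pr, pr])
      fp <- (sp[seq_along(H)] / df) / (sp[length(sp)] / df_res)
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
    (1 + exceed) / (1 + n_perm)
  })

  tab <- data.frame(
    source = c(src, "residual", "total"),
    SS = c(ss_terms, ss_res, ss_total),
    df = c(df, df_res, n - 1),
    MS = c(ms, ms_res, NA),
    F = c(f_obs, NA, NA),
    p = c(p, NA, NA))
  structure(list(table = tab, n = n, n_perm = n_perm, two_way = two_way),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA on Euclidean distances (%d permutations)\n",
              x$n_perm))
  tab <- x$table
  tab$SS <- signif(tab$SS, 5); tab$MS <- signif(tab$MS, 3)
  tab$F <- round(tab$F, 2)
  names(tab) <- c("Source", "Sum of sqrs", "df", "Mean square", "F", "p")
  print(tab, row.names = FALSE, na.print = "")
  invisible(x)
}
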