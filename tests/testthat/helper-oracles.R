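# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: naive loops, explicit enumeration and textbook formulas.

# naive double-loop Euclidean distance matrix
naive_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  d
}

# exhaustive Mantel p-value: proportion of ALL row/column permutations of B
# (identity included) whose lower-triangle correlation reaches the observed
perm_recurse <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perm_recurse(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

exhaustive_mantel_p <- function(A, B) {
  lt <- lower.tri(A)
  a <- A[lt]
  obs <- cor(a, B[lt])
  perms <- perm_recurse(seq_len(nrow(A)))
  stats <- vapply(perms, function(p) cor(a, B[p, p][lt]), numeric(1))
  mean(stats >= obs - 1e-12)
}

# naive generalized Procrustes: explicit SVD rotation per specimen, plain
# iteration to a fixed consensus, no tangent projection
naive_gpa <- function(configs, iters = 200) {
  z <- lapply(configs, function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  })
  mean_cfg <- z[[1]]
  for (it in seq_len(iters)) {
    z <- lapply(z, function(m) {
      s <- svd(t(m) %*% mean_cfg)
      r <- s$u %*% t(s$v)
      if (det(r) < 0) {
        u <- s$u; u[, 2] <- -u[, 2]; r <- u %*% t(s$v)
      }
      m %*% r
    })
    mean_cfg <- Reduce(`+`, z) / length(z)
    mean_cfg <- mean_cfg / sqrt(sum(mean_cfg^2))
  }
  list(aligned = z, mean = mean_cfg)
}

# closed-form Kruskal-Wallis H without ties
kw_h_no_ties <- function(groups) {
  all_v <- unlist(groups)
  n <- length(all_v)
  rk <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(rk, idx, mean)
  12 / (n * (n + 1)) * sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
}

# dense generalized eigensolver for CVA on a full-rank matrix:
# eigen of solve(W) %*% B with W, B the pooled within / between covariances
brute_cva_eigen <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g); n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  gm <- apply(xc, 2, function(cl) tapply(cl, g, mean))
  ng <- as.vector(table(g))
  B <- crossprod(gm * sqrt(ng)) / (k - 1)
  W <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(g)) {
    xg <- xc[g == lev, , drop = FALSE]
    xg <- sweep(xg, 2, colMeans(xg))
    W <- W + crossprod(xg)
  }
  W <- W / (n - k)
  ee <- eigen(solve(W) %*% B)
  ord <- order(-Re(ee$values))
  list(values = Re(ee$values)[ord], vectors = Re(ee$vectors)[, ord])
}

# small complete crossed synthetic set for concordance/separation tests
small_design <- function(seed = 1, n_species = 1, n_populations = 3,
                         n_individuals = 8, ...) {
  design_spec(n_species = n_species, n_populations = n_populations,
              n_individuals = n_individuals, seed = seed, ...)
}

quiet_allometry <- function(x, ...) suppressWarnings(fit_allometry(x, ...))
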