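make_lm <- function(coords, n = nrow(coords)) {
  labels <- data.frame(species = "sp1", site = "site1",
                       individual = sprintf("ind%02d", seq_len(n)),
                       measurer = "M1", "repeat" = 1L, check.names = FALSE)
  landmark_dataset(labels, coords)
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

test_that("copies of one configuration align exactly after arbitrary similarity transforms", {
  set.seed(42)
  base <- matrix(rnorm(10), 5, 2)
  n <- 8
  coords <- t(sapply(seq_len(n), function(i) {
    m <- base %*% t(rot2(runif(1, 0, 2 * pi))) * runif(1, 0.5, 3)
    m <- sweep(m, 2, runif(2, -5, 5), "+")
    as.vector(t(m))
  }))
  fit <- procrustes_fit(make_lm(coords))
  d <- dist(fit$aligned)
  expect_lt(max(d), 1e-9)
})

test_that("centroid size is scale-equivariant and computed on raw input", {
  set.seed(1)
  tri <- matrix(rnorm(6), 3, 2)
  x1 <- make_lm(rbind(as.vector(t(tri)), as.vector(t(tri)) + 0.01), n = 2)
  f1 <- procrustes_fit(x1)
  x2 <- make_lm(rbind(2 * as.vector(t(tri)), 2 * (as.vector(t(tri)) + 0.01)),
                n = 2)
  f2 <- procrustes_fit(x2)
  expect_equal(f2$centroid_size, 2 * f1$centroid_size, tolerance = 1e-12)
  expect_equal(f2$aligned, f1$aligned, tolerance = 1e-9)
})

test_that("alignment matches an independent brute-force implementation", {
  set.seed(7)
  configs <- lapply(1:10, function(i) matrix(rnorm(10, sd = 1) +
                                               rep(c(3, 0), each = 5), 5, 2))
  coords <- t(sapply(configs, function(m) as.vector(t(m))))
  fit <- procrustes_fit(make_lm(coords), tol = 1e-10)
  oracle <- naive_gpa(configs)
  # compare pre-projection geometry through pairwise aligned distances
  ours <- as.matrix(dist(fit$aligned_sphere))
  theirs <- as.matrix(dist(t(sapply(oracle$aligned,
                                    function(m) as.vector(t(m))))))
  expect_equal(ours, theirs, tolerance = 1e-6)
  # and the consensus agrees up to rotation: compare mean-shape distances
  expect_equal(as.vector(dist(matrix(fit$mean_shape, 5, 2, byrow = TRUE))),
               as.vector(dist(oracle$mean)), tolerance = 1e-6)
})

test_that("GPA objective is non-increasing and residuals lie in the tangent plane", {
  x <- generate_landmarks(small_design(seed = 5, n_individuals = 6),
                          effect_spec())
  fit <- procrustes_fit(x)
  expect_true(all(diff(fit$objective) < 1e-10))
  resid <- sweep(fit$aligned, 2, fit$mean_shape)
  expect_lt(max(abs(resid %*% fit$mean_shape)), 1e-9)
  # mean of aligned shapes is the consensus
  expect_equal(colMeans(fit$aligned), fit$mean_shape, tolerance = 1e-8)
})

test_that("degenerate configurations are reported by specimen", {
  coords <- rbind(c(0, 0, 1, 0, 0, 1), rep(2, 6), c(0, 0, 2, 0, 0, 2))
  expect_error(procrustes_fit(make_lm(coords, n = 3)),
               "degenerate.*ind02")
})

test_that("whole-sample similarity transforms leave shape residuals unchanged", {
  x <- generate_landmarks(small_design(seed = 6, n_individuals = 5),
                          effect_spec())
  res1 <- regress_out_size(procrustes_fit(x))
  co <- as.matrix(as.data.frame(x)[setdiff(names(x),
                                           c("species", "site", "individual",
                                             "measurer", "repeat"))])
  k <- ncol(co) / 2
  r <- rot2(0.7); s <- 2.5; tr <- c(11, -4)
  co2 <- t(apply(co, 1, function(v) {
    m <- matrix(v, k, 2, byrow = TRUE)
    as.vector(t(sweep(s * (m %*% t(r)), 2, tr, "+")))
  }))
  x2 <- landmark_dataset(as.data.frame(x)[c("species", "site", "individual",
                                            "measurer", "repeat")], co2)
  res2 <- regress_out_size(procrustes_fit(x2))
  expect_equal(res1$variables, res2$variables, tolerance = 1e-8)
})

test_that("size regression recovers a constructed allometric slope and zeroes the residual covariance", {
  set.seed(13)
  n <- 100; k <- 5
  logcs <- runif(n, 3, 5)
  slope <- rnorm(2 * k, sd = 0.05)
  base <- as.vector(t(matrix(rnorm(2 * k), k, 2)))
  y <- matrix(base, n, 2 * k, byrow = TRUE) + outer(logcs, slope) +
    matrix(rnorm(n * 2 * k, sd = 0.02), n, 2 * k)
  fake_fit <- structure(list(
    aligned = y, centroid_size = exp(logcs), logCS = logcs,
    mean_shape = colMeans(y),
    labels = data.frame(species = "sp1", site = "site1",
                        individual = sprintf("i%03d", 1:n), measurer = "M1",
                        "repeat" = 1L, check.names = FALSE),
    landmark_names = paste0("lm", 1:k)), class = "procrustes_fit")
  res <- regress_out_size(fake_fit)
  # recovered slope within 2 SE of construction
  se <- 0.02 / sqrt(sum((logcs - mean(logcs))^2))
  expect_true(all(abs(res$slope[, 1] - slope) < 2.5 * se + 1e-12))
  expect_lt(max(abs(colMeans(res$variables))), 1e-10)
  expect_lt(max(abs(cov(res$variables, res$logCS))), 1e-10)
})

test_that("constant logCS yields a zero slope with a warning, or errors in strict mode", {
  set.seed(2)
  y <- matrix(rnorm(40), 10, 4)  # any width works
  fake_fit <- structure(list(
    aligned = y, centroid_size = rep(2, 10), logCS = rep(log(2), 10),
    mean_shape = colMeans(y),
    labels = data.frame(species = "sp1", site = "site1",
                        individual = sprintf("i%02d", 1:10), measurer = "M1",
                        "repeat" = 1L, check.names = FALSE),
    landmark_names = NULL), class = "procrustes_fit")
  expect_warning(res <- regress_out_size(fake_fit), "constant")
  expect_true(all(res$slope == 0))
  expect_error(suppressWarnings(regress_out_size(fake_fit, strict = TRUE)),
               "constant")
})
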