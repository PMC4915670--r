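res_for_sep <- function(seed = 2, ni = 6) {
  d <- small_design(seed = seed, n_individuals = ni)
  regress_out_size(procrustes_fit(generate_landmarks(d, effect_spec())))
}

test_that("random-repeat selection is complete, seeded and degenerate-safe", {
  res <- res_for_sep()
  am <- select_random_repeat(res, seed = 4)
  # one row per (site, individual, measurer)
  expect_equal(nrow(am$values), 3 * 6 * 3)
  key <- paste(am$labels$site, am$labels$individual, am$labels$measurer)
  expect_false(any(duplicated(key)))
  am2 <- select_random_repeat(res, seed = 4)
  expect_identical(am$labels[["repeat"]], am2$labels[["repeat"]])
  am3 <- select_random_repeat(res, seed = 5)
  expect_false(identical(am$labels[["repeat"]], am3$labels[["repeat"]]))

  d1 <- design_spec(n_species = 1, n_individuals = 4, n_repeats = 1,
                    seed = 9)
  res1 <- regress_out_size(procrustes_fit(generate_landmarks(d1,
                                                             effect_spec())))
  am1 <- select_random_repeat(res1, seed = 1)
  expect_true(all(am1$labels[["repeat"]] == 1))
})

test_that("two groups give one canonical axis carrying all the variance", {
  set.seed(12)
  x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 2), 10))
  cv <- cva(x, grouping = factor(rep(c("a", "b"), each = 10)), n_perm = 99,
            seed = 1)
  expect_equal(length(cv$eigenvalues), 1)
  expect_equal(cv$percent_variance, 100)
})

test_that("CVA axes match a brute-force generalized eigensolution on full-rank data", {
  set.seed(31)
  n <- 60; p <- 4
  g <- factor(rep(c("a", "b", "c"), each = 20))
  shift <- cbind(c(0, 0, 0, 0), c(2, 1, 0, 0), c(0, 0, 2, 1))
  x <- t(shift[, as.integer(g)]) + matrix(rnorm(n * p), n, p)
  cv <- cva(x, grouping = g, n_perm = 99, seed = 2)
  oracle <- brute_cva_eigen(x, g)
  expect_equal(cv$eigenvalues, oracle$values[1:2], tolerance = 1e-8)
  # axes agree up to sign/scale: normalized loadings collinear
  for (j in 1:2) {
    a <- cv$loadings[, j] / sqrt(sum(cv$loadings[, j]^2))
    b <- oracle$vectors[, j] / sqrt(sum(oracle$vectors[, j]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
  }
  # cross-check against the discriminant solution of MASS
  ld <- MASS::lda(x, g)
  r <- abs(cor(x %*% ld$scaling[, 1], cv$scores[, 1]))
  expect_equal(as.numeric(r), 1, tolerance = 1e-8)
})

test_that("detachment classification spans none to all-three", {
  set.seed(41)
  g <- factor(rep(c("a", "b", "c"), each = 12))
  null_x <- matrix(rnorm(36 * 3), 36, 3)
  cv0 <- cva(null_x, grouping = g, n_perm = 199, seed = 3)
  expect_true(cv0$n_significant_pairs <= 1)  # null case: mostly none

  sep_x <- null_x + 6 * t(cbind(c(1, 0, 0), c(0, 1, 0),
                                c(0, 0, 1))[, as.integer(g)])
  cv1 <- cva(sep_x, grouping = g, n_perm = 199, seed = 3)
  expect_equal(cv1$detachment_class, "all-three")
  expect_true(all(cv1$pairwise$p < 0.05))
})

test_that("rank-deficient shape residuals are handled by PC reduction", {
  res <- res_for_sep(seed = 8)
  am <- select_random_repeat(res, seed = 1)
  cv <- cva(am, grouping = "site", n_perm = 99, seed = 2)
  expect_equal(length(cv$eigenvalues), 2)
  expect_equal(sum(cv$percent_variance), 100, tolerance = 1e-8)
  expect_equal(nrow(cv$centroids), 3)
})

test_that("two-way PERMANOVA reproduces the design df and the SS partition identity", {
  res <- res_for_sep(seed = 5)
  am <- select_random_repeat(res, seed = 2)
  pm <- suppressWarnings(permanova(am, n_perm = 49, seed = 1))
  expect_equal(pm$table$df, c(2, 2, 4, 54 - 9, 53))
  ss <- pm$table$SS
  expect_equal(sum(ss[1:4]), ss[5], tolerance = 1e-8)
  expect_equal(pm$table$MS[1:4], ss[1:4] / pm$table$df[1:4])
})

test_that("univariate one-way pseudo-F equals the classical ANOVA F", {
  set.seed(51)
  y <- rnorm(30, mean = rep(c(0, 0.5, 1.5), each = 10))
  g <- factor(rep(c("a", "b", "c"), each = 10))
  pm <- permanova(cbind(y), factors = list(group = g), n_perm = 99, seed = 1)
  f_classic <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(pm$table$F[1], f_classic, tolerance = 1e-10)
})

test_that("PERMANOVA agrees with an independent distance-based implementation", {
  skip_if_not_installed("vegan")
  set.seed(61)
  n <- 36
  a <- factor(rep(c("s1", "s2", "s3"), each = 12))
  b <- factor(rep(rep(c("m1", "m2", "m3"), each = 4), 3))
  x <- matrix(rnorm(n * 5), n, 5) + 0.8 * as.integer(a) + 0.4 * as.integer(b)
  pm <- permanova(x, factors = list(site = a, measurer = b), n_perm = 99,
                  seed = 1)
  ad <- vegan::adonis2(dist(x) ~ a * b, permutations = 99, by = "terms")
  expect_equal(pm$table$SS[1:4], ad$SumOfSqs[1:4], tolerance = 1e-8)
  expect_equal(pm$table$F[1:3], ad$F[1:3], tolerance = 1e-8)
})

test_that("PERMANOVA p-values are seed-deterministic and F permutation-free", {
  set.seed(71)
  x <- matrix(rnorm(54 * 3), 54, 3)
  a <- factor(rep(c("s1", "s2", "s3"), each = 18))
  b <- factor(rep(rep(c("m1", "m2", "m3"), each = 6), 3))
  p1 <- permanova(x, factors = list(site = a, measurer = b), n_perm = 199,
                  seed = 9)
  p2 <- permanova(x, factors = list(site = a, measurer = b), n_perm = 199,
                  seed = 9)
  expect_identical(p1$table$p, p2$table$p)
  p3 <- permanova(x, factors = list(site = a, measurer = b), n_perm = 199,
                  seed = 10)
  expect_identical(p1$table$F, p3$table$F)
})

test_that("unbalanced crossed designs are rejected", {
  x <- matrix(rnorm(33 * 2), 33, 2)
  a <- factor(rep(c("s1", "s2", "s3"), each = 11))
  b <- factor(c(rep(c("m1", "m2"), c(5, 6)), rep(c("m1", "m2"), c(6, 5)),
                rep(c("m1", "m2"), c(4, 7))))
  expect_error(permanova(x, factors = list(site = a, measurer = b),
                         n_perm = 99), "unbalanced")
})
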