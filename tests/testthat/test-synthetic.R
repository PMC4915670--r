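test_that("record and measurement counts follow the crossed design", {
  d <- design_spec(n_species = 2, n_populations = 2, n_individuals = 3,
                   n_measurers = 2, n_repeats = 2, seed = 4)
  expect_equal(n_records(d), 2 * 2 * 3 * 2 * 2)
  lm <- generate_landmarks(d, effect_spec())
  expect_equal(nrow(lm), n_records(d))
  expect_equal(n_measurements(lm), n_records(d) * 11)
  sc <- generate_landmarks(d, effect_spec(), template = "scale")
  expect_equal(n_measurements(sc), n_records(d) * 7)
  dd <- generate_distances(d, effect_spec(), mode = "truss")
  expect_equal(nrow(dd), n_records(d))
  expect_equal(n_measurements(dd), n_records(d) * 16)
})

test_that("invalid designs and effects are rejected", {
  expect_error(design_spec(n_individuals = 0), "invalid design")
  expect_error(design_spec(n_measurers = 1.5), "invalid design")
  expect_error(effect_spec(repeat_noise = -1), "finite and >= 0")
  expect_error(effect_spec(sl_range = c(100, 50)), "sl_range")
  expect_error(effect_spec(sl_range = c(-10, 50)), "sl_range")
})

test_that("same seed reproduces bit-identical data; seeds change noise only", {
  d <- small_design(seed = 11, n_individuals = 4)
  a <- generate_landmarks(d, effect_spec())
  b <- generate_landmarks(d, effect_spec())
  expect_identical(a, b)
  d2 <- d; d2$seed <- 12L
  c2 <- generate_landmarks(d2, effect_spec())
  expect_identical(as.data.frame(a)[names(a)[1:5]],
                   as.data.frame(c2)[names(c2)[1:5]])  # same label structure
  expect_false(identical(a$x1, c2$x1))                 # different noise

  t1 <- generate_distances(d, effect_spec(), mode = "truss")
  t2 <- generate_distances(d, effect_spec(), mode = "truss")
  expect_identical(t1, t2)
})

test_that("zero noise and bias give identical records per individual", {
  d <- small_design(seed = 3, n_individuals = 4)
  e <- effect_spec(measurer_bias = 0, repeat_noise = 0)
  x <- generate_landmarks(d, e)
  df <- as.data.frame(x)
  sp <- split(df[setdiff(names(df), c("measurer", "repeat"))],
              paste(df$species, df$site, df$individual))
  for (s in sp) expect_true(all(vapply(s, function(col)
    length(unique(col)) == 1, logical(1))))

  e2 <- effect_spec(measurer_cv = 0, repeat_cv = 0, caliper_bias_inflation = 0,
                    caliper_noise_inflation = 0)
  y <- generate_distances(d, e2, mode = "caliper")
  dfy <- as.data.frame(y)
  spy <- split(dfy[setdiff(names(dfy), c("measurer", "repeat"))],
               paste(dfy$species, dfy$site, dfy$individual))
  for (s in spy) expect_true(all(vapply(s, function(col)
    length(unique(col)) == 1, logical(1))))
})

test_that("pure measurer bias separates measurers but not repeats", {
  d <- small_design(seed = 9, n_populations = 1, n_individuals = 6)
  e <- effect_spec(measurer_bias = 0.05, repeat_noise = 0, bias_interaction = 0)
  x <- generate_landmarks(d, e)
  df <- as.data.frame(x)
  cc <- setdiff(names(df), c("measurer", "repeat", "species", "site",
                             "individual"))
  m1r1 <- df[df$measurer == "M1" & df$`repeat` == 1, cc]
  m1r2 <- df[df$measurer == "M1" & df$`repeat` == 2, cc]
  m2r1 <- df[df$measurer == "M2" & df$`repeat` == 1, cc]
  expect_equal(as.matrix(m1r1), as.matrix(m1r2), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(as.matrix(m1r1), as.matrix(m2r1),
                                check.attributes = FALSE)))
})

test_that("allometry exponent zero decouples distances from SL", {
  d <- design_spec(n_species = 1, n_populations = 1, n_individuals = 60,
                   n_measurers = 1, n_repeats = 1, seed = 21)
  x <- generate_distances(d, effect_spec(allometry_b = 0), mode = "truss")
  vals <- as.matrix(as.data.frame(x)[attr(x, "variable_names")])
  cors <- abs(cor(log(vals), log(x$SL)))
  # no construction-level dependence: correlations are pure noise
  expect_lt(mean(cors), 0.15)
})

test_that("caliper inflation factors of 1 make the modes comparable", {
  d <- design_spec(n_species = 1, n_individuals = 20, seed = 31)
  e <- effect_spec(caliper_noise_inflation = 1, caliper_bias_inflation = 1)
  tr <- generate_distances(d, e, mode = "truss")
  ca <- generate_distances(d, e, mode = "caliper")
  # same noise law: within-individual replicate scatter matches closely
  sc <- function(x) {
    df <- as.data.frame(x)
    v <- log(as.matrix(df[attr(x, "variable_names")]))
    mean(tapply(v[, 1], paste(df$species, df$site, df$individual), sd))
  }
  expect_equal(sc(tr), sc(ca), tolerance = 0.15)
})

test_that("increasing repeat noise strictly degrades mean repeatability", {
  noise <- c(0.002, 0.008, 0.03)
  seeds <- 1:20
  mean_r <- sapply(noise, function(nv) {
    sapply(seeds, function(s) {
      d <- design_spec(n_species = 1, n_populations = 1, n_individuals = 8,
                       seed = 1000 + s)
      x <- generate_landmarks(d, effect_spec(repeat_noise = nv))
      res <- regress_out_size(procrustes_fit(x))
      mean(concordance(res, "repeatability", n_perm = 1, seed = 1,
                       mantel_mode = "sample")$R)
    })
  })
  m <- colMeans(mean_r)
  expect_true(all(diff(m) < 0))
  # and per-seed the degradation is near-universal
  expect_gt(mean(mean_r[, 1] > mean_r[, 3]), 0.95)
})
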