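make_dd <- function(SL, vals, n = length(SL)) {
  labels <- data.frame(species = "sp1", site = rep(c("s1", "s2"),
                                                   length.out = n),
                       individual = sprintf("ind%03d", seq_len(n)),
                       measurer = "M1", "repeat" = 1L, check.names = FALSE)
  distance_dataset(labels, SL, vals)
}

test_that("log-log slope identities: isometry gives b = 1, constants give b = 0", {
  set.seed(3)
  SL <- runif(50, 50, 150)
  x <- make_dd(SL, cbind(0.3 * SL, 0.8 * SL))
  b <- coef(fit_allometry(x))
  expect_equal(unname(b), c(1, 1), tolerance = 1e-10)

  x0 <- make_dd(SL, cbind(rep(7, 50), rep(2, 50)))
  expect_equal(unname(coef(fit_allometry(x0))), c(0, 0), tolerance = 1e-10)
})

test_that("allometric exponent is recovered without bias on noisy power-law data", {
  set.seed(17)
  fits <- replicate(10, {
    n <- 200
    SL <- exp(runif(n, log(50), log(150)))
    M <- 0.4 * SL^1.3 * exp(rnorm(n, sd = 0.05))
    mod <- fit_allometry(make_dd(SL, cbind(M)))
    c(mod$b[1], mod$se[1])
  })
  # the mean of 10 replicate estimates must sit within 2 SE of its own
  # precision, a stricter unbiasedness check than any single draw
  expect_lt(abs(mean(fits[1, ]) - 1.3), 2 * mean(fits[2, ]) / sqrt(10))
  # and each replicate's SE is honest: deviations of ~2 SE are the norm
  expect_lt(max(abs(fits[1, ] - 1.3)), 4 * max(fits[2, ]))
})

test_that("standardization identities and the exact power-law oracle hold", {
  set.seed(5)
  SL <- runif(40, 60, 140)
  M <- cbind(0.2 * SL^1.2, 5 * SL^0.7)
  x <- make_dd(SL, M)
  mod <- fit_allometry(x)

  # L0 = Ls for every specimen -> unchanged
  x_eq <- make_dd(rep(mod$Ls, 40), M)
  mod_eq <- list(b = mod$b, Ls = mod$Ls)
  class(mod_eq) <- "allometric_model"
  adj_eq <- standardize(x_eq, mod_eq)
  expect_equal(as.matrix(as.data.frame(adj_eq)[c("var01", "var02")]), M,
               ignore_attr = TRUE)

  # b = 0 -> unchanged
  mod0 <- structure(list(b = c(0, 0), Ls = mod$Ls),
                    class = "allometric_model")
  adj0 <- standardize(x, mod0)
  expect_equal(as.matrix(as.data.frame(adj0)[c("var01", "var02")]), M,
               ignore_attr = TRUE)

  # exact power law: M = a * L0^b collapses to the constant a * Ls^b
  adj <- standardize(x, mod)
  vals <- as.matrix(as.data.frame(adj)[c("var01", "var02")])
  expect_equal(unname(vals[, 1]), rep(0.2 * mod$Ls^unname(mod$b[1]), 40),
               tolerance = 1e-6)
  expect_equal(unname(vals[, 2]), rep(5 * mod$Ls^unname(mod$b[2]), 40),
               tolerance = 1e-6)
})

test_that("standardization is idempotent under refit and scale-equivariant", {
  set.seed(23)
  n <- 200
  SL <- exp(runif(n, log(50), log(150)))
  M <- cbind(0.4 * SL^1.25 * exp(rnorm(n, sd = 0.05)),
             1.5 * SL^0.9 * exp(rnorm(n, sd = 0.05)))
  x <- make_dd(SL, M)
  adj <- standardize(x, fit_allometry(x))
  b2 <- coef(fit_allometry(adj))
  expect_true(all(abs(b2) < 0.05))

  xc <- make_dd(SL, cbind(M[, 1] * 3, M[, 2]))
  adjc <- standardize(xc, fit_allometry(xc))
  expect_equal(as.data.frame(adjc)$var01, 3 * as.data.frame(adj)$var01,
               tolerance = 1e-10)
})

test_that("decorrelation recheck passes standardized data and fails raw allometric data", {
  set.seed(11)
  pass_rate <- mean(replicate(60, {
    n <- 80
    SL <- exp(runif(n, log(50), log(150)))
    M <- cbind(0.4 * SL^1.3 * exp(rnorm(n, sd = 0.05)),
               2 * SL^0.8 * exp(rnorm(n, sd = 0.05)))
    x <- make_dd(SL, M)
    chk <- recheck_decorrelation(standardize(x, fit_allometry(x)))
    mean(chk$pass)
  }))
  expect_gte(pass_rate, 0.9)

  n <- 120
  SL <- exp(runif(n, log(50), log(150)))
  raw <- make_dd(SL, cbind(0.4 * SL^1.3, 2 * SL^0.8))
  chk_raw <- recheck_decorrelation(raw)
  expect_true(all(!chk_raw$pass))
})

test_that("degenerate inputs are handled: constant columns and constant SL", {
  SL <- runif(30, 60, 120)
  x <- make_dd(SL, cbind(0.5 * SL, 0.5 * SL))
  adj <- standardize(x, fit_allometry(x))
  chk <- recheck_decorrelation(adj)          # adjusted columns are constant
  expect_true(all(is.na(chk$pass)))

  xconst <- make_dd(rep(100, 30), cbind(runif(30, 10, 20), runif(30, 5, 9)))
  expect_error(fit_allometry(xconst), "constant")
})

test_that("the literal printed form of the adjustment is available but not idempotent", {
  set.seed(2)
  n <- 60
  SL <- exp(runif(n, log(50), log(120)))
  M <- cbind(0.4 * SL^1.2 * exp(rnorm(n, sd = 0.03)))
  x <- make_dd(SL, M)
  mod <- fit_allometry(x)
  ratio <- standardize(x, mod)
  # the subtraction form is undefined for L0 >= Ls under a fractional b
  expect_warning(printed <- standardize(x, mod, form = "printed"),
                 "non-finite")
  fin <- is.finite(printed$var01)
  expect_true(any(fin) && any(!fin))
  expect_false(isTRUE(all.equal(as.data.frame(ratio)$var01[fin],
                                printed$var01[fin])))
})
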