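synthetic_residuals <- function(seed = 2, n_individuals = 6,
                                n_populations = 3) {
  d <- small_design(seed = seed, n_individuals = n_individuals,
                    n_populations = n_populations)
  regress_out_size(procrustes_fit(generate_landmarks(d, effect_spec())))
}

test_that("pair enumeration matches the crossed-design combinatorics", {
  res <- synthetic_residuals()
  pr <- enumerate_pairs(res, "repeatability")
  # 1 species x 3 sites x 3 measurers x choose(3,2) repeats
  expect_equal(nrow(pr), 27)
  expect_true(all(pr$measurer_a == pr$measurer_b))
  expect_true(all(pr$repeat_a < pr$repeat_b))
  per_box <- table(pr$species, pr$site, pr$measurer_a)
  expect_true(all(per_box == 3))

  pp <- enumerate_pairs(res, "reproducibility")
  # 3 sites x choose(3,2) measurer pairs x 3^2 repeat pairings
  expect_equal(nrow(pp), 81)
  expect_true(all(pp$measurer_a < pp$measurer_b))
})

test_that("a single measurer yields no reproducibility pairs", {
  d <- design_spec(n_species = 1, n_populations = 1, n_individuals = 5,
                   n_measurers = 1, seed = 4)
  res <- regress_out_size(procrustes_fit(generate_landmarks(d,
                                                            effect_spec())))
  expect_equal(nrow(enumerate_pairs(res, "reproducibility")), 0)
  expect_equal(nrow(enumerate_pairs(res, "repeatability")), 3)
})

test_that("incomplete designs are rejected with the missing cells named", {
  res <- synthetic_residuals(n_individuals = 5, n_populations = 2)
  drop <- !(res$labels$measurer == "M2" & res$labels[["repeat"]] == 3 &
              res$labels$site == "site1")
  broken <- list(labels = res$labels[drop, ], values = res$variables[drop, ])
  expect_error(specimen_matrices(broken), "sp1\\|site1\\|M2\\|3")
})

test_that("concordance of noise-free data gives Mantel R of exactly 1", {
  d <- small_design(seed = 3, n_individuals = 5)
  x <- generate_landmarks(d, effect_spec(measurer_bias = 0, repeat_noise = 0))
  res <- regress_out_size(procrustes_fit(x, tol = 1e-12))
  for (mode in c("repeatability", "reproducibility")) {
    ct <- concordance(res, mode, n_perm = 1, seed = 1)
    expect_equal(ct$R, rep(1, nrow(ct)), tolerance = 1e-9)
  }
})

test_that("concordance tables carry labels, significance and row counts", {
  res <- synthetic_residuals()
  ct <- concordance(res, "repeatability", n_perm = 99, seed = 7,
                    method = "GMB")
  expect_s3_class(ct, "concordance_table")
  expect_equal(nrow(ct), 27)
  expect_true(all(ct$method == "GMB"))
  expect_true(all(ct$n == 6))
  expect_true(all(ct$p > 0 & ct$p <= 1))
  # deterministic under the same seed
  ct2 <- concordance(res, "repeatability", n_perm = 99, seed = 7,
                     method = "GMB")
  expect_identical(ct$p, ct2$p)
})

test_that("Kruskal-Wallis grouping matches the closed-form H and letters collapse for identical groups", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  expect_equal(kw_h_no_ties(groups), 7.2)
  kw <- kruskal.test(groups)
  expect_equal(unname(kw$statistic), 7.2)

  # identical groups: H = 0, one shared letter
  tb <- data.frame(method = rep(c("A", "B"), each = 4),
                   mode = "repeatability",
                   species = "sp1", site = "site1",
                   measurer_a = "M1", repeat_a = 1, measurer_b = "M1",
                   repeat_b = 2,
                   R = rep(c(0.5, 0.6, 0.7, 0.8), 2), p = 0.01, n = 10,
                   sig = "*")
  gc <- group_and_compare(tb, "method")
  expect_equal(gc$omnibus$H, 0, tolerance = 1e-12)
  expect_true(all(gc$summary$letter == "a"))
})

test_that("clearly different groups get distinct letters at the method level", {
  set.seed(6)
  tb <- data.frame(method = rep(c("GMB", "TRA"), each = 27),
                   mode = "repeatability", species = "sp1", site = "site1",
                   measurer_a = "M1", repeat_a = 1, measurer_b = "M1",
                   repeat_b = 2,
                   R = c(runif(27, 0.85, 0.95), runif(27, 0.1, 0.3)),
                   p = 0.01, n = 10, sig = "*")
  gc <- group_and_compare(tb, "method")
  expect_lt(gc$omnibus$p, 0.05)
  s <- gc$summary
  expect_false(s$letter[s$group == "GMB"] == s$letter[s$group == "TRA"])
  # group means/SD are reported on the R scale
  expect_equal(s$n, c(27, 27))
})

test_that("measurer level is rejected for reproducibility tables", {
  res <- synthetic_residuals()
  ct <- concordance(res, "reproducibility", n_perm = 9, seed = 1,
                    method = "GMB")
  expect_error(group_and_compare(ct, "measurer"), "undefined")
})
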