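test_that("SRC reproduces the closed-form standardized coefficients", {
  set.seed(41)
  x1 <- runif(500)
  src <- standardized_regression(cbind(x1 = x1), cbind(y = 3 * x1))
  expect_equal(unname(src$beta[1, 1]), 1, tolerance = 1e-10)
  expect_equal(unname(src$r_squared[1]), 1, tolerance = 1e-10)
  # two equal-variance orthogonal inputs: beta = 1/sqrt(2) each
  x2 <- runif(2000)
  x1 <- runif(2000)
  src <- standardized_regression(cbind(x1, x2), cbind(y = x1 + x2))
  expect_equal(unname(src$beta[, 1]), rep(1 / sqrt(2), 2), tolerance = 0.05)
  # finite-sample input correlation perturbs the population identity
  expect_equal(sum(src$beta[, 1]^2), 1, tolerance = 0.05)
  expect_equal(unname(src$r_squared), 1, tolerance = 1e-12)
})

test_that("SRC on pure noise stays near zero", {
  set.seed(42)
  X <- matrix(runif(10000 * 3), ncol = 3)
  y <- rnorm(10000)
  src <- standardized_regression(X, cbind(y = y))
  expect_true(all(abs(src$beta) < 0.05))
  expect_lt(src$r_squared[1], 0.01)
  expect_false(src$linear[[1]])
})

test_that("SRC flags degenerate designs and constant outputs", {
  set.seed(43)
  x <- runif(100)
  X <- cbind(a = x, b = 2 * x)
  expect_error(standardized_regression(X, cbind(y = x)), "collinear")
  X2 <- cbind(a = x, b = runif(100))
  expect_message(
    src <- standardized_regression(X2, cbind(flat = rep(1, 100))),
    "constant"
  )
  expect_equal(unname(src$r_squared), 0)
  expect_error(standardized_regression(X2[1:3, ], cbind(y = x[1:3])),
               "N > M")
})

test_that("Sobol estimators recover the Ishigami decomposition at
           N = 2^14", {
  am <- analytic_models()
  d <- saltelli_design(2^14, 3)
  y <- am$ishigami$fn(d$unit_matrix)
  s <- sobol_indices(y, n_base = 2^14, n_params = 3)
  truth <- am$ishigami$truth
  expect_equal(as.numeric(s$s1), truth$s1, tolerance = 0.02)
  expect_equal(as.numeric(s$st), truth$st, tolerance = 0.02)
  # the purely interactive input: zero first-order, sizeable total effect
  expect_lt(abs(s$s1[3, 1]), 0.02)
  expect_equal(s$st[3, 1], 0.2437, tolerance = 0.02)
})

test_that("additive models have equal first- and total-order indices that
           sum to one", {
  d <- saltelli_design(4096, 4)
  y <- rowSums(d$unit_matrix)
  s <- sobol_indices(cbind(y = y), 4096, 4)
  expect_equal(as.numeric(s$s1), rep(0.25, 4), tolerance = 0.02)
  expect_equal(as.numeric(s$st), rep(0.25, 4), tolerance = 0.02)
  expect_equal(sum(s$s1), 1, tolerance = 0.03)
})

test_that("an unused input gets indices indistinguishable from zero", {
  am <- analytic_models()
  d <- saltelli_design(4096, 3)
  y <- am$dummy$fn(d$unit_matrix)
  s <- bootstrap_ci(sobol_indices(cbind(y = y), 4096, 3), n_boot = 300,
                    seed = 4)
  expect_lt(abs(s$s1[3, 1]), max(0.02, 2 * s$s1_ci[3, 1]))
  expect_lt(s$st[3, 1], max(0.02, 2 * s$st_ci[3, 1]))
})

test_that("degenerate or mismatched inputs are rejected", {
  expect_error(sobol_indices(cbind(y = rep(1, 64)), 16, 2), "zero variance")
  expect_error(sobol_indices(cbind(y = runif(60)), 16, 2), "N\\*\\(M\\+2\\)")
})

test_that("indices are invariant to affine rescaling of the output", {
  d <- saltelli_design(1024, 3)
  y <- analytic_models()$ishigami$fn(d$unit_matrix)
  s0 <- sobol_indices(cbind(y = y), 1024, 3)
  s1 <- sobol_indices(cbind(y = 5 * y - 20), 1024, 3)
  expect_equal(s0$s1, s1$s1, tolerance = 1e-12)
  expect_equal(s0$st, s1$st, tolerance = 1e-12)
})

test_that("bootstrap intervals are seeded, stable in n_boot and cover the
           analytic truth", {
  am <- analytic_models()
  d <- saltelli_design(4096, 3)
  y <- am$ishigami$fn(d$unit_matrix)
  s <- sobol_indices(cbind(y = y), 4096, 3)
  b1 <- bootstrap_ci(s, n_boot = 400, seed = 9)
  b1b <- bootstrap_ci(s, n_boot = 400, seed = 9)
  expect_identical(b1$s1_ci, b1b$s1_ci)
  b2 <- bootstrap_ci(s, n_boot = 800, seed = 10)
  expect_equal(b1$s1_ci, b2$s1_ci, tolerance = 0.25)
  truth <- am$ishigami$truth$s1
  for (i in 1:3) {
    expect_lt(abs(s$s1[i, 1] - truth[i]), 3 * b2$s1_ci[i, 1] + 1e-3)
  }
  expect_error(bootstrap_ci(s, conf = 1.2), "conf")
  expect_warning(bootstrap_ci(s, n_boot = 50, seed = 1), "unstable")
})

test_that("squared SRC matches the first-order index for a linear model
           run through both estimators", {
  am <- analytic_models()
  d <- saltelli_design(4096, 4)
  y <- am$linear$fn(d$unit_matrix)
  s <- sobol_indices(cbind(y = y), 4096, 4)
  A <- d$unit_matrix[1:4096, ]
  src <- standardized_regression(A, cbind(y = am$linear$fn(A)))
  expect_equal(as.numeric(s$s1), as.numeric(src$beta^2), tolerance = 0.02)
  expect_equal(as.numeric(s$s1), am$linear$truth$s1, tolerance = 0.02)
})

test_that("normalization rescales totals to unit sum and ranks by
           influence", {
  s <- structure(list(
    s1 = matrix(c(0.1, 0.2, 0.4), 3, 1,
                dimnames = list(c("a", "b", "c"), "y")),
    st = matrix(c(0.2, 0.3, 0.5), 3, 1,
                dimnames = list(c("a", "b", "c"), "y")),
    n_params = 3, n_base = 100
  ), class = "pao_sobol")
  r <- normalize_and_rank(s, groups = c("g1", "g1", "g2"))
  expect_equal(r$st_normalized, c(0.2, 0.3, 0.5))
  expect_identical(r$rank, c(3L, 2L, 1L))
  expect_identical(r$rank_in_group, c(2L, 1L, 1L))
  s$st[] <- c(1, 1, 2)
  r <- normalize_and_rank(s)
  expect_equal(r$st_normalized, c(0.25, 0.25, 0.5))
  expect_equal(sum(r$st_normalized), 1, tolerance = 1e-12)
  # negative estimates are clamped before normalizing
  s$st[] <- c(-0.1, 0.5, 0.5)
  r <- normalize_and_rank(s)
  expect_equal(r$st_normalized, c(0, 0.5, 0.5))
  s$st[] <- 0
  expect_error(normalize_and_rank(s), "all-zero")
})
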