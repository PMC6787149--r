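test_that("Saltelli designs have N*(M+2) rows with the radial block
           structure", {
  d <- saltelli_design(8, 2)
  expect_identical(nrow(d$unit_matrix), 32L)
  d <- saltelli_design(16, 5)
  expect_identical(nrow(d$unit_matrix), 16L * 7L)
  N <- 16
  A <- d$unit_matrix[1:N, ]
  B <- d$unit_matrix[N + 1:N, ]
  for (i in 1:5) {
    ABi <- d$unit_matrix[(i + 1) * N + 1:N, ]
    expect_identical(ABi[, i], B[, i])
    expect_identical(ABi[, -i], A[, -i])
  }
  expect_true(all(d$unit_matrix > 0 & d$unit_matrix < 1))
})

test_that("the headline design size is reproduced: 4000 base samples over
           39 inputs give 164,000 parameter vectors", {
  d <- saltelli_design(4000, 39) |> suppressWarnings()
  expect_identical(nrow(d$unit_matrix), 164000L)
  expect_warning(saltelli_design(4000, 2), "power of two")
})

test_that("designs are deterministic under a fixed seed", {
  a <- saltelli_design(1024, 3, seed = 7, scramble = TRUE)
  b <- saltelli_design(1024, 3, seed = 7, scramble = TRUE)
  expect_identical(a$unit_matrix, b$unit_matrix)
  plain <- saltelli_design(1024, 3)
  expect_identical(plain$unit_matrix, saltelli_design(1024, 3)$unit_matrix)
})

test_that("dirichlet weights are simplex-valued, symmetric and have the
           right mean", {
  w <- dirichlet_weights(c(0.4, 0.4, 0.4), c(1, 1, 1))
  expect_equal(w, rep(1 / 3, 3), tolerance = 1e-12)
  set.seed(5)
  U <- matrix(runif(30000), ncol = 3)
  W <- dirichlet_weights(U, c(2, 1, 1))
  expect_true(all(W >= 0))
  expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-12)
  expect_equal(colMeans(W), c(0.5, 0.25, 0.25), tolerance = 0.02)
  expect_error(dirichlet_weights(c(0.5, 0.5), c(1, 0)), "positive")
})

test_that("transform maps unit values through each record's distribution", {
  db <- build_default_database()
  U <- matrix(0.5, nrow = 1, ncol = 39)
  pm <- transform_design(U, db)
  # uniform columns land at the midpoint
  expect_equal(unname(pm$values[1, "T"]), 20)
  expect_equal(unname(pm$values[1, "pH"]), 6.75)
  # erlang column lands at the distribution median
  qpp <- db[db$name == "q_PP", ]
  expect_equal(unname(pm$values[1, "q_PP"]),
               qgamma(0.5, shape = qpp$shape, rate = qpp$rate))
  # equal unit values give equal PHA weights
  expect_equal(unname(pm$values[1, c("w_PHB_i", "w_PHV_i", "w_PH2MV_i")]),
               rep(unname(pm$values[1, "f_PHA_i"]) / 3, 3), tolerance = 1e-12)
})

test_that("sampled matrices satisfy the coupling and support invariants", {
  pm <- draw_rows(200, seed = 3)
  db <- build_default_database()
  wsum <- rowSums(pm$values[, c("w_PHB_i", "w_PHV_i", "w_PH2MV_i")])
  expect_equal(wsum, unname(pm$values[, "f_PHA_i"]), tolerance = 1e-12)
  for (j in which(db$kind == "uniform")) {
    expect_true(all(pm$values[, j] >= db$a[j] & pm$values[, j] <= db$b[j]))
  }
  expect_true(all(pm$values[, db$kind == "erlang"] > 0))
  # derived influent concentrations
  expect_equal(pm$derived$S_HAc_i,
               unname(pm$values[, "S_VFA_i"] * pm$values[, "r_HAc_HPr_i"]))
  expect_equal(pm$derived$S_HAc_i + pm$derived$S_HPr_i,
               unname(pm$values[, "S_VFA_i"]))
})

test_that("derived influent split reproduces the reference scenario
           arithmetic", {
  db <- build_default_database()
  U <- matrix(0.5, 1, 39)
  pm <- transform_design(U, db,
                         frozen = c(S_VFA_i = 1.5, r_HAc_HPr_i = 0.67,
                                    r_P_C_i = 1.5))
  expect_equal(pm$derived$S_HAc_i, 1.005)
  expect_equal(pm$derived$S_HPr_i, 0.495)
  expect_equal(pm$derived$S_PO4_i, 2.25)
})

test_that("transform is monotone per uniform and erlang column", {
  db <- build_default_database()
  U1 <- matrix(0.3, 1, 39)
  U2 <- matrix(0.7, 1, 39)
  x1 <- transform_design(U1, db)$values
  x2 <- transform_design(U2, db)$values
  mono <- db$kind %in% c("uniform", "erlang")
  expect_true(all(x2[1, mono] > x1[1, mono]))
})

test_that("transform rejects malformed input", {
  db <- build_default_database()
  expect_error(transform_design(matrix(0.5, 2, 5), db), "39 records")
  U <- matrix(0.5, 2, 39)
  U[1, 4] <- 1
  expect_error(transform_design(U, db), "strictly in")
  expect_error(transform_design(matrix(0.5, 2, 39), db[1:38, ]),
               "columns|records")
})
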