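test_that("variability tiers follow the literature-abundance rule", {
  expect_identical(variability_level(1), 0.50)
  expect_identical(variability_level(2), 0.25)
  expect_identical(variability_level(7), 0.25)
  expect_identical(variability_level(10), 0.25)
  expect_identical(variability_level(11), 0.05)
  expect_identical(variability_level(33), 0.05)
  expect_identical(variability_level(90), 0.05)
  expect_error(variability_level(0), "fixed_bounds")
  # non-increasing in the number of measurements
  lv <- vapply(1:40, variability_level, numeric(1))
  expect_true(all(diff(lv) <= 0))
})

test_that("uniform bounds extend the variability band to the observed
           extremes", {
  r <- uniform_bounds(2.0)
  expect_equal(c(r$a, r$b), c(1.0, 3.0))
  r <- uniform_bounds(c(0.9, 1.0, 1.1))
  expect_equal(c(r$a, r$b), c(0.75, 1.25))
  # range extension: the observed extremes override the variability band
  r <- uniform_bounds(c(1.0, 1.0, 2.0))
  expect_equal(c(r$a, r$b), c(1.0, 2.0))
  expect_equal(r$x_mean, 4 / 3)
  # zero-variance collections fall back to the single-measurement tier
  r <- uniform_bounds(c(1, 1, 1))
  expect_equal(c(r$a, r$b, r$var), c(0.5, 1.5, 0.5))
  expect_error(uniform_bounds(numeric(0)), "empty")
  expect_error(uniform_bounds(c(1, NA)), "non-finite")
  expect_error(uniform_bounds(c(1, Inf)), "non-finite")
})

test_that("bounds always cover every measurement", {
  set.seed(11)
  for (i in 1:50) {
    m <- rlnorm(sample(c(1, 3, 8, 15, 60), 1), meanlog = runif(1, -2, 2))
    r <- uniform_bounds(m)
    expect_lte(r$a, min(m))
    expect_gte(r$b, max(m))
    expect_lt(r$a, r$b)
  }
})

test_that("Erlang fitting recovers shape and rate by method of moments", {
  set.seed(99)
  x <- rgamma(10000, shape = 3, rate = 2)
  fit <- fit_erlang(x)
  expect_identical(fit$shape, 3L)
  expect_lt(abs(fit$rate - 2) / 2, 0.05)
  # fitted mean equals the sample mean exactly
  expect_equal(fit$shape / fit$rate, mean(x), tolerance = 1e-15)
  expect_error(fit_erlang(rep(1, 60)), "variance")
  expect_error(fit_erlang(rgamma(20, 3, 2)), "uniform_bounds")
  expect_error(fit_erlang(c(rgamma(60, 3, 2), -1)), "positive")
})

test_that("the default database holds 39 characterized records with the
           stated design variables", {
  db <- build_default_database()
  expect_identical(nrow(db), 39L)
  counts <- table(db$group)
  expect_identical(as.integer(counts[c("metabolic", "kinetic", "arrhenius",
                                       "initial_condition",
                                       "environmental")]),
                   c(12L, 9L, 6L, 10L, 2L))
  tt <- db[db$name == "T", ]
  expect_identical(tt$kind, "uniform")
  expect_equal(c(tt$a, tt$b), c(10, 30))
  ph <- db[db$name == "pH", ]
  expect_equal(c(ph$a, ph$b), c(6, 7.5))
  # the data-rich poly-P formation rate takes the Erlang path
  qpp <- db[db$name == "q_PP", ]
  expect_identical(qpp$kind, "erlang")
  expect_gt(qpp$shape, 0)
  # Dirichlet-coupled PHA weights
  w <- db[grepl("^w_", db$name), ]
  expect_identical(nrow(w), 3L)
  expect_true(all(w$kind == "dirichlet_weight"))
  expect_true(all(w$coupled_group == "pha_fractions"))
  # every measured record's range covers its measurements
  for (i in which(lengths(db$measurements) > 0)) {
    expect_lte(db$a[i], min(db$measurements[[i]]))
    expect_gte(db$b[i], max(db$measurements[[i]]))
  }
  # every record resolves to a sampling distribution
  expect_true(all(db$kind %in% c("uniform", "erlang", "dirichlet_weight")))
})

test_that("the database round-trips through YAML losslessly", {
  db <- build_default_database()
  raw <- db[c("name", "group", "units", "measurements", "fixed_bounds",
              "dirichlet")]
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_database(raw, path)
  back <- read_parameter_database(path)
  expect_equal(as.data.frame(back), as.data.frame(raw))
})

test_that("characterization rejects malformed databases", {
  db <- build_default_database()
  bad <- db
  bad$group[1] <- "mystery"
  expect_error(characterize(bad[names(db)[1:6]]), "unknown parameter group")
  bad <- db
  bad$measurements[[2]] <- c(1, NaN)
  expect_error(characterize(bad[names(db)[1:6]]), "non-finite")
  bad <- db
  bad$fixed_bounds[[which(db$name == "T")]] <- c(30, 10)
  expect_error(characterize(bad[names(db)[1:6]]), "fixed_bounds")
})

test_that("summary export has one row per record", {
  db <- build_default_database()
  path <- withr::local_tempfile(fileext = ".csv")
  out <- export_database_summary(db, path)
  expect_identical(nrow(out), 39L)
  expect_identical(names(out), c("name", "group", "a", "b", "kind"))
  expect_true(file.exists(path))
})
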