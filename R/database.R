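# Uncertainty characterization of the model's uncertain inputs: variability
# tiers keyed to literature abundance, range rules extending to the observed
# extremes, and Erlang fits where data are plentiful.

.param_groups <- c("metabolic", "kinetic", "arrhenius",
                   "initial_condition", "environmental")

#' Variability level from the number of literature measurements
#'
#' Uncertainty around a parameter's mean is scaled to how well the literature
#' pins it down: 50 % for a single reported value, 25 % for up to ten values,
#' 5 % once more than ten measurements exist.
#'
#' @param n_measurements Non-negative integer count of reported measurements.
#' @return One of `0.50`, `0.25`, `0.05`.
#' @examples
#' variability_level(1)
#' variability_level(7)
#' @export
variability_level <- function(n_measurements) {
  stopifnot(length(n_measurements) == 1, is.finite(n_measurements))
  n <- as.integer(n_measurements)
  if (n < 1) {
    stop("no measurements: supply `fixed_bounds` for design parameters ",
         "with no literature record", call. = FALSE)
  }
  if (n == 1) 0.50 else if (n <= 10) 0.25 else 0.05
}

#' Sampling range for a measurement collection
#'
#' Builds the uniform sampling range for one uncertain input.  The half-width
#' is `var * x_mean` with `var` from [variability_level()], and the range is
#' extended so it always covers the observed minimum and maximum:
#' `a = min((1 - var) * x_mean, x_min)`, `b = max((1 + var) * x_mean, x_max)`.
#' A zero-variance collection (all values identical) falls back to the
#' single-measurement 50 % rule around the common value, which preserves a
#' sampleable interval.
#'
#' @param measurements Numeric vector of at least one finite value.
#' @return A list of class `uncertainty_range` with elements `a`, `b`, `var`,
#'   `x_mean`, `x_min`, `x_max`.
#' @examples
#' uniform_bounds(c(0.9, 1.0, 1.1))
#' @export
uniform_bounds <- function(measurements) {
  if (length(measurements) == 0) {
    stop("empty measurement collection", call. = FALSE)
  }
  if (!all(is.finite(measurements))) {
    stop("non-finite measurement value", call. = FALSE)
  }
  n <- length(measurements)
  if (n > 1 && stats::var(measurements) == 0) {
    n <- 1L
    measurements <- measurements[1]
  }
  v <- variability_level(n)
  x_mean <- mean(measurements)
  x_min <- min(measurements)
  x_max <- max(measurements)
  out <- list(
    a = min((1 - v) * x_mean, x_min),
    b = max((1 + v) * x_mean, x_max),
    var = v, x_mean = x_mean, x_min = x_min, x_max = x_max
  )
  if (!(out$a < out$b)) stop("degenerate range: a >= b", call. = FALSE)
  class(out) <- "uncertainty_range"
  out
}

#' @export
print.uncertainty_range <- function(x, ...) {
  cat(sprintf("<uncertainty_range> [%g, %g]  (var = %g, mean = %g)\n",
              x$a, x$b, x$var, x$x_mean))
  invisible(x)
}

#' Method-of-moments Erlang fit for data-rich parameters
#'
#' Where a parameter has an abundant literature record (more than 50 strictly
#' positive values) its uncertainty is described by an Erlang distribution
#' (gamma with integer shape).  The shape is `round(mean^2 / variance)`
#' clamped to at least 1 and the rate is `shape / mean`, so the fitted mean
#' reproduces the sample mean exactly.
#'
#' @param measurements More than 50 strictly positive values.
#' @return A list of class `distribution_spec` with `kind = "erlang"` and
#'   elements `shape` (integer) and `rate`.
#' @examples
#' fit_erlang(rgamma(100, shape = 3, rate = 2))
#' @export
fit_erlang <- function(measurements) {
  if (length(measurements) <= 50) {
    stop("<= 50 measurements: use uniform_bounds() instead", call. = FALSE)
  }
  if (!all(is.finite(measurements) & measurements > 0)) {
    stop("Erlang fit requires strictly positive, finite values",
         call. = FALSE)
  }
  m <- mean(measurements)
  v <- stats::var(measurements)
  if (v == 0) {
    stop("zero sample variance: Erlang shape is unbounded", call. = FALSE)
  }
  k <- max(1L, as.integer(round(m^2 / v)))
  out <- list(kind = "erlang", shape = k, rate = k / m)
  class(out) <- "distribution_spec"
  out
}

#' @export
print.distribution_spec <- function(x, ...) {
  ps <- paste(names(x)[-1], unlist(x[-1]), sep = " = ", collapse = ", ")
  cat(sprintf("<distribution_spec> %s(%s)\n", x$kind, ps))
  invisible(x)
}

# resolve the sampling distribution of one record
.resolve_spec <- function(name, measurements, fixed_bounds, dirichlet) {
  if (!is.null(dirichlet)) {
    out <- list(kind = "dirichlet_weight",
                alpha = dirichlet$alpha,
                coupled_group = dirichlet$coupled_group)
    if (!(is.numeric(out$alpha) && out$alpha > 0)) {
      stop("record '", name, "': dirichlet alpha must be positive",
           call. = FALSE)
    }
    class(out) <- "distribution_spec"
    return(out)
  }
  if (!is.null(fixed_bounds)) {
    if (!(length(fixed_bounds) == 2 && fixed_bounds[1] < fixed_bounds[2])) {
      stop("record '", name, "': fixed_bounds must be (lower < upper)",
           call. = FALSE)
    }
    out <- list(kind = "uniform", a = fixed_bounds[1], b = fixed_bounds[2])
    class(out) <- "distribution_spec"
    return(out)
  }
  if (length(measurements) == 0) {
    stop("record '", name, "': no measurements and no fixed_bounds",
         call. = FALSE)
  }
  if (length(measurements) > 50) {
    return(fit_erlang(measurements))
  }
  rng <- uniform_bounds(measurements)
  out <- list(kind = "uniform", a = rng$a, b = rng$b)
  class(out) <- "distribution_spec"
  out
}

#' Characterize a parameter database
#'
#' Applies the variability rule, the range rules and the Erlang criterion to
#' every record of a raw parameter database, attaching the resolved sampling
#' specification.  Records with `fixed_bounds` are sampled uniformly on those
#' bounds; Dirichlet weight records are passed through for coupled simplex
#' sampling.
#'
#' @param db A parameter database tibble as returned by
#'   [read_parameter_database()].
#' @return The database tibble with columns `a`, `b`, `var`, `x_mean`,
#'   `kind`, `shape`, `rate`, `alpha`, `coupled_group` and a `spec`
#'   list-column holding each record's `distribution_spec`.
#' @export
characterize <- function(db) {
  validate_parameter_database(db)
  spec <- purrr::pmap(
    list(db$name, db$measurements, db$fixed_bounds, db$dirichlet),
    .resolve_spec
  )
  rng <- purrr::map2(db$measurements, db$fixed_bounds, function(m, fb) {
    if (length(m) > 0) {
      uniform_bounds(m)
    } else if (!is.null(fb)) {
      list(a = fb[1], b = fb[2], var = NA_real_,
           x_mean = mean(fb), x_min = NA_real_, x_max = NA_real_)
    } else {
      list(a = 0, b = 1, var = NA_real_, x_mean = NA_real_,
           x_min = NA_real_, x_max = NA_real_)
    }
  })
  db$a <- purrr::map_dbl(rng, "a")
  db$b <- purrr::map_dbl(rng, "b")
  db$var <- purrr::map_dbl(rng, "var")
  db$x_mean <- purrr::map_dbl(rng, "x_mean")
  db$kind <- purrr::map_chr(spec, "kind")
  db$shape <- purrr::map_dbl(spec, function(s) s$shape %||% NA_real_)
  db$rate <- purrr::map_dbl(spec, function(s) s$rate %||% NA_real_)
  db$alpha <- purrr::map_dbl(spec, function(s) s$alpha %||% NA_real_)
  db$coupled_group <- purrr::map_chr(
    spec, function(s) s$coupled_group %||% NA_character_
  )
  db$spec <- spec
  db
}

#' Validate the structural invariants of a parameter database
#'
#' @param db A parameter database tibble.
#' @return `db`, invisibly, after checking groups, finiteness of all
#'   measurements and ordering of any fixed bounds.
#' @export
validate_parameter_database <- function(db) {
  stopifnot(is.data.frame(db))
  required <- c("name", "group", "units", "measurements",
                "fixed_bounds", "dirichlet")
  missing <- setdiff(required, names(db))
  if (length(missing) > 0) {
    stop("database lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(db$name)) {
    stop("duplicated parameter names", call. = FALSE)
  }
  bad <- setdiff(unique(db$group), .param_groups)
  if (length(bad) > 0) {
    stop("unknown parameter group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ok <- purrr::map_lgl(db$measurements, function(m) all(is.finite(m)))
  if (!all(ok)) {
    stop("non-finite measurements in: ",
         paste(db$name[!ok], collapse = ", "), call. = FALSE)
  }
  ok <- purrr::map_lgl(db$fixed_bounds, function(fb) {
    is.null(fb) || (length(fb) == 2 && all(is.finite(fb)) && fb[1] < fb[2])
  })
  if (!all(ok)) {
    stop("invalid fixed_bounds in: ",
         paste(db$name[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(db)
}

#' Read a parameter database from YAML
#'
#' @param path Path to a YAML database file (one entry per record with
#'   `name`, `group`, `units`, `measurements` and optional `fixed_bounds` or
#'   `dirichlet` fields).
#' @return A tibble with one row per record; `measurements` is a list-column,
#'   `fixed_bounds` and `dirichlet` hold `NULL` where absent.
#' @export
read_parameter_database <- function(path) {
  raw <- yaml::read_yaml(path)$parameters
  db <- tibble::tibble(
    name = purrr::map_chr(raw, "name"),
    group = purrr::map_chr(raw, "group"),
    units = purrr::map_chr(raw, "units"),
    measurements = purrr::map(raw, function(r) {
      as.numeric(unlist(r$measurements))
    }),
    fixed_bounds = purrr::map(raw, function(r) {
      if (is.null(r$fixed_bounds)) NULL else as.numeric(r$fixed_bounds)
    }),
    dirichlet = purrr::map(raw, "dirichlet")
  )
  validate_parameter_database(db)
  db
}

#' Write a parameter database to YAML
#'
#' Inverse of [read_parameter_database()]; the write/read round trip is
#' lossless for all record fields.
#'
#' @param db A parameter database tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_database <- function(db, path) {
  validate_parameter_database(db)
  entries <- purrr::pmap(
    list(db$name, db$group, db$units, db$measurements,
         db$fixed_bounds, db$dirichlet),
    function(name, group, units, measurements, fixed_bounds, dirichlet) {
      e <- list(name = name, group = group, units = units,
                measurements = as.list(measurements))
      if (!is.null(fixed_bounds)) e$fixed_bounds <- as.list(fixed_bounds)
      if (!is.null(dirichlet)) e$dirichlet <- dirichlet
      e
    }
  )
  yaml::write_yaml(list(parameters = entries), path, precision = 15)
  invisible(path)
}

#' Default 39-input uncertainty database
#'
#' Loads the package's curated database of the 39 uncertain model inputs --
#' 12 metabolic parameters, 9 kinetic parameters, 6 Arrhenius temperature
#' coefficients, 10 initial/influent conditions and the 2 environmental
#' design variables (temperature, sampled on 10-30 degrees C, and pH, sampled
#' on 6-7.5) -- and characterizes every record.  The three PHA constituent
#' weights are Dirichlet-coupled so they always sum to the sampled total PHA
#' fraction.
#'
#' @return A characterized database tibble with 39 rows (see
#'   [characterize()]).
#' @examples
#' db <- build_default_database()
#' nrow(db)
#' @export
build_default_database <- function() {
  path <- system.file("extdata", "pao_parameters.yaml", package = "paosens")
  if (path == "") {
    stop("packaged parameter database not found", call. = FALSE)
  }
  db <- characterize(read_parameter_database(path))
  stopifnot(nrow(db) == 39)
  db
}

#' Export a characterized database as a plain summary table
#'
#' @param db A characterized database (from [characterize()]).
#' @param path Optional CSV output path; when given the table is also
#'   written with [utils::write.csv()].
#' @return A tibble with columns `name`, `group`, `a`, `b`, `kind`.
#' @export
export_database_summary <- function(db, path = NULL) {
  out <- tibble::tibble(name = db$name, group = db$group,
                        a = db$a, b = db$b, kind = db$kind)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
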