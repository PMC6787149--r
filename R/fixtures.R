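# Synthetic fixtures: mock literature-measurement collections, analytic
# test models with known variance decompositions, and canned cycle
# scenarios.  Everything here is seeded and byte-reproducible.

#' Specification for a synthetic fixture set
#'
#' @param seed Integer seed; identical specs produce identical fixtures.
#' @param counts Named integer vector of per-parameter measurement counts.
#'   The default spans the three variability tiers (1, 2-10, >10) and
#'   includes one data-rich parameter (>50 points) to exercise the Erlang
#'   path.
#' @param truth Named list of truth distributions per parameter, each
#'   `list(dist = "normal", mean, sd)` or `list(dist = "erlang", shape,
#'   rate)`.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         counts = c(p_single = 1L, p_sparse = 7L,
                                    p_rich = 33L, p_dense = 90L),
                         truth = NULL) {
  stopifnot(all(counts >= 1))
  if (is.null(truth)) {
    truth <- list(
      p_single = list(dist = "normal", mean = 2, sd = 0.4),
      p_sparse = list(dist = "normal", mean = 1, sd = 0.2),
      p_rich = list(dist = "normal", mean = 0.2, sd = 0.03),
      p_dense = list(dist = "erlang", shape = 3, rate = 2)
    )[names(counts)]
  }
  out <- list(seed = as.integer(seed), counts = counts, truth = truth)
  class(out) <- "fixture_spec"
  out
}

#' Generate mock literature-measurement collections
#'
#' Draws seeded measurement sets from the spec's truth distributions,
#' emulating the varying abundance of literature data behind each model
#' input without any download.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of numeric measurement vectors.
#' @export
mock_literature <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  purrr::imap(as.list(spec$counts), function(n, nm) {
    tr <- spec$truth[[nm]]
    if (is.null(tr)) tr <- list(dist = "normal", mean = 1, sd = 0.2)
    if (tr$dist == "erlang") {
      stats::rgamma(n, shape = tr$shape, rate = tr$rate)
    } else {
      abs(stats::rnorm(n, tr$mean, tr$sd))
    }
  })
}

# closed-form variance decompositions (the analytic oracle backing the
# estimator validation; kept apart from the estimator code on purpose)
.linear_truth <- function(coef, input_var = rep(1 / 12, length(coef))) {
  v_i <- coef^2 * input_var
  v <- sum(v_i)
  list(s1 = v_i / v, st = v_i / v, beta = sign(coef) * sqrt(v_i / v),
       r_squared = 1)
}

.ishigami_truth <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- b^2 * pi^8 * 8 / 225
  v <- v1 + v2 + v13
  list(s1 = c(v1, v2, 0) / v,
       st = c(v1 + v13, v2, v13) / v,
       var_y = v)
}

#' Analytic test models with known variance decompositions
#'
#' A small suite of deterministic test functions whose first- and
#' total-order Sobol indices (and, where meaningful, standardized
#' regression coefficients) are known in closed form, used to validate the
#' estimators independently of the metabolic model:
#' \describe{
#'   \item{linear}{`y = sum(coef_i * x_i)` on independent uniform inputs;
#'     `beta_i^2 = S_i = ST_i` and `R^2 = 1`.}
#'   \item{ishigami}{the standard three-input benchmark with strong
#'     interactions and one purely interactive input, on `(-pi, pi)^3`.}
#'   \item{dummy}{a linear model carrying one unused input whose true
#'     indices are exactly zero.}
#' }
#'
#' @param linear_coef Coefficients of the linear model.
#' @param ishigami_a,ishigami_b Ishigami constants (community-standard
#'   defaults 7 and 0.1).
#' @return Named list of models; each has `n_inputs`, `fn` (mapping a
#'   unit-hypercube matrix to outputs) and `truth` (closed-form `s1`, `st`,
#'   and where applicable `beta`, `r_squared`).
#' @export
analytic_models <- function(linear_coef = c(1, 2, 3, 4),
                            ishigami_a = 7, ishigami_b = 0.1) {
  linear <- list(
    n_inputs = length(linear_coef),
    fn = function(U) as.matrix(U) %*% linear_coef,
    truth = .linear_truth(linear_coef)
  )
  ishigami <- list(
    n_inputs = 3L,
    fn = function(U) {
      X <- -pi + 2 * pi * as.matrix(U)
      sin(X[, 1]) + ishigami_a * sin(X[, 2])^2 +
        ishigami_b * X[, 3]^4 * sin(X[, 1])
    },
    truth = .ishigami_truth(ishigami_a, ishigami_b)
  )
  dummy_coef <- c(1, 2, 0)
  dummy <- list(
    n_inputs = 3L,
    fn = function(U) as.matrix(U)[, 1] + 2 * as.matrix(U)[, 2],
    truth = .linear_truth(dummy_coef)
  )
  list(linear = linear, ishigami = ishigami, dummy = dummy)
}

#' Canned cycle scenarios
#'
#' Named reference conditions for the cycle simulator.  `"fig2_fixed_ic"`
#' holds the initial conditions fixed at the reference reactor state (total
#' influent VFA 1.5 C-mmol/l split 0.67 acetate, phosphate-to-carbon ratio
#' 1.5, biomass 4.43 C-mmol/l, intra-cellular PHA/glycogen/poly-P fractions
#' 0.14/0.36/0.30) with all kinetic and metabolic inputs at their database
#' means, temperature 20 C and pH 7.
#'
#' @param name Scenario name.
#' @param database A characterized parameter database supplying mean values
#'   for the non-scenario inputs.
#' @return Named numeric row vector (inputs plus derived influent
#'   concentrations) suitable for [resolve_parameters()].
#' @export
paper_scenario <- function(name = "fig2_fixed_ic",
                           database = build_default_database()) {
  known <- c("fig2_fixed_ic")
  if (!name %in% known) {
    stop("unknown scenario '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  means <- ifelse(database$kind == "erlang",
                  database$shape / database$rate,
                  (database$a + database$b) / 2)
  row <- stats::setNames(means, database$name)
  row[c("S_VFA_i", "r_HAc_HPr_i", "r_P_C_i", "X_PAO_i")] <-
    c(1.5, 0.67, 1.5, 4.43)
  row[c("f_PHA_i", "f_Gly_i", "f_PP_i")] <- c(0.14, 0.36, 0.30)
  # PHA split unspecified in the reference condition: equal thirds
  row[c("w_PHB_i", "w_PHV_i", "w_PH2MV_i")] <- 0.14 / 3
  row[c("T", "pH")] <- c(20, 7)
  c(row,
    S_HAc_i = row[["S_VFA_i"]] * row[["r_HAc_HPr_i"]],
    S_HPr_i = row[["S_VFA_i"]] * (1 - row[["r_HAc_HPr_i"]]),
    S_PO4_i = row[["S_VFA_i"]] * row[["r_P_C_i"]])
}
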