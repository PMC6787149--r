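# Saltelli cross-sampled quasi-random designs and their transform to
# physical parameter space.

#' Saltelli cross-sampled design on the unit hypercube
#'
#' Builds the radial cross-sampling design for simultaneous estimation of
#' first- and total-order Sobol indices: a `2M`-dimensional Sobol' sequence
#' supplies the base matrices `A` and `B` (`N` rows each), and `M` hybrid
#' blocks `A_B^(i)` equal `A` with column `i` replaced from `B`, for
#' `N * (M + 2)` rows in total.
#'
#' @param n_base Base sample size `N` (at least 2).  Powers of two make best
#'   use of the digital sequence; other sizes are accepted with a warning.
#' @param n_params Number of independent sampling dimensions `M`.
#' @param seed Integer seed, used only when `scramble = TRUE`.
#' @param scramble Apply a seeded digital shift to the Sobol' points?
#'   Default `FALSE`: the design is then fully deterministic.
#' @return An object of class `saltelli_design`: a list with `unit_matrix`
#'   (`N*(M+2)` by `M`, entries strictly in (0, 1)), `n_base`, `n_params`,
#'   `seed`, `scramble` and a `block` row-label vector (`"A"`, `"B"`,
#'   `"AB1"`, ...).
#' @examples
#' d <- saltelli_design(8, 2)
#' dim(d$unit_matrix)
#' @export
saltelli_design <- function(n_base, n_params, seed = NULL, scramble = FALSE) {
  stopifnot(n_base >= 2, n_params >= 1)
  n_base <- as.integer(n_base)
  n_params <- as.integer(n_params)
  if (bitwAnd(n_base, n_base - 1L) != 0L) {
    warning("n_base = ", n_base, " is not a power of two; the Sobol' ",
            "sequence is balanced at powers of two", call. = FALSE)
  }
  U <- sobol_sequence(n_base, 2L * n_params, scramble = scramble, seed = seed)
  A <- U[, seq_len(n_params), drop = FALSE]
  B <- U[, n_params + seq_len(n_params), drop = FALSE]
  blocks <- vector("list", n_params + 2L)
  blocks[[1]] <- A
  blocks[[2]] <- B
  for (i in seq_len(n_params)) {
    ABi <- A
    ABi[, i] <- B[, i]
    blocks[[i + 2L]] <- ABi
  }
  out <- list(
    unit_matrix = do.call(rbind, blocks),
    n_base = n_base,
    n_params = n_params,
    seed = seed,
    scramble = scramble,
    block = rep(c("A", "B", paste0("AB", seq_len(n_params))),
                each = n_base)
  )
  class(out) <- "saltelli_design"
  out
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat(sprintf(
    "<saltelli_design> N = %d base samples, M = %d parameters, %d rows%s\n",
    x$n_base, x$n_params, nrow(x$unit_matrix),
    if (x$scramble) sprintf(" (scrambled, seed %s)", x$seed) else ""
  ))
  invisible(x)
}

#' Dirichlet simplex weights from unit-hypercube values
#'
#' Deterministic column-wise transform used to couple compositional inputs
#' inside a quasi-random design: each unit value is pushed through the
#' inverse CDF of a Gamma(alpha_i, 1) distribution and the results are
#' normalized to sum to one.  Marginally the weights follow a Dirichlet
#' distribution with concentration `alpha`.
#'
#' @param unit_values Numeric vector in (0, 1), or a matrix with one row per
#'   sample and one column per component.
#' @param alpha Positive concentration vector, one entry per component.
#' @return Weights of the same shape as `unit_values`; each sample's weights
#'   are non-negative and sum to one.
#' @examples
#' dirichlet_weights(c(0.5, 0.5, 0.5), c(1, 1, 1))
#' @export
dirichlet_weights <- function(unit_values, alpha) {
  if (any(alpha <= 0)) stop("alpha must be strictly positive", call. = FALSE)
  if (is.matrix(unit_values)) {
    stopifnot(ncol(unit_values) == length(alpha))
    g <- vapply(seq_along(alpha), function(j) {
      stats::qgamma(unit_values[, j], shape = alpha[j], rate = 1)
    }, numeric(nrow(unit_values)))
    g <- matrix(g, nrow = nrow(unit_values))
    g / rowSums(g)
  } else {
    stopifnot(length(unit_values) == length(alpha))
    g <- stats::qgamma(unit_values, shape = alpha, rate = 1)
    g / sum(g)
  }
}

#' Transform a unit-hypercube design to physical parameter space
#'
#' Maps every column of a design through the sampling distribution resolved
#' for the corresponding database record: uniform columns by
#' `a + u * (b - a)`, Erlang columns by the Gamma inverse CDF, and
#' Dirichlet-coupled weight columns via [dirichlet_weights()] followed by
#' multiplication with the row's sampled coupling total (for the PHA
#' constituents, the total PHA fraction), so the coupled columns sum to that
#' total exactly.  Initial liquid-phase concentrations are derived from the
#' sampled influent descriptors and returned alongside.
#'
#' @param design A `saltelli_design`, or any numeric matrix with values in
#'   (0, 1) and one column per database record.
#' @param database A characterized parameter database ([characterize()] /
#'   [build_default_database()]); column order follows database order.
#' @param coupling_totals Named character vector mapping each Dirichlet
#'   `coupled_group` to the database record holding its total.
#' @param frozen Optional named numeric vector; the named columns are pinned
#'   to the given physical values after transformation (conditioning the
#'   experiment on fixed process conditions).
#' @return An object of class `parameter_matrix`: list with `values` (rows by
#'   `M` physical matrix), `analysis_values` (identical except that
#'   Dirichlet-coupled columns keep their independent Gamma coordinates, so
#'   regression designs stay full rank), `column_names`, `derived` (tibble
#'   with `S_HAc_i`, `S_HPr_i`, `S_PO4_i`), and the design metadata.
#' @export
transform_design <- function(design, database,
                             coupling_totals = c(pha_fractions = "f_PHA_i"),
                             frozen = NULL) {
  if (inherits(design, "saltelli_design")) {
    U <- design$unit_matrix
    meta <- design[c("n_base", "n_params", "seed", "scramble", "block")]
  } else {
    U <- as.matrix(design)
    meta <- list(n_base = nrow(U), n_params = ncol(U),
                 seed = NULL, scramble = FALSE, block = NULL)
  }
  if (ncol(U) != nrow(database)) {
    stop("design has ", ncol(U), " columns but database has ",
         nrow(database), " records", call. = FALSE)
  }
  if (any(U <= 0 | U >= 1)) {
    stop("unit values must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.null(database$kind)) {
    stop("database is not characterized; run characterize() first",
         call. = FALSE)
  }
  X <- matrix(NA_real_, nrow = nrow(U), ncol = ncol(U),
              dimnames = list(NULL, database$name))
  for (j in seq_len(ncol(U))) {
    kind <- database$kind[j]
    if (kind == "uniform") {
      X[, j] <- database$a[j] + U[, j] * (database$b[j] - database$a[j])
    } else if (kind == "erlang") {
      X[, j] <- stats::qgamma(U[, j], shape = database$shape[j],
                              rate = database$rate[j])
    } else if (kind == "dirichlet_weight") {
      # filled below, group-wise
    } else {
      stop("no sampling rule for kind '", kind, "' (column ",
           database$name[j], ")", call. = FALSE)
    }
  }
  # independent coordinates for the regression-based analyses: identical to
  # the physical values except that Dirichlet-coupled columns keep their
  # independent Gamma variates (the coupled fractions are exactly linearly
  # dependent on their total, which would make an OLS design singular)
  A <- X
  for (grp in unique(stats::na.omit(database$coupled_group))) {
    idx <- which(!is.na(database$coupled_group) &
                   database$coupled_group == grp)
    g <- vapply(seq_along(idx), function(j) {
      stats::qgamma(U[, idx[j]], shape = database$alpha[idx[j]], rate = 1)
    }, numeric(nrow(U)))
    g <- matrix(g, nrow = nrow(U))
    w <- g / rowSums(g)
    total_name <- coupling_totals[[grp]]
    if (is.null(total_name) || !(total_name %in% database$name)) {
      stop("no coupling total known for Dirichlet group '", grp, "'",
           call. = FALSE)
    }
    X[, idx] <- w * X[, total_name]
    A[, idx] <- g
  }
  if (!is.null(frozen)) {
    bad <- setdiff(names(frozen), colnames(X))
    if (length(bad) > 0) {
      stop("frozen columns not in database: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(frozen)) {
      X[, nm] <- frozen[[nm]]
      A[, nm] <- frozen[[nm]]
    }
  }
  derived <- NULL
  if (all(c("S_VFA_i", "r_HAc_HPr_i", "r_P_C_i") %in% colnames(X))) {
    derived <- tibble::tibble(
      S_HAc_i = unname(X[, "S_VFA_i"] * X[, "r_HAc_HPr_i"]),
      S_HPr_i = unname(X[, "S_VFA_i"] * (1 - X[, "r_HAc_HPr_i"])),
      S_PO4_i = unname(X[, "S_VFA_i"] * X[, "r_P_C_i"])
    )
  }
  out <- c(list(values = X, analysis_values = A,
                column_names = database$name, derived = derived),
           meta)
  class(out) <- "parameter_matrix"
  out
}

#' @export
print.parameter_matrix <- function(x, ...) {
  cat(sprintf("<parameter_matrix> %d rows x %d parameters\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname transform_design
#' @param x A `parameter_matrix`.
#' @param ... Unused.
#' @export
as_tibble.parameter_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values))
  if (!is.null(x$block)) out <- dplyr::mutate(out, block = x$block,
                                              .before = 1)
  out
}
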