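# Sensitivity measures: standardized regression coefficients with R^2
# diagnostics, first- and total-order Sobol indices from Saltelli designs,
# bootstrap confidence intervals, normalization and ranking.

#' Standardized regression coefficients (SRC)
#'
#' Fits one ordinary-least-squares regression per output on all inputs and
#' rescales each slope by the input/output standard deviations,
#' `beta = b * sigma_m / sigma_k`.  For an exactly linear model the squared
#' coefficients sum to the coefficient of determination, which equals one.
#' `R^2 >= 0.7` is flagged as the rule-of-thumb threshold above which the
#' SRC is a trustworthy first-order sensitivity measure.
#'
#' @param inputs `N x M` numeric matrix or data frame of sampled inputs.
#' @param outputs `N x K` matrix/data frame of scalar outputs (or a
#'   `pao_outputs` object, whose cycle means are transposed in).
#' @return Object of class `pao_src`: list with `beta` (`M x K`), `raw_b`,
#'   `intercept`, `r_squared`, `residual_variance`, `linear` (logical per
#'   output), `n`.
#' @export
standardized_regression <- function(inputs, outputs) {
  X <- as.matrix(inputs)
  if (inherits(outputs, "pao_outputs")) {
    Y <- t(outputs$cycle_means)
  } else {
    Y <- as.matrix(outputs)
  }
  keep <- stats::complete.cases(Y) & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(X)
  m <- ncol(X)
  if (n <= m + 1) stop("need N > M + 1 samples", call. = FALSE)
  qr_x <- qr(cbind(`(Intercept)` = 1, X))
  if (qr_x$rank < m + 1) {
    bad <- colnames(qr_x$qr)[qr_x$pivot[(qr_x$rank + 1):(m + 1)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qr_x, Y)
  b <- coefs[-1, , drop = FALSE]
  fitted <- qr.fitted(qr_x, Y)
  sd_x <- apply(X, 2, stats::sd)
  sd_y <- apply(Y, 2, stats::sd)
  const <- sd_y == 0
  if (any(const)) {
    message("constant output column(s) ",
            paste(colnames(Y)[const], collapse = ", "),
            ": R^2 set to 0 by convention")
  }
  rss <- colSums((Y - fitted)^2)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(const, 0, 1 - rss / tss)
  beta <- b * (sd_x %o% ifelse(const, 1, 1 / sd_y))
  beta[, const] <- 0
  out <- list(
    beta = beta, raw_b = b, intercept = coefs[1, ],
    r_squared = stats::setNames(r2, colnames(Y)),
    residual_variance = rss / (n - m - 1),
    linear = r2 >= 0.7, n = n
  )
  class(out) <- "pao_src"
  out
}

#' @export
print.pao_src <- function(x, ...) {
  cat(sprintf("<pao_src> %d inputs x %d outputs, N = %d\n",
              nrow(x$beta), ncol(x$beta), x$n))
  cat("R^2:", paste(sprintf("%s %.3g", names(x$r_squared), x$r_squared),
                    collapse = ", "), "\n")
  invisible(x)
}

# split a stacked Saltelli output matrix into A, B and the AB_i blocks
.split_blocks <- function(y, n_base, n_params) {
  y <- as.matrix(y)
  expected <- n_base * (n_params + 2)
  if (nrow(y) != expected) {
    stop("output rows (", nrow(y), ") do not match N*(M+2) = ", expected,
         call. = FALSE)
  }
  idx <- function(b) ((b - 1) * n_base + 1):(b * n_base)
  list(
    A = y[idx(1), , drop = FALSE],
    B = y[idx(2), , drop = FALSE],
    AB = lapply(seq_len(n_params), function(i) y[idx(i + 2), , drop = FALSE])
  )
}

#' First- and total-order Sobol indices from a Saltelli design
#'
#' Estimates, per output, the first-order index with the Saltelli (2010)
#' estimator `S_i = mean(f_B * (f_ABi - f_A)) / Var(Y)` and the total-order
#' index with the Jansen estimator
#' `ST_i = mean((f_A - f_ABi)^2) / (2 Var(Y))`, with `Var(Y)` computed on
#' the pooled `A` and `B` samples.  Base samples containing any failed
#' simulation are dropped as complete tuples so the estimators stay valid.
#'
#' @param y Output values evaluated over the stacked design rows
#'   (`N*(M+2)` by `K` matrix), or a `pao_outputs` object from a Saltelli
#'   run (cycle means are transposed in).
#' @param n_base Base sample size `N` (taken from `y` when it is a
#'   `pao_outputs`).
#' @param n_params Number of parameters `M`.
#' @param input_names,output_names Optional dimension names for the result.
#' @return Object of class `pao_sobol`: list with `s1` and `st`
#'   (`M x K` matrices), `var_y`, `n_base` (after tuple filtering),
#'   `n_params`; confidence intervals are added by [bootstrap_ci()].
#' @export
sobol_indices <- function(y, n_base = NULL, n_params = NULL,
                          input_names = NULL, output_names = NULL) {
  if (inherits(y, "pao_outputs")) {
    n_base <- n_base %||% y$n_base
    ym <- t(y$cycle_means)
  } else {
    ym <- as.matrix(y)
  }
  if (is.null(n_base)) stop("n_base is required", call. = FALSE)
  n_params <- n_params %||% (nrow(ym) / n_base - 2)
  stopifnot(n_params == round(n_params), n_params >= 1)
  if (nrow(ym) != n_base * (n_params + 2)) {
    stop("output rows (", nrow(ym), ") do not match N*(M+2) = ",
         n_base * (n_params + 2), call. = FALSE)
  }
  incomplete <- !stats::complete.cases(ym)
  ok <- rowSums(matrix(incomplete, nrow = n_base)) == 0
  if (!all(ok)) {
    keep_rows <- rep(ok, times = n_params + 2)
    ym <- ym[keep_rows, , drop = FALSE]
    n_base <- sum(ok)
  }
  bl <- .split_blocks(ym, n_base, n_params)
  # center on the pooled mean: leaves the estimators' expectations unchanged
  # but avoids catastrophic cancellation for outputs with small coefficients
  # of variation
  mu <- colMeans(rbind(bl$A, bl$B))
  ym <- sweep(ym, 2, mu)
  bl <- .split_blocks(ym, n_base, n_params)
  pooled <- rbind(bl$A, bl$B)
  var_y <- apply(pooled, 2, stats::var)
  if (any(var_y == 0)) {
    stop("degenerate output with zero variance: ",
         paste(colnames(ym)[var_y == 0], collapse = ", "), call. = FALSE)
  }
  K <- ncol(ym)
  s1 <- matrix(NA_real_, n_params, K)
  st <- matrix(NA_real_, n_params, K)
  for (i in seq_len(n_params)) {
    s1[i, ] <- colMeans(bl$B * (bl$AB[[i]] - bl$A)) / var_y
    st[i, ] <- colMeans((bl$A - bl$AB[[i]])^2) / (2 * var_y)
  }
  dn <- list(input_names %||% paste0("x", seq_len(n_params)),
             output_names %||% colnames(ym) %||% paste0("y", seq_len(K)))
  dimnames(s1) <- dn
  dimnames(st) <- dn
  out <- list(s1 = s1, st = st, var_y = var_y, n_base = n_base,
              n_params = n_params, y = ym)
  class(out) <- "pao_sobol"
  out
}

#' @export
print.pao_sobol <- function(x, ...) {
  cat(sprintf("<pao_sobol> %d inputs x %d outputs, N = %d%s\n",
              x$n_params, ncol(x$s1), x$n_base,
              if (!is.null(x$s1_ci)) sprintf(", %g%% bootstrap CIs",
                                             100 * x$conf_level) else ""))
  invisible(x)
}

#' Bootstrap confidence intervals for Sobol indices
#'
#' Resamples the base-sample indices with replacement -- keeping every
#' `(A, B, A_B^i)` tuple intact -- recomputes both estimators per resample
#' and returns percentile confidence-interval half-widths.  Deterministic
#' under a fixed seed.
#'
#' @param sobol A `pao_sobol` object from [sobol_indices()].
#' @param n_boot Number of bootstrap resamples (at least 100; fewer raises
#'   a warning).
#' @param conf Confidence level in (0, 1).
#' @param seed Integer seed for the resampling.
#' @return The `pao_sobol` object with `s1_ci` and `st_ci` (`M x K`
#'   half-width matrices), `n_boot` and `conf_level` added.
#' @export
bootstrap_ci <- function(sobol, n_boot = 1000, conf = 0.95, seed = 1L) {
  stopifnot(inherits(sobol, "pao_sobol"))
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals",
                            call. = FALSE)
  if (!(conf > 0 && conf < 1)) stop("conf must be in (0, 1)", call. = FALSE)
  N <- sobol$n_base
  if (N < 32) stop("need at least 32 base samples", call. = FALSE)
  M <- sobol$n_params
  K <- ncol(sobol$s1)
  bl <- .split_blocks(sobol$y, N, M)
  # per-tuple estimator terms, flattened to N x (M*K)
  P1 <- matrix(NA_real_, N, M * K)
  PT <- matrix(NA_real_, N, M * K)
  for (i in seq_len(M)) {
    cols <- (i - 1) * K + seq_len(K)
    P1[, cols] <- bl$B * (bl$AB[[i]] - bl$A)
    PT[, cols] <- (bl$A - bl$AB[[i]])^2
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  W <- matrix(0, N, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(N, N, replace = TRUE)
    W[, b] <- tabulate(idx, N)
  }
  Wn <- W / N
  # pooled-variance pieces per resample (A and B carry the same weights)
  sum_y  <- crossprod(Wn, bl$A + bl$B)            # n_boot x K
  sum_y2 <- crossprod(Wn, bl$A^2 + bl$B^2)
  mu <- sum_y / 2
  v <- (sum_y2 / 2 - mu^2) * (2 * N) / (2 * N - 1)
  m1 <- crossprod(Wn, P1)                          # n_boot x (M*K)
  mt <- crossprod(Wn, PT)
  vrep <- v[, rep(seq_len(K), times = M), drop = FALSE]
  S1b <- m1 / vrep
  STb <- mt / (2 * vrep)
  alpha <- (1 - conf) / 2
  hw <- function(B) {
    q <- apply(B, 2, stats::quantile, probs = c(alpha, 1 - alpha),
               names = FALSE)
    matrix((q[2, ] - q[1, ]) / 2, nrow = M, ncol = K, byrow = TRUE,
           dimnames = dimnames(sobol$s1))
  }
  sobol$s1_ci <- hw(S1b)
  sobol$st_ci <- hw(STb)
  sobol$n_boot <- n_boot
  sobol$conf_level <- conf
  sobol
}

#' Normalize total-order indices and rank parameters
#'
#' Clamps negative estimates at zero, rescales each output's total-order
#' indices to sum to one, and ranks parameters per output (and within each
#' parameter group) by descending total-order index.  Entries below the
#' display cut-offs are flagged rather than removed, so full tables can
#' still be exported.
#'
#' @param sobol A `pao_sobol` object.
#' @param groups Character vector of group labels, one per input (e.g. the
#'   `group` column of the parameter database).
#' @param cutoffs Named numeric display cut-offs, `first` (default 0.05)
#'   and `total` (default 0.3).
#' @return Object of class `pao_ranking`: a tibble with one row per
#'   input-output pair: `output`, `parameter`, `group`, `s1`, `st`,
#'   `st_normalized`, `rank`, `rank_in_group`, `display_first`,
#'   `display_total`.
#' @export
normalize_and_rank <- function(sobol, groups = NULL,
                               cutoffs = c(first = 0.05, total = 0.3)) {
  stopifnot(inherits(sobol, "pao_sobol"))
  M <- sobol$n_params
  groups <- groups %||% rep("all", M)
  stopifnot(length(groups) == M)
  st0 <- pmax(sobol$st, 0)
  s10 <- sobol$s1
  sums <- colSums(st0)
  if (any(sums == 0)) {
    stop("all-zero total-order column: ",
         paste(colnames(st0)[sums == 0], collapse = ", "), call. = FALSE)
  }
  st_norm <- sweep(st0, 2, sums, "/")
  long <- tidyr::expand_grid(
    output = factor(colnames(st0), levels = colnames(st0)),
    parameter = factor(rownames(st0), levels = rownames(st0))
  )
  ord_in <- match(long$parameter, rownames(st0))
  ord_out <- match(long$output, colnames(st0))
  long$group <- groups[ord_in]
  long$s1 <- s10[cbind(ord_in, ord_out)]
  long$st <- st0[cbind(ord_in, ord_out)]
  long$st_normalized <- st_norm[cbind(ord_in, ord_out)]
  long <- long |>
    dplyr::group_by(.data$output) |>
    # ties broken by database column order, which expand_grid preserves
    dplyr::mutate(rank = rank(-.data$st, ties.method = "first")) |>
    dplyr::group_by(.data$output, .data$group) |>
    dplyr::mutate(rank_in_group = rank(-.data$st, ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      display_first = .data$s1 >= cutoffs[["first"]],
      display_total = .data$st >= cutoffs[["total"]]
    )
  class(long) <- c("pao_ranking", class(long))
  attr(long, "cutoffs") <- cutoffs
  long
}
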