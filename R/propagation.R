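# Monte Carlo propagation: evaluate the cycle model over every sampled
# parameter vector, reduce trajectories to cycle means, summarize output
# distributions.

#' Propagate a parameter matrix through the cycle model
#'
#' Runs one 5-hour cycle simulation per row of a physical parameter matrix
#' and reduces each trajectory to its cycle-mean vector.  Results are
#' deterministic for a fixed matrix and independent of evaluation order and
#' of the number of workers.  Individual simulation failures are recorded,
#' not raised; more than 1 % failed rows aborts with an error since that
#' signals a mis-specified parameter range.
#'
#' @param pm A `parameter_matrix` from [transform_design()] (or a plain
#'   matrix with database column names plus a `derived` attribute-compatible
#'   layout).
#' @param model A `pao_model`.
#' @param workers Number of forked workers (1 = sequential).  Any value
#'   yields bitwise-identical results.
#' @param grid_points Output grid size per trajectory (default from model).
#' @param keep_trajectories Keep the full time-resolved output tensor
#'   (`T` times x `K` outputs x `N` samples)?  Off by default; cycle means
#'   are always kept.
#' @return An object of class `pao_outputs`: list with `cycle_means`
#'   (`K x N` matrix), `output_names`, `time_grid`, `tensor` (array or
#'   `NULL`), `failed` (tibble of row indices and reasons), `block` (design
#'   block labels, if the matrix came from a Saltelli design) and `n_base`.
#' @export
run_batch <- function(pm, model = pao_model(), workers = 1,
                      grid_points = NULL, keep_trajectories = FALSE) {
  stopifnot(inherits(pm, "parameter_matrix"))
  X <- pm$values
  D <- pm$derived
  if (is.null(D)) {
    stop("parameter matrix lacks derived influent concentrations",
         call. = FALSE)
  }
  n <- nrow(X)
  n_t <- grid_points %||% model$numerics$grid_points
  comp <- model_components()
  derived_m <- as.matrix(D)
  one <- function(i) {
    row <- c(X[i, ], derived_m[i, ])
    tryCatch({
      rp <- resolve_parameters(row, model)
      m <- .simulate_cycle_matrix(rp$init, rp$parms, model, n_t)
      list(ok = TRUE, states = m[, comp, drop = FALSE])
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  }
  res <- if (workers > 1) {
    parallel::mclapply(seq_len(n), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n), one)
  }
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  failed <- tibble::tibble(
    row = which(!ok),
    reason = vapply(res[!ok], function(r) r$msg, character(1))
  )
  if (nrow(failed) > n / 100) {
    stop("more than 1% of simulations failed (", nrow(failed), " of ", n,
         "); first reason: ", failed$reason[1], call. = FALSE)
  }
  times <- seq(0, model$numerics$cycle_hours, length.out = n_t)
  cm <- matrix(NA_real_, nrow = length(comp), ncol = n,
               dimnames = list(comp, NULL))
  w <- .trapezoid_weights(times)
  for (i in which(ok)) {
    cm[, i] <- as.numeric(crossprod(res[[i]]$states, w))
  }
  tensor <- NULL
  if (keep_trajectories) {
    tensor <- array(NA_real_, dim = c(n_t, length(comp), n),
                    dimnames = list(NULL, comp, NULL))
    for (i in which(ok)) tensor[, , i] <- res[[i]]$states
  }
  out <- list(
    cycle_means = cm, output_names = comp, time_grid = times,
    tensor = tensor, failed = failed,
    block = pm$block, n_base = pm$n_base
  )
  class(out) <- "pao_outputs"
  out
}

#' @export
print.pao_outputs <- function(x, ...) {
  cat(sprintf(
    "<pao_outputs> %d outputs x %d samples (%d failed)%s\n",
    nrow(x$cycle_means), ncol(x$cycle_means), nrow(x$failed),
    if (!is.null(x$tensor)) sprintf(", tensor %s", paste(dim(x$tensor),
                                                         collapse = "x"))
    else ""
  ))
  invisible(x)
}

# composite trapezoid weights on an increasing grid, normalized to average
.trapezoid_weights <- function(times) {
  stopifnot(all(diff(times) > 0))
  h <- diff(times)
  w <- c(h / 2, 0) + c(0, h / 2)
  w / (times[length(times)] - times[1])
}

#' Cycle-mean reduction of a trajectory
#'
#' Trapezoidal time-average of every component over the cycle, the scalar
#' reduction required by the sensitivity estimators.
#'
#' @param trajectory A `pao_trajectory` tibble ([simulate_cycle()]) or a
#'   numeric matrix with a `time` column.
#' @return Named vector of time-averaged values (all non-time columns).
#' @examples
#' tr <- tibble::tibble(time = seq(0, 5, length.out = 11),
#'                      ramp = seq(0, 1, length.out = 11))
#' cycle_mean(tr)
#' @export
cycle_mean <- function(trajectory) {
  df <- as.data.frame(trajectory)
  if (!"time" %in% names(df)) stop("trajectory lacks a time column",
                                   call. = FALSE)
  times <- df$time
  num <- vapply(df, is.numeric, logical(1))
  vals <- as.matrix(df[num & names(df) != "time"])
  w <- .trapezoid_weights(times)
  stats::setNames(as.numeric(crossprod(vals, w)), colnames(vals))
}

#' Summarize cycle-mean output distributions
#'
#' Per-output mean and variance over samples plus normalized histograms
#' (bin fractions summing to one).
#'
#' @param outputs A `pao_outputs` object or a `K x N` cycle-mean matrix.
#' @param bins Number of histogram bins.
#' @return List with `moments` (tibble: output, mu, var) and `histogram`
#'   (tibble: output, midpoint, fraction).
#' @export
summarize_outputs <- function(outputs, bins = 30) {
  cm <- if (inherits(outputs, "pao_outputs")) outputs$cycle_means
        else as.matrix(outputs)
  keep <- colSums(is.na(cm)) == 0
  cm <- cm[, keep, drop = FALSE]
  if (ncol(cm) < 2) stop("need at least 2 non-failed samples", call. = FALSE)
  moments <- tibble::tibble(
    output = rownames(cm),
    mu = unname(rowMeans(cm)),
    var = unname(apply(cm, 1, stats::var))
  )
  histogram <- purrr::map_dfr(seq_len(nrow(cm)), function(k) {
    x <- cm[k, ]
    if (min(x) == max(x)) {
      return(tibble::tibble(output = rownames(cm)[k], midpoint = x[1],
                            fraction = 1))
    }
    h <- graphics::hist(x, breaks = bins, plot = FALSE)
    tibble::tibble(output = rownames(cm)[k], midpoint = h$mids,
                   fraction = h$counts / sum(h$counts))
  })
  list(moments = moments, histogram = histogram)
}
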