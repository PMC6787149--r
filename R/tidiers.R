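# broom-style tidiers and ggplot2 visualisations for the result objects.

#' Tidy a standardized-regression result
#'
#' @param x A `pao_src` object.
#' @param ... Unused.
#' @return Tibble with one row per input-output pair: `output`, `parameter`,
#'   `beta`, `b`.
#' @export
tidy.pao_src <- function(x, ...) {
  tibble::tibble(
    output = rep(colnames(x$beta), each = nrow(x$beta)),
    parameter = rep(rownames(x$beta), times = ncol(x$beta)),
    beta = as.numeric(x$beta),
    b = as.numeric(x$raw_b)
  )
}

#' Per-output regression diagnostics
#'
#' @param x A `pao_src` object.
#' @param ... Unused.
#' @return Tibble with `output`, `r_squared`, `linear` (the `R^2 >= 0.7`
#'   verdict), `sum_beta_sq` and `n`.
#' @export
glance.pao_src <- function(x, ...) {
  tibble::tibble(
    output = names(x$r_squared),
    r_squared = unname(x$r_squared),
    linear = unname(x$linear),
    sum_beta_sq = unname(colSums(x$beta^2)),
    n = x$n
  )
}

#' Tidy a Sobol-index result
#'
#' @param x A `pao_sobol` object.
#' @param ... Unused.
#' @return Tibble with one row per input-output pair: `output`, `parameter`,
#'   `s1`, `st` and, when [bootstrap_ci()] has been run, `s1_ci`, `st_ci`.
#' @export
tidy.pao_sobol <- function(x, ...) {
  out <- tibble::tibble(
    output = rep(colnames(x$s1), each = nrow(x$s1)),
    parameter = rep(rownames(x$s1), times = ncol(x$s1)),
    s1 = as.numeric(x$s1),
    st = as.numeric(x$st)
  )
  if (!is.null(x$s1_ci)) {
    out$s1_ci <- as.numeric(x$s1_ci)
    out$st_ci <- as.numeric(x$st_ci)
  }
  out
}

#' Per-output Sobol summary
#'
#' @param x A `pao_sobol` object.
#' @param ... Unused.
#' @return Tibble with `output`, `var_y`, `sum_s1`, `max_s1`, `max_st`,
#'   `n_base`.
#' @export
glance.pao_sobol <- function(x, ...) {
  tibble::tibble(
    output = colnames(x$s1),
    var_y = unname(x$var_y),
    sum_s1 = unname(colSums(x$s1)),
    max_s1 = unname(apply(x$s1, 2, max)),
    max_st = unname(apply(x$st, 2, max)),
    n_base = x$n_base
  )
}

#' Heatmap of Sobol sensitivity indices
#'
#' Mirrors the conventional presentation: outputs as rows, inputs as
#' columns, tiles coloured by index value, entries below the display
#' cut-off blanked.
#'
#' @param object A `pao_sobol` object.
#' @param which `"s1"` or `"st"`.
#' @param cutoff Minimum index value to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pao_sobol <- function(object, which = c("st", "s1"),
                               cutoff = 0.05, ...) {
  which <- match.arg(which)
  df <- tidy(object)
  df$value <- df[[which]]
  df$value[df$value < cutoff] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$parameter, levels = rownames(object$s1)),
    y = factor(.data$output, levels = rev(colnames(object$s1))),
    fill = .data$value
  )) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = toupper(which)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Heatmap of standardized regression coefficients
#'
#' @param object A `pao_src` object.
#' @param cutoff Minimum `|beta|` to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pao_src <- function(object, cutoff = 0.05, ...) {
  df <- tidy(object)
  df$value <- df$beta
  df$value[abs(df$value) < cutoff] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$parameter, levels = rownames(object$beta)),
    y = factor(.data$output, levels = rev(colnames(object$beta))),
    fill = .data$value
  )) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(na.value = "white", name = "beta") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Group-wise heatmaps of normalized total effects
#'
#' @param object A `pao_ranking` from [normalize_and_rank()].
#' @param ... Unused.
#' @return A ggplot object faceted by parameter group.
#' @export
autoplot.pao_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$parameter, y = .data$output, fill = .data$st_normalized
  )) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(name = "normalized ST") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot the spread of simulated trajectories
#'
#' @param object A `pao_trajectory` from [simulate_cycle()].
#' @param components Components to show (default all ten).
#' @param ... Unused.
#' @return A ggplot object with one panel per component and the phase
#'   switch marked.
#' @export
autoplot.pao_trajectory <- function(object, components = model_components(),
                                    ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "time", dplyr::all_of(components)),
    -"time", names_to = "component", values_to = "concentration"
  )
  df$component <- factor(df$component, levels = components)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 2.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (C- or P-mmol/l)") +
    ggplot2::theme_minimal()
}
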