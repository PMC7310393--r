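#' Tidy a Monte Carlo EM REML fit
#'
#' @param x An `mcem_reml_fit`.
#' @param what `"variance"` for one row per variance component,
#'   `"correlation"` for one row per genetic correlation.
#' @param se Optional [approximate_se()] object; adds a `std.error`
#'   column.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (and `std.error`).
#' @export
tidy.mcem_reml_fit <- function(x, what = c("variance", "correlation"),
                               se = NULL, ...) {
  what <- match.arg(what)
  if (what == "variance") {
    flat <- .vc_flatten(x$vc)
    out <- tibble(term = names(flat), estimate = unname(flat))
    if (!is.null(se)) {
      out <- out %>% left_join(
        tibble(term = names(se$vc_se), std.error = unname(se$vc_se)),
        by = "term"
      )
    }
    return(out)
  }
  R <- genetic_correlations(x$vc)
  labs <- rownames(R)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  out <- tibble(
    term = paste0(labs[idx[, 1]], ":", labs[idx[, 2]]),
    estimate = R[idx]
  )
  if (!is.null(se)) out$std.error <- se$rg_se[idx]
  out
}

#' Glance at a Monte Carlo EM REML fit
#'
#' @param x An `mcem_reml_fit`.
#' @param ... Unused.
#' @return A one-row tibble: rounds run, convergence flag, worst final
#'   standardized slope, problem sizes, and positive-definiteness of the
#'   final genetic matrix.
#' @export
glance.mcem_reml_fit <- function(x, ...) {
  chk <- check_vce_convergence(x$trajectory, x$settings)
  ev <- eigen(x$vc$genetic, symmetric = TRUE, only.values = TRUE)$values
  tibble(
    rounds = x$rounds_run,
    converged = x$converged,
    worst_slope = chk$worst_slope,
    n_records = x$design$n_records,
    n_animals = x$design$n_animals,
    n_equations = x$design$n_equations,
    positive_definite = min(ev) > 0
  )
}

#' Trajectory plot of a Monte Carlo EM REML fit
#'
#' One panel per variance component, estimates against REML round; the
#' flat right-hand tail is what the slope convergence criterion measures.
#'
#' @param object An `mcem_reml_fit`.
#' @param components Optional regular expression selecting components.
#' @param ... Unused.
#' @export
autoplot.mcem_reml_fit <- function(object, components = NULL, ...) {
  tr <- object$trajectory
  if (!is.null(components)) tr <- tr %>% filter(grepl(components, .data$component))
  ggplot2::ggplot(tr, ggplot2::aes(.data$round, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "REML round", y = "estimate",
                  title = "Variance component trajectories")
}

#' Heatmap of a genetic correlation matrix
#'
#' @param object A matrix from [genetic_correlations()] (or any labelled
#'   correlation matrix).
#' @param ... Unused.
#' @export
plot_rg_matrix <- function(object, ...) {
  labs <- rownames(object)
  df <- as_tibble(as.data.frame(as.table(object))) %>%
    rlang::set_names(c("row", "col", "value")) %>%
    mutate(row = factor(.data$row, levels = rev(labs)),
           col = factor(.data$col, levels = labs))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Across-country genetic correlations") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
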