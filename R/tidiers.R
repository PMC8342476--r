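#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an optimization result
#'
#' One row per decision variable: the three nitrogen fractions, the LET
#' proportion and the five energy fractions.
#'
#' @param x a `photo_optim` object.
#' @param ... unused.
#' @return A tibble with columns `term`, `kind`, `estimate`.
#' @export
tidy.photo_optim <- function(x, ...) {
  tibble::tibble(
    term = c("n_Etot", "n_C4", "n_Jmax", "p",
             "f_cb_m", "f_pr_m", "f_cb_s", "f_pr_s", "f_c4"),
    kind = c(rep("nitrogen", 3), "let_proportion", rep("energy", 5)),
    estimate = c(x$alloc$n_Etot, x$alloc$n_C4, x$alloc$n_Jmax, x$alloc$p,
                 x$partition$f_cb_m, x$partition$f_pr_m, x$partition$f_cb_s,
                 x$partition$f_pr_s, x$partition$f_c4))
}

#' Summarize an optimization result in one row
#'
#' @param x a `photo_optim` object.
#' @param ... unused.
#' @return A one-row tibble with `A_star`, `converged`, `n_restarts_used`,
#'   `best_start`, `constraint_violation`.
#' @export
glance.photo_optim <- function(x, ...) {
  tibble::tibble(A_star = x$A_star, converged = x$converged,
                 n_restarts_used = x$n_restarts_used,
                 best_start = x$best_start %||% NA_integer_,
                 constraint_violation = x$constraint_violation)
}

#' Tidy an assimilation result
#'
#' @param x a `photo_assim` object.
#' @param ... unused.
#' @return A one-row tibble with the realized rate, its components and the
#'   binding limitation.
#' @export
tidy.photo_assim <- function(x, ...) {
  tibble::tibble(A = x$A, A_j_ATP = x$A_j_ATP, A_j_NADPH = x$A_j_NADPH,
                 A_j = x$A_j, A_c = x$A_c, limiting = x$limiting)
}

#' Tidy a nitrogen re-allocation result
#'
#' @param x a `photo_delta_n` object.
#' @param ... unused.
#' @return A tibble with one row per nitrogen pool plus the total.
#' @export
tidy.photo_delta_n <- function(x, ...) {
  tibble::tibble(pool = c(names(x$per_pool), "total"),
                 reallocation = c(unname(x$per_pool), x$delta_n))
}

#' Plot an environment-scan error surface
#'
#' Heatmap of the mean normalized squared residual over mesophyll CO2 and
#' irradiance, faceted by temperature; the best-fitting environment is
#' circled.
#'
#' @param object a `photo_scan` from [environment_scan()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.photo_scan <- function(object, ...) {
  surface <- object$surface
  ggplot2::ggplot(surface, ggplot2::aes(x = .data$C_m, y = .data$I,
                                        fill = log10(.data$error))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$argmin, shape = 21, size = 4,
                        fill = NA, colour = "black", stroke = 1.2) +
    ggplot2::facet_wrap(~T_leaf, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "log10 error") +
    ggplot2::labs(x = "mesophyll CO2 (ubar)",
                  y = "irradiance (umol quanta m-2 s-1)")
}

#' Plot simulated response curves
#'
#' Line plot of assimilation against the swept variable for one or more
#' response-curve tables (see [response_curves()]).
#'
#' @param data a measurement table with quantity `"A"`; multiple curves are
#'   distinguished by `curve_id`.
#' @return A ggplot object.
#' @export
plot_response_curves <- function(data) {
  data <- measurement_table(data)
  data <- data[data$quantity == "A", ]
  xlab <- switch(unique(data$x_kind)[1],
                 Ci = "intercellular CO2 (ubar)",
                 T = "leaf temperature (C)",
                 N = "leaf nitrogen (mmol m-2)", "x")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$x_value, y = .data$value,
                                     colour = .data$curve_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = xlab, y = "net CO2 assimilation (umol m-2 s-1)",
                  colour = NULL)
}

#' @importFrom rlang .data
NULL
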