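#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an amplitude summary
#'
#' @param x A \code{dam_amplitudes} object.
#' @param ... Unused.
#' @return A plain tibble with one row per pool.
#' @export
tidy.dam_amplitudes <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a sweep result
#'
#' Unnests the per-grid-value amplitude summaries into a long table.
#'
#' @param x A \code{dam_sweep} object.
#' @param ... Unused.
#' @return A tibble with one row per (grid value, pool).
#' @export
tidy.dam_sweep <- function(x, ...) {
  kept <- dplyr::filter(tibble::as_tibble(x), !purrr::map_lgl(
    .data$amplitudes, is.null))
  tidyr::unnest(
    dplyr::select(kept, "param", "value", "periodic", "amplitudes"),
    "amplitudes"
  )
}

#' One-row summary of a trajectory
#'
#' @param x A \code{dam_trajectory}.
#' @param ... Unused.
#' @return A tibble with the grid size, span, conserved total and the
#'   maximum conservation drift.
#' @export
glance.dam_trajectory <- function(x, ...) {
  total <- x$p1 + x$p2 + x$p3
  tibble::tibble(
    n = nrow(x),
    t_end = max(x$t),
    n_periods = attr(x, "n_periods"),
    extended = isTRUE(attr(x, "extended")),
    total_carbon = total[1],
    max_drift = max(abs(total - total[1]))
  )
}

#' Plot pool and flux dynamics
#'
#' Faceted time-course of the four pools, the driver signals and the five
#' fluxes, optionally restricted to the final forcing period.
#'
#' @param object A \code{dam_trajectory}.
#' @param what Which series groups to show; any of \code{"pools"},
#'   \code{"drivers"}, \code{"fluxes"}.
#' @param last_period Restrict to the final period (default FALSE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dam_trajectory <- function(object,
                                    what = c("pools", "drivers", "fluxes"),
                                    last_period = FALSE, ...) {
  what <- match.arg(what, several.ok = TRUE)
  groups <- list(
    pools = c("p0", "p1", "p2", "p3"),
    drivers = c("ca", "atp", "nadh"),
    fluxes = c("j01", "j12", "j13", "j32")
  )[what]
  df <- tibble::as_tibble(object)
  if (last_period) {
    T0 <- attr(object, "driver_params")$T0
    df <- final_period(df |> `attr<-`("driver_params", NULL), T0 = T0)
  }
  long <- tidyr::pivot_longer(df, cols = unlist(groups, use.names = FALSE),
                              names_to = "series", values_to = "level")
  long$group <- NA_character_
  for (g in names(groups)) long$group[long$series %in% groups[[g]]] <- g
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$level,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (periods)", y = "level (dimensionless)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sweep result
#'
#' Final-period amplitude of each pool against the swept quantity.
#'
#' @param object A \code{dam_sweep}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dam_sweep <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$amplitude,
                                     colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "param"), y = "amplitude (max - min)",
                  colour = "pool") +
    ggplot2::theme_minimal()
}

#' @export
print.dam_amplitudes <- function(x, ...) {
  cat("Final-period oscillation amplitudes (T0 =", attr(x, "T0"), ")\n")
  NextMethod()
}
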