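#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into long form
#'
#' @param x An `atn_trajectory`.
#' @param ... Unused.
#' @return Tibble `t_hours, node_id, biomass_g_m2`, one row per node per
#'   output time.
#' @export
tidy.atn_trajectory <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$biomass)) |>
    dplyr::mutate(t_hours = x$times, .before = 1) |>
    tidyr::pivot_longer(-"t_hours", names_to = "node_id",
                        values_to = "biomass_g_m2")
}

#' One-row trajectory summary
#'
#' @param x An `atn_trajectory`.
#' @param ... Unused.
#' @return Tibble with the node count, time span, extirpation count, and
#'   initial/final community biomass.
#' @export
glance.atn_trajectory <- function(x, ...) {
  tibble::tibble(
    n_nodes = ncol(x$biomass),
    n_samples = length(x$times),
    span_hours = max(x$times) - min(x$times),
    n_extirpated = nrow(x$extirpations),
    total_biomass_start = sum(x$biomass[1, ]),
    total_biomass_end = sum(x$biomass[nrow(x$biomass), ]),
    k_mixing = x$k_mixing,
    phase = x$phase
  )
}

#' Tidy a food web into an edge table
#'
#' @param x An `atn_foodweb`.
#' @param ... Unused.
#' @return The link tibble augmented with each endpoint's role.
#' @export
tidy.atn_foodweb <- function(x, ...) {
  roles <- stats::setNames(x$nodes$role, x$nodes$node_id)
  x$links |>
    dplyr::mutate(consumer_role = unname(roles[.data$consumer_id]),
                  resource_role = unname(roles[.data$resource_id]))
}

#' One-row food web summary
#'
#' @param x An `atn_foodweb`.
#' @param ... Unused.
#' @return Tibble with node, link, producer and consumer counts plus the
#'   realized connectance links/nodes^2 over dynamic nodes.
#' @export
glance.atn_foodweb <- function(x, ...) {
  n_dyn <- sum(x$nodes$is_dynamic)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_dynamic = n_dyn,
    n_links = nrow(x$links),
    n_producers = sum(x$nodes$is_producer & x$nodes$is_dynamic),
    n_consumers = sum(x$nodes$role == "consumer"),
    connectance = nrow(x$links) / n_dyn^2,
    split = !is.null(x$op_id)
  )
}

#' Plot a trajectory
#'
#' Biomass of every dynamic node over time on a log10 scale, coloured by
#' guild when a guild table is supplied.
#'
#' @param object An `atn_trajectory`.
#' @param guilds Optional tibble `node_id, guild` from [assign_guilds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.atn_trajectory <- function(object, guilds = NULL, ...) {
  long <- tidy(object)
  p <- if (is.null(guilds)) {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$t_hours / 24,
                                       y = .data$biomass_g_m2,
                                       group = .data$node_id))
  } else {
    ggplot2::ggplot(dplyr::left_join(long, guilds, by = "node_id"),
                    ggplot2::aes(x = .data$t_hours / 24,
                                 y = .data$biomass_g_m2,
                                 group = .data$node_id,
                                 colour = .data$guild))
  }
  p + ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "biomass (g/m2)")
}

#' Plot a forcing function
#'
#' The continuous forcing evaluated on a 6-hour grid with the daily samples
#' overlaid.
#'
#' @param object An `atn_forcing`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.atn_forcing <- function(object, ...) {
  grid <- tibble::tibble(t_hours = seq(object$t_min, object$t_max, by = 6))
  grid$B_op <- evaluate_forcing(object, grid$t_hours)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t_hours / 24,
                                     y = .data$B_op)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$knots,
                        ggplot2::aes(x = .data$t_hours / 24,
                                     y = .data$biomass_g_m2),
                        size = 0.4, colour = "steelblue") +
    ggplot2::labs(x = "time (days)",
                  y = "offshore phytoplankton (g/m2)")
}

#' Plot a normalized-CV report
#'
#' Jittered per-species normalized CVs by guild (the tabular counterpart of
#' a violin plot), restricted to the five consumerguilds plus algae.
#'
#' @param object A `cv_report` from [normalized_cv_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  keep <- object[object$guild %in% c("algae", "filter_feeder", "herbivore",
                                     "omnivore", "carnivore") &
                   !is.na(object$cv_norm), ]
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$guild, y = .data$cv_norm)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3,
                          colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "CV normalized to offshore phytoplankton")
}
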