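#' Build the allometric parameter set for a food web
#'
#' Populates every rate and shape constant of the bioenergetic model from
#' body masses and the configuration: producer intrinsic growth rates `r_i`
#' and consumer metabolic rates `x_i` as power laws of body mass, maximum
#' consumption rates `y_ij`, assimilation efficiencies `e_ij` (plant vs
#' animal resource), uniform preferences `omega_ij`, half-saturation `B0`,
#' interference `d`, the Holling exponent `q`, and the community carrying
#' capacity `K`.
#'
#' @param web An `atn_foodweb` (split or unsplit).
#' @param config An `atn_config`, see [atn_default_config()].
#' @param K Community-level carrying capacity (g/m2) shared by all producers;
#'   see [estimate_carrying_capacity()]. Required here because it is a
#'   property of the community, not of any single species.
#'
#' @return An object of class `atn_params`: list with
#'   \describe{
#'     \item{rates}{tibble `node_id, role, body_mass_g, r, x` (per-day on
#'       construction; `r`/`x` are NA where not applicable).}
#'     \item{link_params}{tibble `consumer_id, resource_id, y, e, omega`.}
#'     \item{B0, d}{named vectors per consumer.}
#'     \item{q, K, f_a, f_m}{scalars.}
#'     \item{units}{`"per_day"` until [convert_daily_to_hourly()] is applied.}
#'   }
#' @export
build_parameters <- function(web, config = atn_default_config(), K) {
  stopifnot(inherits(web, "atn_foodweb"))
  if (missing(K) || !is.numeric(K) || K <= 0) {
    stop("a positive carrying capacity K (g/m2) is required", call. = FALSE)
  }
  al <- config$allometry
  ef <- config$efficiencies
  fr <- config$functional_response

  nodes <- web$nodes
  dyn <- nodes[nodes$is_dynamic, ]
  if (any(!is.finite(dyn$body_mass_g))) {
    stop("missing body mass for node(s): ",
         paste(dyn$node_id[!is.finite(dyn$body_mass_g)], collapse = ", "),
         call. = FALSE)
  }
  rel_mass <- dyn$body_mass_g / al$reference_mass_g
  r <- ifelse(dyn$is_producer, al$a_r * rel_mass^al$mass_exponent, NA_real_)
  x <- ifelse(dyn$role == "consumer", al$a_x * rel_mass^al$mass_exponent,
              NA_real_)
  rates <- tibble::tibble(
    node_id = dyn$node_id, role = dyn$role,
    body_mass_g = dyn$body_mass_g, r = r, x = x
  )

  links <- web$links
  res_producer <- nodes$is_producer[match(links$resource_id, nodes$node_id)]
  res_baseline <- !is.null(web$baseline_id) &
    links$resource_id == (web$baseline_id %||% "")
  e <- ifelse(res_producer | res_baseline, ef$e_plant, ef$e_animal)
  link_params <- links |>
    dplyr::mutate(y = al$y, e = e) |>
    dplyr::group_by(.data$consumer_id) |>
    dplyr::mutate(omega = 1 / dplyr::n()) |>
    dplyr::ungroup()

  consumers <- unique(links$consumer_id)
  B0 <- stats::setNames(rep(fr$B0, length(consumers)), consumers)
  d <- stats::setNames(rep(fr$d, length(consumers)), consumers)

  params <- structure(
    list(rates = rates, link_params = link_params, B0 = B0, d = d,
         q = fr$q, K = K,
         f_a = config$scenario$f_a, f_m = config$scenario$f_m,
         units = "per_day"),
    class = "atn_params"
  )
  validate_params(params)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
validate_params <- function(p) {
  stopifnot(p$q > 0, p$K > 0, all(p$B0 > 0), all(p$d >= 0))
  lp <- p$link_params
  if (any(lp$e <= 0 | lp$e > 1)) {
    stop("assimilation efficiencies must lie in (0, 1]", call. = FALSE)
  }
  if (any(lp$y < 0)) stop("negative consumption rate", call. = FALSE)
  osum <- tapply(lp$omega, lp$consumer_id, sum)
  if (any(abs(osum - 1) > 1e-10)) {
    stop("preferences do not sum to 1 for consumer(s): ",
         paste(names(osum)[abs(osum - 1) > 1e-10], collapse = ", "),
         call. = FALSE)
  }
  r <- p$rates$r[!is.na(p$rates$r)]
  x <- p$rates$x[!is.na(p$rates$x)]
  if (any(r < 0) || any(x < 0)) stop("negative rate", call. = FALSE)
  invisible(p)
}

#' @export
print.atn_params <- function(x, ...) {
  cat("<atn_params> [", x$units, "] ", nrow(x$rates), " nodes, ",
      nrow(x$link_params), " links; q = ", x$q, ", K = ", format(x$K),
      " g/m2\n", sep = "")
  invisible(x)
}

#' Convert a per-day parameter set to per-hour rates
#'
#' The simulation clock runs in hours, so the dimensioned rates (`r_i`,
#' `x_i`) are divided by 24. Dimensionless quantities (`y`, `e`, `omega`,
#' `q`, `d`) and densities (`B0`, `K`) are untouched. Converting a set that
#' is already per-hour is an error, to catch accidental double conversion.
#'
#' @param params An `atn_params` tagged `"per_day"`.
#' @return The same set tagged `"per_hour"`.
#' @export
convert_daily_to_hourly <- function(params) {
  stopifnot(inherits(params, "atn_params"))
  if (params$units != "per_day") {
    stop("parameter set is already in per-hour units", call. = FALSE)
  }
  params$rates$r <- params$rates$r / 24
  params$rates$x <- params$rates$x / 24
  params$units <- "per_hour"
  params
}

#' Estimate the community-level carrying capacity
#'
#' The shared producer carrying capacity is taken as the sum, over producer
#' functional groups, of the biomass of the fastest-growing member of each
#' group weighted by the group's species count:
#' K = sum_g n_g * B(argmax_r in g). Ties in growth rate are broken by
#' lexicographic node id so the estimate is deterministic.
#'
#' @param group_table Data frame with columns `group`, `node_id`, `biomass`
#'   (g/m2) and `growth_rate`.
#' @return K in g/m2 (scalar).
#' @export
estimate_carrying_capacity <- function(group_table) {
  gt <- tibble::as_tibble(group_table)
  req <- c("group", "node_id", "biomass", "growth_rate")
  if (!all(req %in% names(gt))) {
    stop("group table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(gt) == 0) stop("empty group table", call. = FALSE)
  if (any(is.na(gt$biomass)) || any(is.na(gt$growth_rate))) {
    stop("NA biomass or growth rate", call. = FALSE)
  }
  per_group <- gt |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(dplyr::desc(.data$growth_rate), .data$node_id,
                   .by_group = TRUE) |>
    dplyr::summarise(n = dplyr::n(),
                     top_biomass = dplyr::first(.data$biomass),
                     .groups = "drop")
  sum(per_group$n * per_group$top_biomass)
}
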