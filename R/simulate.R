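#' Scenario configuration
#'
#' Bundles the run-level knobs: mixing rate, equilibration strategy and span,
#' extinction threshold, and solver tolerances.
#'
#' @param k_mixing Pelagic-intertidal exchange rate, 1/h.
#' @param strategy Equilibration strategy: `1` runs the autonomous model
#'   (offshore node deactivated) for `equilibration_years`; `2` runs against
#'   that many appended copies of the year's forcing instead.
#' @param equilibration_years Span of the equilibration phase in 365-day
#'   years.
#' @param extinction_threshold Biomass (g/m2) below which a species is
#'   considered locally extirpated and clamped to zero.
#' @param clamp If TRUE (default), a node crossing the threshold is pinned
#'   at zero for the rest of the run; if FALSE crossings are only logged.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`,
#'   stiff-capable adaptive).
#' @param seed Optional integer seed recorded with the run.
#' @return A list with class `atn_scenario`.
#' @export
atn_scenario <- function(k_mixing = 1.0, strategy = 1,
                         equilibration_years = 10,
                         extinction_threshold = 1e-6, clamp = TRUE,
                         rtol = 1e-8, atol = 1e-10, method = "lsoda",
                         seed = NULL) {
  stopifnot(k_mixing >= 0, strategy %in% c(1, 2),
            equilibration_years >= 0, extinction_threshold > 0)
  structure(list(k_mixing = k_mixing, strategy = strategy,
                 equilibration_years = equilibration_years,
                 extinction_threshold = extinction_threshold, clamp = clamp,
                 rtol = rtol, atol = atol, method = method, seed = seed),
            class = "atn_scenario")
}

#' Default initial state for a web
#'
#' Uses the species table's `initial_biomass_g_m2` column when present;
#' otherwise producers start at 500 g/m2 and consumers at 50 g/m2.
#'
#' @param web An `atn_foodweb`.
#' @return Named biomass vector over the dynamic nodes.
#' @export
default_initial_state <- function(web) {
  nodes <- web$nodes[web$nodes$is_dynamic, ]
  if ("initial_biomass_g_m2" %in% names(nodes) &&
      all(is.finite(nodes$initial_biomass_g_m2))) {
    return(stats::setNames(as.numeric(nodes$initial_biomass_g_m2),
                           nodes$node_id))
  }
  stats::setNames(ifelse(nodes$is_producer, 500, 50), nodes$node_id)
}

# Core integrator: adaptive solve with threshold-crossing roots. Nodes that
# cross are clamped to exactly zero (except FP, which the mixing subsidy can
# legitimately revive) and the first crossing time is recorded.
integrate_atn <- function(ctx, init, times, scenario) {
  n <- ctx$n
  clampable <- rep(TRUE, n)
  if (!is.na(ctx$fp_idx)) clampable[ctx$fp_idx] <- FALSE
  env <- new.env(parent = emptyenv())
  env$events <- list()
  thr <- scenario$extinction_threshold
  # nodes already extinct on entry are pinned, not logged as new events
  init <- unname(init)
  pre_dead <- clampable & init < thr
  env$clamped <- pre_dead
  if (scenario$clamp) init[pre_dead] <- 0

  func <- function(t, y, parms) {
    list(ctx$rhs(t, y, clamped = if (scenario$clamp) env$clamped else NULL))
  }
  rootfun <- function(t, y, parms) {
    r <- y - thr
    r[!clampable | env$clamped] <- -1  # no further roots from these
    r
  }
  eventfun <- function(t, y, parms) {
    hit <- clampable & !env$clamped & y <= thr * (1 + 1e-9)
    if (any(hit)) {
      env$events <- c(env$events,
                      lapply(which(hit), function(i) list(i = i, t = t)))
      if (scenario$clamp) {
        env$clamped <- env$clamped | hit
        y[hit] <- 0
      }
    }
    y
  }
  sol <- deSolve::ode(
    y = init, times = times, func = func, parms = NULL,
    method = scenario$method, rtol = scenario$rtol, atol = scenario$atol,
    rootfunc = rootfun, events = list(func = eventfun, root = TRUE),
    maxsteps = 5e5
  )
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed (istate = ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  }
  mat <- unname(sol[, -1, drop = FALSE])
  mat[mat < 0] <- 0
  colnames(mat) <- ctx$ids
  ext <- if (length(env$events) > 0) {
    tibble::tibble(
      node_id = ctx$ids[vapply(env$events, `[[`, integer(1), "i")],
      t_hours = vapply(env$events, `[[`, numeric(1), "t")
    ) |>
      dplyr::group_by(.data$node_id) |>
      dplyr::summarise(t_hours = min(.data$t_hours), .groups = "drop")
  } else {
    tibble::tibble(node_id = character(), t_hours = numeric())
  }
  # clamped nodes are exactly zero after their crossing
  if (scenario$clamp && nrow(ext) > 0) {
    for (k in seq_len(nrow(ext))) {
      j <- match(ext$node_id[k], ctx$ids)
      mat[sol[, 1] >= ext$t_hours[k], j] <- 0
    }
  }
  list(times = sol[, 1], biomass = mat, extirpations = ext)
}

new_trajectory <- function(times, biomass, extirpations, phase, k_mixing) {
  structure(list(times = times, biomass = biomass,
                 extirpations = extirpations, phase = phase,
                 k_mixing = k_mixing),
            class = "atn_trajectory")
}

#' @export
print.atn_trajectory <- function(x, ...) {
  cat("<atn_trajectory> [", x$phase, "] ", ncol(x$biomass), " nodes x ",
      length(x$times), " samples over ", round(max(x$times)), " h; ",
      nrow(x$extirpations), " extirpation(s), k_mixing = ", x$k_mixing,
      " 1/h\n", sep = "")
  invisible(x)
}

#' Equilibrate a community before applying empirical forcing
#'
#' Moves the state near its attractor so the experimental year is not
#' dominated by arbitrary initial conditions. Strategy 1 deactivates the
#' offshore node (no mixing) and integrates the autonomous system for the
#' configured number of years; strategy 2 integrates against the year's
#' forcing repeated periodically for the same span.
#'
#' @param web A split `atn_foodweb` (unsplit webs are allowed for strategy 1).
#' @param params An `atn_params` in per-hour units.
#' @param scenario An [atn_scenario()].
#' @param init Named initial biomass vector; defaults to
#'   [default_initial_state()].
#' @param forcing Required for strategy 2: the year's `atn_forcing`.
#' @return Named end-state biomass vector over the dynamic nodes.
#' @export
equilibrate <- function(web, params, scenario = atn_scenario(),
                        init = default_initial_state(web), forcing = NULL) {
  span_h <- scenario$equilibration_years * 365 * 24
  nodes <- web$nodes[web$nodes$is_dynamic, ]
  init <- init[nodes$node_id]
  if (any(is.na(init))) stop("initial state incomplete", call. = FALSE)
  if (span_h == 0) return(init)
  if (scenario$strategy == 1) {
    ctx <- build_sim_context(web, params, forcing = NULL, k_mixing = 0)
  } else {
    if (is.null(forcing)) {
      stop("strategy 2 needs the year's forcing", call. = FALSE)
    }
    ctx <- build_sim_context(web, params, forcing = forcing,
                             k_mixing = scenario$k_mixing,
                             periodic_hours = 365 * 24)
  }
  times <- seq(0, span_h, length.out = 201)
  out <- integrate_atn(ctx, init, times, scenario)
  stats::setNames(out$biomass[nrow(out$biomass), ], ctx$ids)
}

#' Simulate one experimental year under empirical forcing
#'
#' Integrates the forced system over the forcing's window, sampling hourly.
#' Species whose biomass crosses the extinction threshold are clamped to
#' zero (they cannot recover without external input) and logged with their
#' first crossing time.
#'
#' @inheritParams equilibrate
#' @param forcing The year's `atn_forcing`.
#' @param init Named initial biomass vector (typically from [equilibrate()]).
#' @return An `atn_trajectory`.
#' @export
run_year <- function(web, params, forcing, init, scenario = atn_scenario()) {
  stopifnot(inherits(forcing, "atn_forcing"))
  nodes <- web$nodes[web$nodes$is_dynamic, ]
  init <- init[nodes$node_id]
  if (any(is.na(init))) stop("initial state incomplete", call. = FALSE)
  ctx <- build_sim_context(web, params, forcing = forcing,
                           k_mixing = scenario$k_mixing)
  times <- seq(0, forcing$t_max, by = 1)
  out <- integrate_atn(ctx, init, times, scenario)
  new_trajectory(out$times, out$biomass, out$extirpations,
                 phase = "experimental", k_mixing = scenario$k_mixing)
}

#' Scan mixing rates across years
#'
#' Runs the full equilibrate-then-simulate protocol for every combination of
#' forcing year and mixing rate, recording which species were extirpated.
#' The equilibrated initial state is shared across mixing rates under
#' strategy 1 (the equilibration is autonomous, so it does not depend on k).
#'
#' @inheritParams equilibrate
#' @param forcing_by_year Named list of `atn_forcing`, one per year label.
#' @param k_grid Mixing rates to scan, 1/h (default the standard grid
#'   0.1, 1, 10).
#' @return A tibble with one row per (year, k): `year`, `peak_op` (maximum
#'   of the year's scaled daily samples, g/m2), `k_mixing`, `extirpated`
#'   (list column of node ids), `n_extirpated`.
#' @export
scan_mixing <- function(web, params, forcing_by_year,
                        k_grid = c(0.1, 1, 10),
                        scenario = atn_scenario(),
                        init = default_initial_state(web)) {
  if (length(k_grid) == 0 || length(forcing_by_year) == 0) {
    return(tibble::tibble(year = character(), peak_op = numeric(),
                          k_mixing = numeric(), extirpated = list(),
                          n_extirpated = integer()))
  }
  if (is.null(names(forcing_by_year))) {
    names(forcing_by_year) <- seq_along(forcing_by_year)
  }
  eq_state <- NULL
  if (scenario$strategy == 1) {
    eq_state <- equilibrate(web, params, scenario, init)
  }
  grid <- tidyr::expand_grid(year = names(forcing_by_year), k = k_grid)
  rows <- purrr::pmap(grid, function(year, k) {
    forcing <- forcing_by_year[[year]]
    sc <- scenario
    sc$k_mixing <- k
    state0 <- if (scenario$strategy == 1) {
      eq_state
    } else {
      equilibrate(web, params, sc, init, forcing = forcing)
    }
    traj <- run_year(web, params, forcing, state0, sc)
    tibble::tibble(
      year = year,
      peak_op = max(forcing$knots$biomass_g_m2),
      k_mixing = k,
      extirpated = list(traj$extirpations$node_id),
      n_extirpated = nrow(traj$extirpations)
    )
  })
  dplyr::bind_rows(rows)
}
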