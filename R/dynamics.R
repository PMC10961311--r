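#' Shared logistic growth factor
#'
#' All producers compete for one community-level carrying capacity K:
#' `G = 1 - sum(producer biomass) / K`. G can be negative when producers
#' overshoot K, in which case producer growth reverses. The offshore and
#' baseline nodes never enter the sum: OP is outside the community and the
#' baseline is a constant boundary condition, not a growing population.
#'
#' @param state Named numeric vector of biomasses (g/m2) over the dynamic
#'   nodes of `web`.
#' @param web An `atn_foodweb`.
#' @param K Carrying capacity, g/m2 (> 0).
#' @return Scalar G, shared by every producer.
#' @export
logistic_factor <- function(state, web, K) {
  if (!is.numeric(K) || K <= 0) stop("K must be positive", call. = FALSE)
  prod_ids <- web$nodes$node_id[web$nodes$is_producer & web$nodes$is_dynamic]
  1 - sum(state[prod_ids]) / K
}

#' One-way pelagic-intertidal mixing flux
#'
#' Water-borne exchange moves offshore phytoplankton into the food-web
#' phytoplankton compartment at rate `k_mixing` whenever the offshore
#' concentration exceeds the intertidal one, and is zero otherwise —
#' intertidal phytoplankton is never exported. The flux is continuous at
#' `B_op = B_fp` (both branches give 0).
#'
#' @param B_op Offshore phytoplankton biomass, g/m2.
#' @param B_fp Food-web phytoplankton biomass, g/m2.
#' @param k_mixing Exchange rate, 1/h (>= 0).
#' @return Flux in g/(m2 h), always >= 0. Vectorized over the biomasses.
#' @export
mixing_flux <- function(B_op, B_fp, k_mixing) {
  if (any(k_mixing < 0)) stop("k_mixing must be >= 0", call. = FALSE)
  ifelse(B_op >= B_fp, k_mixing * (B_op - B_fp), 0)
}

#' Holling functional response of one consumer
#'
#' For consumer i and each of its resources j:
#' `F_ij = omega_ij B_j^q / (B0_i^q + d_i B_i B0_i + sum_l omega_il B_l^q)`.
#' With q = 1.2 the response sits between Type II and Type III. The baseline
#' detritus node enters the sums at its constant biomass; the OP node never
#' appears (it is not a trophic resource).
#'
#' @param consumer_id Id of the consumer node.
#' @param state Named biomass vector over dynamic nodes.
#' @param web An `atn_foodweb`.
#' @param params An `atn_params`.
#' @return Tibble `resource_id, F` with one row per resource of the
#'   consumer; each F in [0, 1).
#' @export
functional_response <- function(consumer_id, state, web, params) {
  lp <- params$link_params[params$link_params$consumer_id == consumer_id, ]
  if (nrow(lp) == 0) {
    stop("'", consumer_id, "' has no resources", call. = FALSE)
  }
  B_j <- resource_biomass(lp$resource_id, state, web)
  q <- params$q
  B0 <- params$B0[[consumer_id]]
  d <- params$d[[consumer_id]]
  B_i <- state[[consumer_id]]
  denom <- B0^q + d * B_i * B0 + sum(lp$omega * B_j^q)
  tibble::tibble(resource_id = lp$resource_id,
                 F = lp$omega * B_j^q / denom)
}

# biomass lookup that sees the constant baseline node
resource_biomass <- function(ids, state, web) {
  B <- state[ids]
  if (!is.null(web$baseline_id)) {
    B[ids == web$baseline_id] <- web$baseline_biomass
  }
  if (any(is.na(B))) {
    stop("no biomass for resource(s): ",
         paste(ids[is.na(B)], collapse = ", "), call. = FALSE)
  }
  unname(B)
}

# total predation loss inflicted on node i by all its consumers:
# sum_j x_j y_ji B_j F_ji / e_ji
predation_loss <- function(i, state, web, params) {
  lp <- params$link_params
  preds <- lp[lp$resource_id == i, ]
  if (nrow(preds) == 0) return(0)
  loss <- 0
  for (k in seq_len(nrow(preds))) {
    j <- preds$consumer_id[k]
    x_j <- params$rates$x[params$rates$node_id == j]
    Fj <- functional_response(j, state, web, params)
    F_ji <- Fj$F[Fj$resource_id == i]
    loss <- loss + x_j * preds$y[k] * state[[j]] * F_ji / preds$e[k]
  }
  loss
}

#' Producer growth equation (single node)
#'
#' `dB_i/dt = r_i B_i G(B) - sum_j x_j y_ji B_j F_ji / e_ji`: logistic
#' autotrophic growth under the shared carrying capacity minus losses to
#' every predator j. Applies to algae and to the food-web phytoplankton node
#' (whose mixing subsidy is added separately in [full_rhs()]).
#'
#' @inheritParams functional_response
#' @param i Id of a producer node.
#' @return dB_i/dt in g/(m2 h) (units follow the parameter set).
#' @export
producer_rhs <- function(i, state, web, params) {
  r_i <- params$rates$r[params$rates$node_id == i]
  if (length(r_i) != 1 || is.na(r_i)) {
    stop("'", i, "' is not a dynamic producer", call. = FALSE)
  }
  G <- logistic_factor(state, web, params$K)
  r_i * state[[i]] * G - predation_loss(i, state, web, params)
}

#' Consumer growth equation (single node)
#'
#' `dB_i/dt = f_a x_i B_i sum_j y_ij F_ij - f_m x_i B_i -
#' sum_j x_j y_ji B_j F_ji / e_ji`: assimilated consumption minus metabolic
#' maintenance and mortality minus losses to predation.
#'
#' @inheritParams functional_response
#' @param i Id of a consumer node.
#' @return dB_i/dt in g/(m2 h) (units follow the parameter set).
#' @export
consumer_rhs <- function(i, state, web, params) {
  x_i <- params$rates$x[params$rates$node_id == i]
  if (length(x_i) != 1 || is.na(x_i)) {
    stop("'", i, "' is not a dynamic consumer", call. = FALSE)
  }
  lp <- params$link_params[params$link_params$consumer_id == i, ]
  Fi <- functional_response(i, state, web, params)
  gain <- params$f_a * x_i * state[[i]] *
    sum(lp$y[match(Fi$resource_id, lp$resource_id)] * Fi$F)
  gain - params$f_m * x_i * state[[i]] -
    predation_loss(i, state, web, params)
}

#' Assembled right-hand side of the full system
#'
#' Producer rows follow the producer equation, consumer rows the consumer
#' equation, and the food-web phytoplankton row additionally receives the
#' one-way mixing subsidy `k_mixing (B_op(t) - B_fp)` when the offshore
#' concentration exceeds the intertidal one. The OP and baseline nodes carry
#' no state. With `k_mixing = 0` (or no forcing) the system reduces exactly
#' to the autonomous model.
#'
#' This reference implementation loops over nodes; the integrator uses an
#' algebraically identical vectorized path (see [build_sim_context()]).
#'
#' @param t Time in hours (used only to evaluate the forcing).
#' @param state Named biomass vector over dynamic nodes.
#' @param web An `atn_foodweb`.
#' @param params An `atn_params` (per-hour units for simulation).
#' @param forcing An `atn_forcing` giving B_op(t), or NULL for no subsidy.
#' @param k_mixing Exchange rate 1/h.
#' @return Named derivative vector, same order as `state`.
#' @export
full_rhs <- function(t, state, web, params, forcing = NULL, k_mixing = 0) {
  if (any(is.na(state) | !is.finite(state))) {
    stop("non-finite biomass at index ",
         paste(which(is.na(state) | !is.finite(state)), collapse = ", "),
         call. = FALSE)
  }
  dB <- vapply(names(state), function(i) {
    role <- web$nodes$role[web$nodes$node_id == i]
    if (role == "consumer") consumer_rhs(i, state, web, params)
    else producer_rhs(i, state, web, params)
  }, numeric(1))
  if (!is.null(forcing) && !is.null(web$fp_id) && k_mixing > 0) {
    B_op <- evaluate_forcing(forcing, t)
    dB[web$fp_id] <- dB[web$fp_id] +
      mixing_flux(B_op, state[[web$fp_id]], k_mixing)
  }
  dB
}

#' Precompute the vectorized simulation context
#'
#' Packs the web and parameters into index vectors and weight matrices so the
#' right-hand side evaluates with a handful of matrix products per call. The
#' returned context's `$rhs(t, B, clamped)` is algebraically identical to
#' [full_rhs()]; `clamped` is a logical mask of extirpated nodes whose rows
#' are pinned at zero.
#'
#' @param web A split `atn_foodweb`.
#' @param params An `atn_params` in per-hour units.
#' @param forcing An `atn_forcing` or NULL.
#' @param k_mixing Exchange rate 1/h.
#' @param periodic_hours If not NULL, forcing time wraps modulo this period
#'   (used for equilibration against repeated copies of a year).
#' @return A list with `$ids`, `$rhs`, and the index/weight internals.
#' @export
build_sim_context <- function(web, params, forcing = NULL, k_mixing = 0,
                              periodic_hours = NULL) {
  stopifnot(inherits(web, "atn_foodweb"), inherits(params, "atn_params"))
  if (params$units != "per_hour") {
    stop("simulation requires per-hour parameters; ",
         "apply convert_daily_to_hourly()", call. = FALSE)
  }
  nodes <- web$nodes[web$nodes$is_dynamic, ]
  ids <- nodes$node_id
  n <- length(ids)
  has_baseline <- !is.null(web$baseline_id)
  res_ids <- c(ids, if (has_baseline) web$baseline_id)
  n_res <- length(res_ids)

  idx_prod <- which(nodes$is_producer)
  idx_cons <- which(nodes$role == "consumer")
  fp_idx <- if (!is.null(web$fp_id)) match(web$fp_id, ids) else NA_integer_

  rates <- params$rates
  r <- rates$r[match(ids[idx_prod], rates$node_id)]
  x_c <- rates$x[match(ids[idx_cons], rates$node_id)]
  cons_ids <- ids[idx_cons]
  B0 <- unname(params$B0[cons_ids])
  d <- unname(params$d[cons_ids])

  W <- Wy <- Wye <- matrix(0, length(idx_cons), n_res,
                           dimnames = list(cons_ids, res_ids))
  lp <- params$link_params
  ri <- match(lp$resource_id, res_ids)
  ci <- match(lp$consumer_id, cons_ids)
  keep <- !is.na(ri) & !is.na(ci)
  lp <- lp[keep, ]; ri <- ri[keep]; ci <- ci[keep]
  W[cbind(ci, ri)] <- lp$omega
  Wy[cbind(ci, ri)] <- lp$omega * lp$y
  Wye[cbind(ci, ri)] <- lp$omega * lp$y / lp$e

  q <- params$q; K <- params$K
  f_a <- params$f_a; f_m <- params$f_m
  baseline <- if (has_baseline) web$baseline_biomass else NULL
  B0q <- B0^q

  rhs <- function(t, B, clamped = NULL) {
    if (any(!is.finite(B))) {
      stop("non-finite biomass at index ",
           paste(which(!is.finite(B)), collapse = ", "), call. = FALSE)
    }
    B <- pmax(B, 0)
    Bres <- c(B, baseline)
    Bq <- Bres^q
    S <- drop(W %*% Bq)
    denom <- B0q + d * B[idx_cons] * B0 + S
    u <- x_c * B[idx_cons] / denom
    loss <- (Bq * drop(crossprod(Wye, u)))[seq_len(n)]
    dB <- numeric(n)
    G <- 1 - sum(B[idx_prod]) / K
    dB[idx_prod] <- r * B[idx_prod] * G - loss[idx_prod]
    dB[idx_cons] <- f_a * x_c * B[idx_cons] * drop(Wy %*% Bq) / denom -
      f_m * x_c * B[idx_cons] - loss[idx_cons]
    if (!is.na(fp_idx) && !is.null(forcing) && k_mixing > 0) {
      tt <- if (is.null(periodic_hours)) t else t %% periodic_hours
      dB[fp_idx] <- dB[fp_idx] +
        mixing_flux(evaluate_forcing(forcing, tt), B[fp_idx], k_mixing)
    }
    if (!is.null(clamped)) dB[clamped] <- 0
    dB
  }

  list(ids = ids, n = n, rhs = rhs, idx_prod = idx_prod,
       idx_cons = idx_cons, fp_idx = fp_idx, k_mixing = k_mixing,
       forcing = forcing)
}
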