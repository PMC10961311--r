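#' Build a validated trophic network
#'
#' Constructs an `atn_foodweb` from a species table and a trophic edge list.
#' The species table gives one row per node with its body mass and role;
#' the edge list gives directed consumer-to-resource feeding links.
#'
#' @param species A data frame with columns `node_id`, `name`, `body_mass_g`,
#'   `role` (one of `"producer"`, `"consumer"`, `"phytoplankton"`) and
#'   optionally `guild_override` (NA or one of the guild labels, see
#'   [assign_guilds()]).
#' @param edges A data frame with columns `consumer_id`, `resource_id`; each
#'   row is one feeding link, endpoints must appear in `species`.
#'
#' @return An object of class `atn_foodweb`: a list with tibbles `nodes` and
#'   `links`, plus `op_id`, `fp_id`, `baseline_id` (populated by
#'   [split_phytoplankton()]) and `baseline_biomass`.
#'
#' @details Validation enforces: unique node ids, positive body masses for
#'   dynamic nodes, no self-links, no dangling edge endpoints, every consumer
#'   with at least one resource, and no dynamic node that is completely
#'   isolated (no links in or out).
#'
#' @examples
#' sp <- tibble::tibble(
#'   node_id = c("alga", "snail", "crab"),
#'   name = c("alga", "snail", "crab"),
#'   body_mass_g = c(1e-3, 1, 50),
#'   role = c("producer", "consumer", "consumer")
#' )
#' ed <- tibble::tibble(
#'   consumer_id = c("snail", "crab"),
#'   resource_id = c("alga", "snail")
#' )
#' web <- build_foodweb(sp, ed)
#' web
#' @export
build_foodweb <- function(species, edges) {
  species <- tibble::as_tibble(species)
  edges <- tibble::as_tibble(edges)
  req <- c("node_id", "name", "body_mass_g", "role")
  missing_cols <- setdiff(req, names(species))
  if (length(missing_cols) > 0) {
    stop("species table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("consumer_id", "resource_id") %in% names(edges))) {
    stop("edge list needs columns consumer_id, resource_id", call. = FALSE)
  }
  if (!"guild_override" %in% names(species)) species$guild_override <- NA_character_
  species <- dplyr::mutate(
    species,
    node_id = as.character(.data$node_id),
    name = as.character(.data$name),
    body_mass_g = as.numeric(.data$body_mass_g),
    role = as.character(.data$role),
    guild_override = as.character(.data$guild_override)
  )
  edges <- dplyr::mutate(
    edges,
    consumer_id = as.character(.data$consumer_id),
    resource_id = as.character(.data$resource_id)
  )

  dup <- species$node_id[duplicated(species$node_id)]
  if (length(dup) > 0) {
    stop("duplicated node_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(species$role),
                      c("producer", "consumer", "phytoplankton"))
  if (length(bad_role) > 0) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }

  species$is_producer <- species$role %in% c("producer", "phytoplankton")
  species$is_dynamic <- TRUE

  web <- structure(
    list(nodes = species, links = edges,
         op_id = NULL, fp_id = NULL, baseline_id = NULL,
         baseline_biomass = NA_real_),
    class = "atn_foodweb"
  )
  validate_foodweb(web)
  web
}

#' @keywords internal
validate_foodweb <- function(web) {
  nodes <- web$nodes
  links <- web$links
  ids <- nodes$node_id

  dangling <- setdiff(unique(c(links$consumer_id, links$resource_id)), ids)
  if (length(dangling) > 0) {
    stop("edge endpoint(s) not in species table: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  self <- links$consumer_id == links$resource_id
  if (any(self)) {
    stop("self-links are not allowed (node ",
         paste(unique(links$consumer_id[self]), collapse = ", "), ")",
         call. = FALSE)
  }
  dyn <- nodes$node_id[nodes$is_dynamic]
  bad_mass <- dyn[!is.finite(nodes$body_mass_g[match(dyn, ids)]) |
                    nodes$body_mass_g[match(dyn, ids)] <= 0]
  if (length(bad_mass) > 0) {
    stop("dynamic node(s) without positive body mass: ",
         paste(bad_mass, collapse = ", "), call. = FALSE)
  }
  consumers <- nodes$node_id[nodes$role == "consumer" & nodes$is_dynamic]
  starved <- setdiff(consumers, unique(links$consumer_id))
  if (length(starved) > 0) {
    stop("consumer(s) with zero resources: ",
         paste(starved, collapse = ", "), call. = FALSE)
  }
  if (nrow(links) > 0) {
    touched <- unique(c(links$consumer_id, links$resource_id))
    isolated <- setdiff(dyn, touched)
    if (length(isolated) > 0) {
      stop("isolated dynamic node(s) (no links in or out): ",
           paste(isolated, collapse = ", "), call. = FALSE)
    }
  } else if (!all(nodes$is_producer[nodes$is_dynamic])) {
    stop("a web without links must be producer-only", call. = FALSE)
  }
  invisible(web)
}

#' @export
print.atn_foodweb <- function(x, ...) {
  n_dyn <- sum(x$nodes$is_dynamic)
  cat("<atn_foodweb> ", nrow(x$nodes), " nodes (", n_dyn, " dynamic), ",
      nrow(x$links), " trophic links\n", sep = "")
  if (!is.null(x$op_id)) {
    cat("  phytoplankton split: OP = ", x$op_id, ", FP = ", x$fp_id,
        ", baseline = ", x$baseline_id,
        " (", format(x$baseline_biomass), " g/m2)\n", sep = "")
  }
  invisible(x)
}

#' Split the phytoplankton node into offshore, food-web, and baseline nodes
#'
#' Intertidal phytoplankton receives a pelagic subsidy. To represent this the
#' single phytoplankton node is split three ways: an offshore-phytoplankton
#' (OP) node whose biomass is prescribed by the forcing series (non-dynamic,
#' connected to the web only through water-borne exchange with FP); the
#' food-web phytoplankton (FP) node, which keeps the original node's trophic
#' links and its differential equation; and a constant baseline node standing
#' for detrital particulate organic matter, consumable by exactly the same
#' consumers as FP.
#'
#' @param web An `atn_foodweb` with exactly one node of role
#'   `"phytoplankton"`, which must have at least one consumer.
#' @param baseline_biomass Constant biomass of the baseline detritus node in
#'   g/m2. Default 3750, the minimal particulate-organic-matter level that
#'   keeps filter feeders fed through extended low-phytoplankton periods.
#'
#' @return The modified `atn_foodweb` with `op_id`, `fp_id`, `baseline_id`
#'   set. The OP-FP exchange is *not* a trophic link and never enters a
#'   functional response; it is stored implicitly via `op_id`/`fp_id`.
#' @export
split_phytoplankton <- function(web, baseline_biomass = 3750) {
  stopifnot(inherits(web, "atn_foodweb"))
  if (!is.null(web$op_id)) {
    stop("phytoplankton node already split", call. = FALSE)
  }
  phyto <- web$nodes$node_id[web$nodes$role == "phytoplankton"]
  if (length(phyto) == 0) {
    stop("no node with role 'phytoplankton' designated", call. = FALSE)
  }
  if (length(phyto) > 1) {
    stop("more than one phytoplankton node: ",
         paste(phyto, collapse = ", "), call. = FALSE)
  }
  fp_id <- phyto
  consumers <- unique(web$links$consumer_id[web$links$resource_id == fp_id])
  if (length(consumers) == 0) {
    stop("phytoplankton node '", fp_id, "' has no consumers; nothing to split",
         call. = FALSE)
  }
  m_phyto <- web$nodes$body_mass_g[web$nodes$node_id == fp_id]
  op_id <- paste0(fp_id, ".op")
  baseline_id <- paste0(fp_id, ".baseline")

  extra <- tibble::tibble(
    node_id = c(op_id, baseline_id),
    name = c("offshore phytoplankton", "baseline detritus"),
    body_mass_g = m_phyto,
    role = "phytoplankton",
    guild_override = c("phytoplankton", "detritus"),
    is_producer = c(TRUE, FALSE),
    is_dynamic = FALSE
  )
  web$nodes <- dplyr::bind_rows(web$nodes, extra)
  # baseline shares FP's consumer set exactly
  web$links <- dplyr::bind_rows(
    web$links,
    tibble::tibble(consumer_id = consumers, resource_id = baseline_id)
  )
  web$op_id <- op_id
  web$fp_id <- fp_id
  web$baseline_id <- baseline_id
  web$baseline_biomass <- baseline_biomass
  validate_foodweb(web)
  web
}

#' Prey-averaged trophic level
#'
#' Solves the linear system TL_i = 1 + mean(TL over resources of i), which
#' handles loops (mutual predation, cannibalism excluded by validation) and
#' assigns basal nodes level exactly 1.
#'
#' @param web An `atn_foodweb`.
#' @return A tibble with columns `node_id`, `trophic_level`, one row per node
#'   (OP and baseline included; both are basal).
#' @export
prey_averaged_trophic_level <- function(web) {
  stopifnot(inherits(web, "atn_foodweb"))
  ids <- web$nodes$node_id
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(web$links) > 0) {
    ci <- match(web$links$consumer_id, ids)
    ri <- match(web$links$resource_id, ids)
    for (k in seq_along(ci)) D[ci[k], ri[k]] <- D[ci[k], ri[k]] + 1
    deg <- rowSums(D)
    D[deg > 0, ] <- D[deg > 0, , drop = FALSE] / deg[deg > 0]
  }
  tl <- tryCatch(
    solve(diag(n) - D, rep(1, n)),
    error = function(e) stop("trophic-level system is singular: ",
                             conditionMessage(e), call. = FALSE)
  )
  tibble::tibble(node_id = ids, trophic_level = as.numeric(tl))
}

guild_levels <- c("algae", "filter_feeder", "herbivore", "omnivore",
                  "carnivore", "phytoplankton", "detritus")

#' Assign functional guilds
#'
#' Classifies every node into one of the guilds used for the variability
#' analysis: `algae` (non-phytoplankton producers), `filter_feeder`
#' (consumers of FP or baseline particulate matter), `herbivore` (consumers
#' of producers only), `carnivore` (consumers of animals only), `omnivore`
#' (mixed diet), plus `phytoplankton` (OP, FP) and `detritus` (baseline).
#' A non-NA `guild_override` in the species table wins over the rule.
#'
#' @param web An `atn_foodweb`, split (see [split_phytoplankton()]) or not.
#' @return A tibble with columns `node_id`, `guild` (factor over the seven
#'   labels), one row per node.
#' @export
assign_guilds <- function(web) {
  stopifnot(inherits(web, "atn_foodweb"))
  nodes <- web$nodes
  links <- web$links
  phyto_ids <- c(web$op_id, web$fp_id, web$baseline_id,
                 nodes$node_id[nodes$role == "phytoplankton"])
  producer_ids <- nodes$node_id[nodes$is_producer]

  classify <- function(id, role) {
    if (role == "phytoplankton") {
      return(if (!is.null(web$baseline_id) && id == web$baseline_id)
        "detritus" else "phytoplankton")
    }
    if (role == "producer") return("algae")
    res <- links$resource_id[links$consumer_id == id]
    if (any(res %in% phyto_ids)) return("filter_feeder")
    plant <- res %in% producer_ids
    if (all(plant)) return("herbivore")
    if (all(!plant)) return("carnivore")
    "omnivore"
  }
  guild <- purrr::map2_chr(nodes$node_id, nodes$role, classify)
  override <- !is.na(nodes$guild_override)
  guild[override] <- nodes$guild_override[override]
  bad <- setdiff(unique(guild), guild_levels)
  if (length(bad) > 0) {
    stop("unknown guild label(s) in overrides: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(node_id = nodes$node_id,
                 guild = factor(guild, levels = guild_levels))
}
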