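# Shared in-code fixtures for the test suite. Everything is built
# programmatically; nothing is read from disk.

tiny_species <- function() {
  tibble::tibble(
    node_id = c("alga", "snail", "crab"),
    name = c("an alga", "a snail", "a crab"),
    body_mass_g = c(10, 1, 50),
    role = c("producer", "consumer", "consumer"),
    guild_override = NA_character_
  )
}

tiny_edges <- function() {
  tibble::tibble(consumer_id = c("snail", "crab"),
                 resource_id = c("alga", "snail"))
}

tiny_web <- function() build_foodweb(tiny_species(), tiny_edges())

# a split 5-node web: phytoplankton + alga, filter feeder, herbivore,
# predator; used wherever the OP/FP/baseline structure matters
split_web <- function(baseline_biomass = 3750) {
  species <- tibble::tibble(
    node_id = c("phy", "alga", "ff", "herb", "pred"),
    name = node_id,
    body_mass_g = c(1e-9, 10, 0.5, 0.2, 20),
    role = c("phytoplankton", "producer", "consumer", "consumer",
             "consumer"),
    guild_override = NA_character_
  )
  edges <- tibble::tibble(
    consumer_id = c("ff", "herb", "pred", "pred"),
    resource_id = c("phy", "alga", "ff", "herb")
  )
  split_phytoplankton(build_foodweb(species, edges),
                      baseline_biomass = baseline_biomass)
}

split_web_params <- function(web, K = 8000, ...) {
  convert_daily_to_hourly(
    build_parameters(web, atn_default_config(...), K = K)
  )
}

random_state <- function(web, seed, scale = 1000) {
  ids <- web$nodes$node_id[web$nodes$is_dynamic]
  set.seed(seed)
  stats::setNames(stats::runif(length(ids), 0.1, scale), ids)
}

# fixture suite is deterministic; build once per test run
fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture_suite()
    cache
  }
})

# forward-difference Jacobian for the fixed-point cross-checks
numDeriv_jac <- function(g, v, h = 1e-6) {
  n <- length(v)
  J <- matrix(0, n, n)
  g0 <- g(v)
  for (j in seq_len(n)) {
    vp <- v
    vp[j] <- vp[j] + h * max(1, abs(v[j]))
    J[, j] <- (g(vp) - g0) / (h * max(1, abs(v[j])))
  }
  J
}

# fresh scratch directory under the session tempdir (cleaned up by R itself)
withr_local_tempdir <- function() {
  d <- tempfile("atnsubsidy-test-")
  dir.create(d)
  d
}
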