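test_that("build_foodweb constructs and counts a small web", {
  web <- tiny_web()
  expect_s3_class(web, "atn_foodweb")
  expect_equal(nrow(web$nodes), 3)
  expect_equal(nrow(web$links), 2)
  expect_equal(sum(web$nodes$is_producer), 1)
  expect_true(all(web$nodes$is_dynamic))
})

test_that("structural validation rejects malformed webs by name", {
  expect_error(
    build_foodweb(tiny_species(),
                  tibble::tibble(consumer_id = "snail",
                                 resource_id = "x99")),
    "x99"
  )
  sp <- tiny_species()
  expect_error(build_foodweb(dplyr::bind_rows(sp, sp[2, ]), tiny_edges()),
               "duplicated.*snail")
  # crab has no resources once its link is dropped
  expect_error(build_foodweb(tiny_species(), tiny_edges()[1, ]),
               "zero resources.*crab")
  expect_error(
    build_foodweb(tiny_species(),
                  dplyr::bind_rows(tiny_edges(),
                                   tibble::tibble(consumer_id = "crab",
                                                  resource_id = "crab"))),
    "self-link"
  )
  bad_mass <- tiny_species()
  bad_mass$body_mass_g[1] <- -2
  expect_error(build_foodweb(bad_mass, tiny_edges()), "body mass.*alga")
})

test_that("a linkless web is only valid when producer-only", {
  sp <- tibble::tibble(node_id = c("a", "b"), name = c("a", "b"),
                       body_mass_g = c(1, 2), role = "producer")
  no_edges <- tibble::tibble(consumer_id = character(),
                             resource_id = character())
  expect_s3_class(build_foodweb(sp, no_edges), "atn_foodweb")
  sp$role[2] <- "consumer"
  expect_error(build_foodweb(sp, no_edges), "zero resources")
})

test_that("split_phytoplankton gives FP and baseline identical consumers", {
  species <- tibble::tibble(
    node_id = c("phy", "a", "b"),
    name = node_id,
    body_mass_g = c(1e-9, 0.5, 0.7),
    role = c("phytoplankton", "consumer", "consumer")
  )
  edges <- tibble::tibble(consumer_id = c("a", "b"),
                          resource_id = c("phy", "phy"))
  web <- split_phytoplankton(build_foodweb(species, edges),
                             baseline_biomass = 3750)
  expect_equal(web$fp_id, "phy")
  fp_consumers <- sort(web$links$consumer_id[
    web$links$resource_id == web$fp_id])
  bl_consumers <- sort(web$links$consumer_id[
    web$links$resource_id == web$baseline_id])
  expect_equal(fp_consumers, bl_consumers)
  expect_equal(fp_consumers, c("a", "b"))
  expect_equal(web$baseline_biomass, 3750)
  # OP is non-dynamic and appears in no trophic link
  op_row <- web$nodes[web$nodes$node_id == web$op_id, ]
  expect_false(op_row$is_dynamic)
  expect_false(web$op_id %in% c(web$links$consumer_id,
                                web$links$resource_id))
})

test_that("split_phytoplankton validates its preconditions", {
  expect_error(split_phytoplankton(tiny_web()), "phytoplankton")
  # a phyto node nobody eats is already rejected as isolated at build time
  species <- tibble::tibble(
    node_id = c("phy", "alga", "h"),
    name = node_id,
    body_mass_g = c(1e-9, 10, 1),
    role = c("phytoplankton", "producer", "consumer")
  )
  edges <- tibble::tibble(consumer_id = "h", resource_id = "alga")
  expect_error(build_foodweb(species, edges), "isolated.*phy")
  # and split itself guards against a consumerless phyto node
  edges2 <- tibble::tibble(consumer_id = c("h", "h"),
                           resource_id = c("alga", "phy"))
  web <- build_foodweb(species, edges2)
  web$links <- web$links[web$links$resource_id != "phy", ]
  expect_error(split_phytoplankton(web), "no consumers")
  expect_error(split_phytoplankton(split_web()), "already split")
})

test_that("prey-averaged trophic levels solve the linear system", {
  web <- tiny_web()
  tl <- prey_averaged_trophic_level(web)
  lv <- stats::setNames(tl$trophic_level, tl$node_id)
  expect_equal(lv[["alga"]], 1)
  expect_equal(lv[["snail"]], 2)
  expect_equal(lv[["crab"]], 3)

  # omnivore eating a basal species and a herbivore sits at 2.5
  species <- tibble::tibble(
    node_id = c("p", "h", "o"), name = node_id,
    body_mass_g = c(10, 1, 5),
    role = c("producer", "consumer", "consumer")
  )
  edges <- tibble::tibble(consumer_id = c("h", "o", "o"),
                          resource_id = c("p", "p", "h"))
  tl2 <- prey_averaged_trophic_level(build_foodweb(species, edges))
  expect_equal(tl2$trophic_level[tl2$node_id == "o"], 2.5)
})

test_that("an n-link chain has trophic level n + 1 at the top", {
  for (n_links in 2:6) {
    ids <- paste0("n", seq_len(n_links + 1))
    species <- tibble::tibble(
      node_id = ids, name = ids,
      body_mass_g = 10^seq(0, n_links),
      role = c("producer", rep("consumer", n_links))
    )
    edges <- tibble::tibble(consumer_id = ids[-1],
                            resource_id = ids[-length(ids)])
    tl <- prey_averaged_trophic_level(build_foodweb(species, edges))
    expect_equal(max(tl$trophic_level), n_links + 1)
  }
})

test_that("guild rules follow diet composition and overrides win", {
  web <- split_web()
  g <- assign_guilds(web)
  lab <- stats::setNames(as.character(g$guild), g$node_id)
  expect_equal(lab[["alga"]], "algae")
  expect_equal(lab[["ff"]], "filter_feeder")   # eats FP + baseline
  expect_equal(lab[["herb"]], "herbivore")     # algae only
  expect_equal(lab[["pred"]], "carnivore")     # animals only
  expect_equal(lab[["phy"]], "phytoplankton")
  expect_equal(lab[[web$baseline_id]], "detritus")

  # mixed plant/animal diet -> omnivore
  species <- tibble::tibble(
    node_id = c("p", "h", "o"), name = node_id,
    body_mass_g = c(10, 1, 5),
    role = c("producer", "consumer", "consumer")
  )
  edges <- tibble::tibble(consumer_id = c("h", "o", "o"),
                          resource_id = c("p", "p", "h"))
  g2 <- assign_guilds(build_foodweb(species, edges))
  expect_equal(as.character(g2$guild[g2$node_id == "o"]), "omnivore")

  # explicit override beats the rule
  species$guild_override <- c(NA, NA, "carnivore")
  g3 <- assign_guilds(build_foodweb(species, edges))
  expect_equal(as.character(g3$guild[g3$node_id == "o"]), "carnivore")
})

test_that("guild assignment partitions every dynamic node", {
  for (fx_name in c("flat_forcing", "niche50_pulse")) {
    web <- fixtures()[[fx_name]]$web
    g <- assign_guilds(web)
    dyn <- web$nodes$node_id[web$nodes$is_dynamic]
    expect_setequal(intersect(g$node_id, dyn), dyn)
    expect_equal(anyDuplicated(g$node_id), 0)
    expect_false(any(is.na(g$guild)))
  }
})
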