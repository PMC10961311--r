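test_that("logistic factor is linear in total producer biomass", {
  web <- split_web()
  p <- split_web_params(web)
  K <- p$K
  st <- c(phy = 0, alga = 0, ff = 10, herb = 5, pred = 1)
  expect_equal(logistic_factor(st, web, K), 1)
  st["alga"] <- K
  expect_equal(logistic_factor(st, web, K), 0)
  st["alga"] <- 2 * K
  expect_equal(logistic_factor(st, web, K), -1)
  # baseline detritus never enters the producer sum: only phy + alga count
  st2 <- c(phy = K / 2, alga = K / 2, ff = 1e6, herb = 1e6, pred = 1e6)
  expect_equal(logistic_factor(st2, web, K), 0)
  expect_error(logistic_factor(st, web, K = 0), "positive")
})

test_that("mixing flux is one-way and continuous at the boundary", {
  expect_equal(mixing_flux(10, 4, 1), 6)
  expect_equal(mixing_flux(4, 10, 1), 0)
  expect_equal(mixing_flux(7, 7, 5), 0)
  expect_error(mixing_flux(1, 1, -0.1), ">= 0")
})

test_that("functional response is half-saturated at B0 for any q", {
  species <- tibble::tibble(node_id = c("p", "c"), name = node_id,
                            body_mass_g = c(10, 1),
                            role = c("producer", "consumer"))
  edges <- tibble::tibble(consumer_id = "c", resource_id = "p")
  web <- build_foodweb(species, edges)
  for (q in c(1, 1.2, 2)) {
    p <- build_parameters(
      web,
      atn_default_config(functional_response = list(q = q, d = 0)),
      K = 1000
    )
    B0 <- unname(p$B0["c"])
    st <- c(p = B0, c = 50)
    Fr <- functional_response("c", st, web, p)
    expect_equal(Fr$F, 0.5)
    # zero resource density means zero consumption
    expect_equal(functional_response("c", c(p = 0, c = 50), web, p)$F, 0)
  }
})

test_that("functional response matches scalar re-computation", {
  web <- split_web()
  p <- split_web_params(web)
  set.seed(31)
  for (rep in 1:10) {
    st <- random_state(web, seed = rep)
    for (cons in c("ff", "herb", "pred")) {
      Fr <- functional_response(cons, st, web, p)
      lp <- p$link_params[p$link_params$consumer_id == cons, ]
      lp <- lp[match(Fr$resource_id, lp$resource_id), ]
      Bj <- ifelse(lp$resource_id == web$baseline_id,
                   web$baseline_biomass, st[lp$resource_id])
      denom <- p$B0[[cons]]^p$q +
        p$d[[cons]] * st[[cons]] * p$B0[[cons]] +
        sum(lp$omega * Bj^p$q)
      expect_equal(Fr$F, unname(lp$omega * Bj^p$q / denom))
      expect_true(all(Fr$F >= 0 & Fr$F < 1))
    }
  }
})

test_that("functional response rises with prey density, falls with interference", {
  species <- tibble::tibble(node_id = c("p", "c"), name = node_id,
                            body_mass_g = c(10, 1),
                            role = c("producer", "consumer"))
  edges <- tibble::tibble(consumer_id = "c", resource_id = "p")
  web <- build_foodweb(species, edges)
  mk <- function(d) build_parameters(
    web, atn_default_config(functional_response = list(d = d)), K = 1000
  )
  p_d <- mk(0.5)
  grid <- seq(10, 5000, length.out = 40)
  f_of_b <- vapply(grid, function(b) {
    functional_response("c", c(p = b, c = 100), web, p_d)$F
  }, numeric(1))
  expect_true(all(diff(f_of_b) > 0))
  f_of_d <- vapply(c(0, 0.1, 0.5, 2, 10), function(d) {
    functional_response("c", c(p = 500, c = 100), web, mk(d))$F
  }, numeric(1))
  expect_true(all(diff(f_of_d) < 0))
})

test_that("producer equation has its logistic and absorbing fixed points", {
  fx <- fixtures()$producer_only
  web <- fx$web
  p <- fx$params
  # sole producer exactly at K with no consumers: dB/dt = 0
  st <- c(algaA = p$K, algaB = 0, algaC = 0)
  expect_equal(producer_rhs("algaA", st, web, p), 0)
  expect_equal(producer_rhs("algaB", st, web, p), 0)  # extinct producer
})

test_that("consumer equation decays at rate f_m x when starved", {
  web <- split_web()
  p <- split_web_params(web)
  # herb's only resource (alga) is empty and its predator is absent, so the
  # equation reduces to pure metabolic decay; the detrital pool never
  # empties, which is why the starved node must lack that channel
  st <- c(phy = 1000, alga = 0, ff = 100, herb = 50, pred = 0)
  x_h <- p$rates$x[p$rates$node_id == "herb"]
  expect_equal(consumer_rhs("herb", st, web, p),
               -p$f_m * x_h * st[["herb"]])
  # biomass zero is absorbing
  st["pred"] <- 0
  expect_equal(consumer_rhs("pred", st, web, p), 0)
})

test_that("energy accounting: consumer gain over prey loss equals f_a e", {
  web <- split_web()
  p <- split_web_params(web)
  for (rep in 1:5) {
    st <- random_state(web, seed = 100 + rep)
    # link pred -> herb: gain term f_a x_p B_p y F, prey loss x_p y B_p F/e
    x_p <- p$rates$x[p$rates$node_id == "pred"]
    lp <- p$link_params[p$link_params$consumer_id == "pred" &
                          p$link_params$resource_id == "herb", ]
    Fr <- functional_response("pred", st, web, p)
    F_ph <- Fr$F[Fr$resource_id == "herb"]
    gain <- p$f_a * x_p * st[["pred"]] * lp$y * F_ph
    loss <- x_p * lp$y * st[["pred"]] * F_ph / lp$e
    expect_equal(gain / loss, p$f_a * lp$e)
    expect_lte(p$f_a * lp$e, 1)
  }
})

test_that("assembled rhs equals per-node evaluation and vectorized context", {
  web <- split_web()
  p <- split_web_params(web)
  forcing <- constant_forcing(5000)
  ctx <- build_sim_context(web, p, forcing = forcing, k_mixing = 2)
  for (seed in 1:8) {
    st <- random_state(web, seed = seed)
    loop <- full_rhs(0, st, web, p, forcing = forcing, k_mixing = 2)
    vec <- ctx$rhs(0, unname(st[ctx$ids]))
    expect_equal(unname(loop[ctx$ids]), vec)
  }
})

test_that("with k_mixing = 0 the forced rhs reduces to the autonomous one", {
  web <- split_web()
  p <- split_web_params(web)
  forcing <- constant_forcing(1e6)
  ctx_forced <- build_sim_context(web, p, forcing = forcing, k_mixing = 0)
  ctx_auto <- build_sim_context(web, p)
  for (seed in 1:5) {
    st <- unname(random_state(web, seed = seed)[ctx_auto$ids])
    expect_identical(ctx_forced$rhs(13, st), ctx_auto$rhs(13, st))
  }
})

test_that("the FP row gains exactly the mixing flux", {
  web <- split_web()
  p <- split_web_params(web)
  st <- random_state(web, seed = 77)
  level <- 1e5
  forcing <- constant_forcing(level)
  with_k <- full_rhs(0, st, web, p, forcing = forcing, k_mixing = 3)
  without <- full_rhs(0, st, web, p)
  diff <- with_k - without
  expect_equal(unname(diff[web$fp_id]),
               mixing_flux(level, st[[web$fp_id]], 3))
  expect_equal(unname(diff[names(st) != web$fp_id]),
               rep(0, length(st) - 1))
})

test_that("all-zero state gives an all-zero derivative", {
  web <- split_web()
  p <- split_web_params(web)
  st <- stats::setNames(rep(0, 5), c("phy", "alga", "ff", "herb", "pred"))
  expect_equal(unname(full_rhs(0, st, web, p)), rep(0, 5))
  expect_error(full_rhs(0, replace(st, 2, NaN), web, p), "index 2")
})
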