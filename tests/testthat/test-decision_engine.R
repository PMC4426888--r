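test_that("with all probabilities zero a year only ages agents", {
  r <- get_tiny_region()
  ctx <- decision_context(scenario_zeroed(), run_seed = 1)
  r2 <- step_year(r, ctx)
  expect_identical(r2$year, r$year + 1L)
  expect_identical(r2$parcels, r$parcels)
  expect_equal(r2$farmers$age, pmin(r$farmers$age + 1, 100))
  expect_identical(r2$farmers$active, r$farmers$active)
  expect_identical(r2$residents, r$residents)
  expect_identical(r2$tourism_demand, r$tourism_demand)
})

test_that("a ceasing farmer with no buyers abandons all parcels to semi-natural", {
  r <- toy_region(1L)
  ctx <- decision_context(scenario_flat_cessation(1), run_seed = 1)
  r2 <- step_year(r, ctx)
  expect_false(r2$farmers$active[1])
  expect_true(all(r2$parcels$land_use == "semi_natural"))
  expect_true(all(r2$parcels$owner_class == "none"))
  expect_identical(sum(r2$parcels$area_ha), sum(r$parcels$area_ha))
  expect_identical(nrow(validate_region(r2)), 0L)
})

test_that("homogeneous cessation matches the binomial expectation", {
  # 60-farm fixture, p = 0.1, one year, 200 replicates: mean within 3 s.e.
  r <- get_tiny_region()
  n <- sum(r$farmers$active)
  p <- 0.1
  sc <- scenario_flat_cessation(p)
  reps <- 200L
  cess <- vapply(seq_len(reps), function(rep) {
    ctx <- decision_context(sc, run_seed = 11, replicate = rep,
                            validate = FALSE)
    sum(!step_year(r, ctx)$farmers$active)
  }, numeric(1))
  se <- sqrt(n * p * (1 - p) / reps)
  expect_lt(abs(mean(cess) - n * p), 3 * se)
})

test_that("decide_cessation composes configured rates multiplicatively", {
  # base 0.2 (mid age class) x small-farm multiplier 0.5 at 8 DSU -> 0.10
  sc <- scenario_flat_cessation(0.2)
  sc$cessation$small_farm_subsidy <- 0.5
  sc <- coulisse:::validate_scenario(sc)
  ctx <- decision_context(sc, run_seed = 1)
  farmer <- list(type = "conventional", age = 50, dsu = 8, retire_age = 65)
  set.seed(99)
  u <- runif(50000)
  out <- vapply(u, function(ui) decide_cessation(farmer, ctx, u = ui),
                character(1))
  freq <- mean(out == "cease")
  se <- sqrt(0.1 * 0.9 / 50000)
  expect_lt(abs(freq - 0.10), 3 * se)
  # age below every configured retirement trigger never retires
  expect_false(any(out == "retire_with_successor"))
})

test_that("a small farm ceases less often under BTS than AMIS (common draws)", {
  bts <- decision_context(load_scenario("BTS"), run_seed = 1)
  amis <- decision_context(load_scenario("AMIS"), run_seed = 1)
  farmer <- list(type = "conventional", age = 50, dsu = 8, retire_age = 65)
  set.seed(12)
  u <- runif(10000)
  n_bts <- sum(vapply(u, function(ui)
    decide_cessation(farmer, bts, u = ui) == "cease", logical(1)))
  n_amis <- sum(vapply(u, function(ui)
    decide_cessation(farmer, amis, u = ui) == "cease", logical(1)))
  expect_lt(n_bts, n_amis)
})

test_that("raising a cessation multiplier never lowers realised cessations", {
  # common random numbers: cease occupies the lower end of the draw, so the
  # outcome is monotone per farmer and in aggregate
  r <- get_tiny_region()
  cess <- vapply(c(0.5, 1, 2, 4, 8), function(m) {
    sc <- scenario_flat_cessation(0.05)
    sc$cessation$scenario_mult <- m
    ctx <- decision_context(coulisse:::validate_scenario(sc), run_seed = 21,
                            validate = FALSE)
    sum(!step_year(r, ctx)$farmers$active)
  }, numeric(1))
  expect_true(all(diff(cess) >= 0))
})

test_that("expansion bids rank by productivity and zone multipliers", {
  sc <- load_scenario("AMIS")
  ctx <- decision_context(sc, run_seed = 1)
  farmer <- list(id = 1L, type = "expansionist", x = 0, y = 0)
  offers <- data.table::data.table(
    id = c(10L, 11L), x = c(3000, 3000), y = c(0, 0), area_ha = 1,
    productivity = c(0.4, 0.9),
    z_protect = FALSE, z_habitat = FALSE, z_agridev = FALSE,
    z_leader = FALSE, z_pilot = FALSE, z_attraction = FALSE)
  bids <- decide_expansion_bids(farmer, offers, ctx)
  expect_identical(bids$parcel_id, c(11L, 10L))  # higher productivity first

  # identical parcels, development vs habitat zone: score ratio equals the
  # configured multiplier ratio exactly
  offers2 <- data.table::data.table(
    id = c(20L, 21L), x = 3000, y = 0, area_ha = 1, productivity = 0.8,
    z_protect = FALSE, z_habitat = c(FALSE, TRUE), z_agridev = c(TRUE, FALSE),
    z_leader = FALSE, z_pilot = FALSE, z_attraction = FALSE)
  b2 <- decide_expansion_bids(farmer, offers2, ctx)
  expect_identical(b2$parcel_id[1], 20L)
  expect_equal(b2$score[b2$parcel_id == 20L] / b2$score[b2$parcel_id == 21L],
               sc$expansion$zone_mult[["agri_development"]] /
                 sc$expansion$zone_mult[["habitat_directive"]])

  # a type with zero propensity submits no bids
  hobby <- list(id = 2L, type = "hobby", x = 0, y = 0)
  expect_identical(nrow(decide_expansion_bids(hobby, offers, ctx)), 0L)
})

test_that("market allocation follows the bid > estate > nature > abandon cascade", {
  r <- toy_region(2L)
  sc <- scenario_zeroed()
  ctx <- decision_context(sc, run_seed = 1)
  offers <- data.table::data.table(parcel_id = c(3L, 4L),
                                   seller_id = c(1L, 2L), forced = FALSE)
  no_bids <- data.table::data.table(parcel_id = integer(),
                                    bidder_id = integer(),
                                    bidder_type = character(),
                                    score = numeric())
  # (d) everything abandons when no channel is open
  tr <- allocate_market(offers, no_bids, ctx, r$parcels)
  expect_true(all(tr$buyer_class == "abandon"))

  # (c) nature organisation takes habitat parcels with probability 1
  sc2 <- scenario_zeroed(); sc2$market$p_nature[["habitat_directive"]] <- 1
  ctx2 <- decision_context(coulisse:::validate_scenario(sc2), run_seed = 1)
  r2 <- toy_region(2L); r2$parcels[3:4, z_habitat := TRUE]
  tr2 <- allocate_market(offers, no_bids, ctx2, r2$parcels)
  expect_true(all(tr2$buyer_class == "nature"))

  # (a) a farmer bid beats both
  bids <- data.table::data.table(parcel_id = 3L, bidder_id = 2L,
                                 bidder_type = "expansionist", score = 1)
  tr3 <- allocate_market(offers, bids, ctx2, r2$parcels)
  expect_identical(tr3[tr3$parcel_id == 3L]$buyer_class, "farmer")
  expect_identical(tr3[tr3$parcel_id == 3L]$buyer_id, 2L)

  # a parcel offered twice is rejected
  expect_error(allocate_market(rbind(offers, offers[1]), no_bids, ctx,
                               r$parcels), "offered twice")
})

test_that("estate purchases match the binomial oracle", {
  # 100 qualifying parcels, p_estate = 0.3, 500 one-year replicates
  n <- 100L
  parcels <- data.table::data.table(
    id = seq_len(n), x = 50, y = 50, area_ha = 1, land_use = "agriculture",
    productivity = 0.5, aesthetic = 0.9, element_m = 0,
    z_protect = FALSE, z_habitat = FALSE, z_agridev = FALSE,
    z_leader = FALSE, z_pilot = FALSE, z_attraction = FALSE,
    owner_id = 1L, owner_class = "farmer")
  sc <- scenario_zeroed(); sc$market$p_estate <- 0.3
  sc <- coulisse:::validate_scenario(sc)
  offers <- data.table::data.table(parcel_id = seq_len(n), seller_id = 1L,
                                   forced = FALSE)
  no_bids <- data.table::data.table(parcel_id = integer(),
                                    bidder_id = integer(),
                                    bidder_type = character(),
                                    score = numeric())
  reps <- 500L
  bought <- vapply(seq_len(reps), function(i) {
    set.seed(i)
    ctx <- decision_context(sc, run_seed = i)
    sum(allocate_market(offers, no_bids, ctx, parcels)$buyer_class == "resident")
  }, numeric(1))
  se <- sqrt(n * 0.3 * 0.7 / reps)
  expect_lt(abs(mean(bought) - 30), 3 * se)
})

test_that("element actions update lengths by the configured arithmetic", {
  sc <- load_scenario("BTS")
  ctx <- decision_context(sc, run_seed = 1)
  parcel <- list(element_m = 300, area_ha = 1, z_protect = FALSE,
                 z_habitat = FALSE)
  # keep leaves the length unchanged
  pr <- coulisse:::element_probs("conventional", FALSE, FALSE, sc)
  keep_u <- pr$cut + pr$plant + 0.5 * pr$keep
  expect_equal(decide_element_action("conventional", parcel, ctx,
                                     u = keep_u)$element_m, 300)
  # cut with cut_fraction 1 empties the parcel
  sc2 <- load_scenario("BTS"); sc2$elements$cut_fraction <- 1
  ctx2 <- decision_context(coulisse:::validate_scenario(sc2), run_seed = 1)
  expect_equal(decide_element_action("conventional", parcel, ctx2,
                                     u = 0)$element_m, 0)
  # plant adds increment x area: 100 m + 50 m/ha on 1 ha -> 150 m
  parcel2 <- list(element_m = 100, area_ha = 1, z_protect = FALSE,
                  z_habitat = FALSE)
  out <- decide_element_action("conventional", parcel2, ctx,
                               u = pr$cut + pr$plant / 2)
  expect_identical(out$action, "plant")
  expect_equal(out$element_m, 100 + sc$elements$plant_increment_m_ha)
  # unknown manager class is a configuration error
  expect_error(decide_element_action("martian", parcel, ctx), "martian")
})

test_that("cutting is strictly less likely inside protection zones under BTS", {
  sc <- load_scenario("BTS")
  ctx <- decision_context(sc, run_seed = 1)
  inside <- list(element_m = 100, area_ha = 1, z_protect = TRUE,
                 z_habitat = FALSE)
  outside <- list(element_m = 100, area_ha = 1, z_protect = FALSE,
                  z_habitat = FALSE)
  set.seed(5)
  u <- runif(10000)
  cut_in <- sum(vapply(u, function(ui)
    decide_element_action("conventional", inside, ctx, u = ui)$action == "cut",
    logical(1)))
  cut_out <- sum(vapply(u, function(ui)
    decide_element_action("conventional", outside, ctx, u = ui)$action == "cut",
    logical(1)))
  expect_lt(cut_in, cut_out)
})

test_that("tourism demand follows the landscape-change feedback formula", {
  r <- toy_region(2L)
  sc <- scenario_zeroed()
  # g = 0: index never moves
  ctx0 <- decision_context(sc, run_seed = 1)
  expect_identical(update_tourism_demand(r, ctx0), 1.0)
  # elements +10% year-on-year, g = 0.5, weights (1,0,0) -> x1.05
  sc$tourism$gain <- 0.5
  sc$tourism$weights <- c(elements = 1, semi_natural = 0, attractions = 0)
  ctx <- decision_context(coulisse:::validate_scenario(sc), run_seed = 1)
  r$last_metrics <- c(elements = sum(r$parcels$element_m) / 1.10,
                      semi_natural = 0, attractions = 0)
  expect_equal(update_tourism_demand(r, ctx), 1 + 0.5 * 0.10)
})

test_that("area is conserved and the region stays valid over many years", {
  r <- generate_region(tiny_cfg(), seed = 9)
  total0 <- sum(r$parcels$area_ha)
  for (scn in c("BTS", "AMIS")) {
    ri <- r
    for (t in 1:8) {
      ctx <- decision_context(load_scenario(scn), run_seed = 4, replicate = 2)
      ri <- step_year(ri, ctx)
      expect_equal(sum(ri$parcels$area_ha), total0)
      expect_identical(nrow(validate_region(ri)), 0L)
    }
    # farmer count non-increasing without in-migration
    expect_lte(sum(ri$farmers$active), sum(r$farmers$active))
  }
})

test_that("trajectories are bit-for-bit reproducible from the seed", {
  r <- get_tiny_region()
  run <- function() {
    ri <- r
    for (t in 1:5) {
      ctx <- decision_context(load_scenario("AMIS"), run_seed = 33,
                              replicate = 4)
      ri <- step_year(ri, ctx)
    }
    ri
  }
  a <- run(); b <- run()
  expect_identical(a$parcels, b$parcels)
  expect_identical(a$farmers, b$farmers)
  expect_identical(a$residents, b$residents)
  expect_identical(a$tourism_demand, b$tourism_demand)
})

test_that("a mismatched context year is rejected before mutation", {
  r <- get_tiny_region()
  ctx <- decision_context(scenario_zeroed(), run_seed = 1, year = 2010L)
  expect_error(step_year(r, ctx), "year")
})
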