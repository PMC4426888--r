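make_bids <- function(...) {
  data.table::data.table(...)
}

test_that("zoning removes only expansionist bids inside restricted zones", {
  r <- toy_region(3L, types = c("expansionist", "diversified_multifunctional",
                                "conventional"))
  r$parcels[c(4L, 5L), z_protect := TRUE]
  spec <- intervention_spec(zoning = list(enabled = TRUE))
  bids <- make_bids(parcel_id = c(4L, 4L, 5L, 6L),
                    bidder_id = c(1L, 2L, 1L, 1L),
                    bidder_type = c("expansionist",
                                    "diversified_multifunctional",
                                    "expansionist", "expansionist"),
                    score = c(1, 0.5, 1, 1))
  out <- restrict_bids_zoning(bids, spec, r$parcels)
  # expansionist bids on protected parcels 4 and 5 removed
  expect_identical(out$bids$parcel_id, c(4L, 6L))
  expect_identical(out$bids$bidder_type,
                   c("diversified_multifunctional", "expansionist"))
  expect_identical(sum(out$restricted), 2L)

  # with no expansionist bids the table is unchanged
  bids2 <- bids[bids$bidder_type != "expansionist"]
  expect_identical(restrict_bids_zoning(bids2, spec, r$parcels)$bids, bids2)
})

test_that("k-nearest neighbour sets equal a brute-force all-pairs computation", {
  # 12 farmsteads on a ring of radius 2 km
  set.seed(3)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  farmers <- data.table::data.table(
    id = 1:12, type = "conventional", age = 45, dsu = 20,
    x = round(5000 + 2000 * cos(th)), y = round(5000 + 2000 * sin(th)),
    farmstead_id = 1:12, retire_age = 65, active = TRUE)
  cand <- coulisse:::knn_candidates(farmers, m = 11L)
  for (i in 1:12) {
    d <- sqrt((farmers$x - farmers$x[i])^2 + (farmers$y - farmers$y[i])^2)
    d[i] <- Inf
    brute <- farmers$id[order(d, farmers$id)][1:11]
    expect_identical(unname(cand[i, ]), brute)
  }
})

# line of farmsteads 300 m apart. Farmers 2..(1+n_mult) are multifunctional,
# so farmer 1's 10-nearest census holds exactly n_mult of them. Tourist
# assets are attraction-tagged parcels at the x positions in `asset_x`
# (none by default); elements are zero everywhere.
coop_region <- function(n_mult, asset_x = numeric(), n = 12L,
                        types = NULL) {
  na <- length(asset_x)
  parcels <- data.table::data.table(
    id = seq_len(n + na), x = c(seq_len(n) * 300 - 250, asset_x),
    y = c(rep(150, n), rep(150, na)),
    area_ha = 1,
    land_use = c(rep("agriculture", n), rep("semi_natural", na)),
    productivity = 0.5, aesthetic = 0.5, element_m = 0,
    z_protect = FALSE, z_habitat = FALSE, z_agridev = FALSE,
    z_leader = FALSE, z_pilot = FALSE,
    z_attraction = c(rep(FALSE, n), rep(TRUE, na)),
    owner_id = c(seq_len(n), rep(NA_integer_, na)),
    owner_class = c(rep("farmer", n), rep("none", na)))
  if (is.null(types)) {
    types <- rep("conventional", n)
    if (n_mult > 0) types[1 + seq_len(n_mult)] <- "diversified_multifunctional"
  }
  farmers <- data.table::data.table(
    id = seq_len(n), type = types, age = 45, dsu = 20,
    x = parcels$x[seq_len(n)], y = parcels$y[seq_len(n)],
    farmstead_id = seq_len(n), retire_age = 65, active = TRUE)
  structure(list(parcels = parcels, farmers = farmers,
                 residents = data.table::data.table(
                   id = integer(), x = numeric(), y = numeric(),
                   residence_id = integer(), migrant = logical()),
                 year = 2005L, start_year = 2005L, tourism_demand = 1.0,
                 grid = list(nx = as.integer(ceiling(max(parcels$x) / 100)),
                             ny = 5L, cell_m = 100),
                 total_area_ha = n + na,
                 baseline = list(element_total_m = 0, semi_natural_ha = na,
                                 attraction_n = na,
                                 element_cell_threshold = 1)),
            class = "region")
}

test_that("adoption needs the neighbour threshold AND a tourist asset", {
  spec <- intervention_spec(cooperation = list(enabled = TRUE, rate = 1,
                                               tourism_increase = 0))
  # 3 of 10 nearest multifunctional: below threshold, no adoption possible
  expect_length(cooperation_adoption_step(coop_region(3, asset_x = 50), spec), 0)
  # 4 of 10 with an asset in range and rate 1: farmer 1 adopts with certainty
  set.seed(1)
  adopters <- cooperation_adoption_step(coop_region(4, asset_x = 50), spec)
  expect_true(1L %in% adopters)
  # 5 of 10 but no tourist asset within the radius: no adoption
  expect_length(cooperation_adoption_step(coop_region(5), spec), 0)
})

test_that("with fewer than k active farmers the census uses all available", {
  r <- coop_region(4, asset_x = 50, n = 6L)        # only 6 farmers exist
  spec <- intervention_spec(cooperation = list(enabled = TRUE, rate = 1,
                                               tourism_increase = 0))
  expect_no_error(adopters <- cooperation_adoption_step(r, spec))
  expect_true(1L %in% adopters)                    # 4 of 5 neighbours mult
})

test_that("adoption is simultaneous: the census sees start-of-year types only", {
  # 15 farmers on a line, multifunctional at ids 2-5, attractions near
  # farmers 7 and 8. Farmer 7's census (2..6, 8..12) holds 4 multifunctional
  # farmers, so 7 adopts with rate 1; farmer 8's census (3..7, 9..13) holds
  # only 3. Were the census sequential, 7's same-year switch would make 8
  # eligible too - simultaneity says 8 must not adopt this year.
  r <- coop_region(4, asset_x = c(1850, 2150), n = 15L)
  spec <- intervention_spec(cooperation = list(enabled = TRUE, rate = 1,
                                               tourism_increase = 0))
  ctx <- decision_context(scenario_zeroed(),
                          intervention = spec, run_seed = 2)
  r2 <- step_year(r, ctx)
  adopted <- r2$farmers$id[r2$farmers$type == "diversified_multifunctional" &
                             r$farmers$type != "diversified_multifunctional"]
  expect_true(7L %in% adopted)
  expect_false(8L %in% adopted)
})

test_that("cooperation stochastically raises the multifunctional count", {
  r <- generate_region(tiny_cfg(), seed = 11)
  run <- function(rate) {
    spec <- intervention_spec(cooperation = list(enabled = TRUE, rate = rate))
    ri <- coulisse:::freeze_asset_threshold(coulisse:::ensure_knn(r), spec)
    for (t in 1:10) {
      ctx <- decision_context(load_scenario("BTS"), intervention = spec,
                              run_seed = 17, replicate = 1, validate = FALSE)
      ri <- step_year(ri, ctx)
    }
    sum(ri$farmers$active &
          ri$farmers$type == "diversified_multifunctional")
  }
  expect_gte(run(0.9), run(0))
})

test_that("in-migration rewires market parameters but not supply", {
  sc <- load_scenario("BTS")
  spec <- intervention_spec(inmigration = list(enabled = TRUE,
                                               purchase_prob = 1.0,
                                               aesthetic_threshold = 0.2))
  m <- apply_inmigration(spec, sc$market)
  expect_identical(m$p_estate, 1.0)
  expect_identical(m$estate_aesthetic_min, 0.2)
  # disabled: a no-op
  expect_identical(apply_inmigration(intervention_spec(), sc$market),
                   sc$market)

  # 50 qualifying offers, purchase probability 1, no competing bids -> 50
  n <- 50L
  parcels <- data.table::data.table(
    id = seq_len(n), x = 50, y = 50, area_ha = 1, land_use = "agriculture",
    productivity = 0.5, aesthetic = 0.5, element_m = 0,
    z_protect = FALSE, z_habitat = FALSE, z_agridev = FALSE,
    z_leader = FALSE, z_pilot = FALSE, z_attraction = FALSE,
    owner_id = 1L, owner_class = "farmer")
  ctx <- decision_context(scenario_zeroed(), intervention = spec,
                          run_seed = 1)
  offers <- data.table::data.table(parcel_id = seq_len(n), seller_id = 1L,
                                   forced = FALSE)
  no_bids <- data.table::data.table(parcel_id = integer(),
                                    bidder_id = integer(),
                                    bidder_type = character(),
                                    score = numeric())
  tr <- allocate_market(offers, no_bids, ctx, parcels)
  expect_identical(sum(tr$buyer_class == "resident"), n)
  expect_identical(sum(tr$qualifying_estate), n)

  # purchase_prob 0 -> no migrant purchases at all
  spec0 <- intervention_spec(inmigration = list(enabled = TRUE,
                                                purchase_prob = 0))
  ctx0 <- decision_context(scenario_zeroed(), intervention = spec0,
                           run_seed = 1)
  tr0 <- allocate_market(offers, no_bids, ctx0, parcels)
  expect_identical(sum(tr0$buyer_class == "resident"), 0L)
})

test_that("zoning keeps restricted-zone expansionist holdings non-increasing", {
  r <- generate_region(tiny_cfg(), seed = 13)
  spec <- intervention_spec(zoning = list(enabled = TRUE))
  restricted <- coulisse:::restricted_parcels(r$parcels, spec)
  count_exp <- function(reg) {
    exp_ids <- reg$farmers$id[reg$farmers$type == "expansionist"]
    sum(reg$parcels$owner_class == "farmer" &
          reg$parcels$owner_id %in% exp_ids &
          restricted)
  }
  prev <- count_exp(r)
  ri <- r
  for (t in 1:8) {
    ctx <- decision_context(load_scenario("AMIS"), intervention = spec,
                            run_seed = 5, replicate = 3, validate = FALSE)
    ri <- step_year(ri, ctx)
    cur <- count_exp(ri)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("intervention specs validate their invariants", {
  expect_error(intervention_spec(cooperation = list(threshold = 12)),
               "threshold")
  expect_error(intervention_spec(inmigration = list(purchase_prob = 1.4)),
               "purchase_prob")
  expect_error(intervention_spec(zoning = list(restricted_zones = "moon")),
               "unknown restricted zone")
})
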